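# shared simulation scene, built once per test run
.spet_cache <- new.env(parent = emptyenv())

spet_fixture <- function() {
  if (is.null(.spet_cache$fx)) {
    spetLogLevel("quiet")
    .spet_cache$fx <- defaultFixture(seed = 7)
  }
  .spet_cache$fx
}

# fixture + one simulated sequencing run, genotyped (unfiltered matrix)
spet_run <- function() {
  if (is.null(.spet_cache$run)) {
    fx <- spet_fixture()
    spetLogLevel("quiet")
    reads <- simulateReads(fx$panel, fx$germplasm, seed = 8)
    depths <- tallyAlleles(reads, fx$panel, fx$genome)
    gm <- discoverSites(depths, fx$panel, fx$config)
    .spet_cache$run <- list(fx = fx, reads = reads, depths = depths,
                            gm = gm)
  }
  .spet_cache$run
}

# build a SpetGenotypes from bare matrices for toy tables
toy_genotypes <- function(geno, depth = NULL, target = NULL,
                          contig = "chr1") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
  if (is.null(depth))
    depth <- matrix(50L, nrow(geno), ncol(geno),
                    dimnames = dimnames(geno))
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (is.null(target)) target <- rep(FALSE, nrow(geno))
  rr <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(seq_len(nrow(geno)) * 100L, width = 1L),
    ref = "A", alt = "G", target = target)
  SpetGenotypes(rr, geno, depth)
}

# a small AlleleDepthTable from a list of per-base count matrices
toy_depths <- function(counts_by_base, pos, ref, samples = NULL,
                       contig = "chr1") {
  n_site <- length(pos)
  n_samp <- ncol(counts_by_base[[1]])
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n_samp))
  arr <- array(0L, c(n_site, n_samp, 4L),
               dimnames = list(NULL, samples, c("A", "C", "G", "T")))
  for (b in names(counts_by_base))
    arr[, , b] <- as.integer(counts_by_base[[b]])
  sites <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(pos, width = 1L),
                                  ref = ref)
  new("AlleleDepthTable", sites = sites, samples = samples, counts = arr)
}

random_candidates <- function(n, contig_len = 2e6, contigs = "chr1",
                              classes = c("CDS", "intron", "UTR")) {
  ct <- sample(contigs, n, replace = TRUE)
  pos <- sample.int(contig_len, n)
  gr <- GenomicRanges::GRanges(ct, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(gr)$ref <- "A"
  S4Vectors::mcols(gr)$alt <- "G"
  S4Vectors::mcols(gr)$alt_count <- 10L
  S4Vectors::mcols(gr)$maf <- 0.3
  S4Vectors::mcols(gr)$feature_class <- sample(classes, n, replace = TRUE)
  S4Vectors::mcols(gr)$anchored <- TRUE
  gr
}

# brute-force check that a selected SNP set satisfies all pairwise
# spacing constraints (independent of the greedy implementation)
spacing_violations <- function(selected, config) {
  if (length(selected) < 2L) return(0L)
  total <- 0L
  for (ct in unique(as.character(GenomicRanges::seqnames(selected)))) {
    s <- selected[as.character(GenomicRanges::seqnames(selected)) == ct]
    if (length(s) < 2L) next
    pos <- GenomicRanges::start(s)
    cds <- S4Vectors::mcols(s)$feature_class == "CDS"
    dd <- abs(outer(pos, pos, `-`))
    req <- ifelse(outer(cds, cds, `&`), config@spacingCds,
                  config@spacingIntronUtr)
    bad <- dd < req
    diag(bad) <- FALSE
    total <- total + sum(bad) / 2
  }
  as.integer(total)
}

# hand-crafted 20-site x 10-sample table exercising the filter boundaries;
# shared with the acceptance suite
toy_filter_table <- function() {
  n_s <- 10L
  geno <- matrix(0L, 20L, n_s)
  depth <- matrix(50L, 20L, n_s)
  # polymorphism everywhere unless stated: sample 10 carries the alt
  geno[, 10L] <- 2L
  # site 1: mean depth 29.9 -> dropped by min-meanDP 30
  depth[1L, ] <- c(rep(30L, 9L), 29L)
  # site 2: exactly 8/10 called (80% boundary) -> retained
  geno[2L, 1:2] <- NA
  # site 3: 7/10 called -> dropped
  geno[3L, 1:3] <- NA
  # site 4: monomorphic hom-ref -> dropped
  geno[4L, ] <- 0L
  # site 5: mean depth exactly 30 -> retained
  depth[5L, ] <- 30L
  # site 6: all het -> retained (non-ref present)
  geno[6L, ] <- 1L
  # site 7: 9/10 called -> retained under the 80% rule
  geno[7L, 5L] <- NA
  # sites 8..20: clean polymorphic, retained
  list(genotypes = toy_genotypes(geno, depth),
       expected_hc = c(2L, 5L, 6L, 7L, 8:20),
       expected_recall = c(2L, 5L, 6L, 7L, 8:20))
}

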