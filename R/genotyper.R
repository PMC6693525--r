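#' Tally per-base read counts at reference positions
#'
#' Each read contributes one count per covered position to (position,
#' sample, base); read offsets are mapped to reference coordinates through
#' the probe's readout window (reads are stored forward-strand, so the
#' mapping is positional). This replaces alignment: simulated reads carry
#' their probe of origin.
#'
#' @param reads a [ReadBatch].
#' @param panel the [ProbePanel] the reads were generated against.
#' @param genome the [GenomeRef] (for reference bases at covered sites).
#' @return an [AlleleDepthTable].
#' @export
tallyAlleles <- function(reads, panel, genome) {
  r <- as.data.table(readTable(reads))
  probes <- probeRanges(panel)
  samples <- sort(unique(r$accession))
  if (nrow(r)) {
    unknown <- setdiff(unique(r$probe_id), probes$probe_id)
    if (length(unknown))
      stop("read(s) reference probe id(s) absent from the panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  p_dt <- data.table(probe_id = probes$probe_id,
                     contig = as.character(seqnames(probes)),
                     w_start = probes$window_start,
                     w_end = probes$window_end)
  empty <- function() {
    sites <- GRanges(ref = character())
    new("AlleleDepthTable", sites = sites, samples = character(),
        counts = array(0L, c(0L, 0L, 4L),
                       dimnames = list(NULL, NULL, c("A", "C", "G", "T"))))
  }
  if (nrow(r) == 0L) return(empty())
  r <- merge(r, p_dt, by = "probe_id", sort = FALSE)
  rl <- r$w_end - r$w_start + 1L
  stopifnot(all(nchar(r$seq) == rl))
  # expand aggregated reads to per-position base counts
  base_l <- strsplit(r$seq, "")
  expanded <- data.table(
    contig = rep(r$contig, rl),
    pos = unlist(lapply(seq_len(nrow(r)),
                        function(i) seq(r$w_start[i], r$w_end[i]))),
    accession = rep(r$accession, rl),
    base = unlist(base_l),
    n = rep(r$n, rl))
  tal <- expanded[, .(n = sum(n)), by = .(contig, pos, accession, base)]
  sites <- unique(tal[, .(contig, pos)])
  setorder(sites, contig, pos)
  site_key <- paste(sites$contig, sites$pos)
  counts <- array(0L, c(nrow(sites), length(samples), 4L),
                  dimnames = list(NULL, samples, c("A", "C", "G", "T")))
  counts[cbind(match(paste(tal$contig, tal$pos), site_key),
               match(tal$accession, samples),
               match(tal$base, c("A", "C", "G", "T")))] <- tal$n
  seqs <- genomeSequences(genome)
  refb <- vapply(seq_len(nrow(sites)), function(i)
    substr(as.character(
      Biostrings::subseq(seqs[[sites$contig[i]]], sites$pos[i],
                         sites$pos[i])), 1L, 1L), character(1))
  gr <- GRanges(sites$contig, IRanges(sites$pos, width = 1L), ref = refb)
  new("AlleleDepthTable", sites = gr, samples = samples, counts = counts)
}

#' Call a genotype from base counts at one site and sample
#'
#' Let `d` be the total depth and `f` the minor-base fraction (second
#' largest base count over `d`). The call is missing when `d <
#' minDepthCall`; homozygous for the major base when `f <= homMaxFrac`;
#' heterozygous when `hetMinFrac <= f <= hetMaxFrac` and the two top bases
#' are exactly the site's ref and alt alleles; and missing (ambiguous)
#' otherwise.
#'
#' @param counts named integer vector of base counts (`A`, `C`, `G`, `T`).
#' @param ref,alt the site's reference and alternative alleles.
#' @param config a [SpetConfig].
#' @return `"hom-ref"`, `"het"`, `"hom-alt"` or `"missing"`.
#' @export
callGenotype <- function(counts, ref, alt, config = spetConfig()) {
  counts <- counts[c("A", "C", "G", "T")]
  counts[is.na(counts)] <- 0L
  d <- sum(counts)
  if (d < config@minDepthCall) return("missing")
  srt <- sort(counts, decreasing = TRUE)
  f <- srt[2] / d
  if (f <= config@homMaxFrac) {
    major <- names(srt)[1]
    if (major == ref) return("hom-ref")
    if (major == alt) return("hom-alt")
    return("missing")
  }
  if (f >= config@hetMinFrac && f <= config@hetMaxFrac) {
    others <- counts[setdiff(names(counts), c(ref, alt))]
    if (max(others) < min(counts[ref], counts[alt])) return("het")
  }
  "missing"
}

# pick, per row, the count slice of the given base index
.slice_by_row <- function(counts, base_idx) {
  out <- matrix(0L, dim(counts)[1], dim(counts)[2])
  for (b in 1:4) {
    rows <- which(base_idx == b)
    if (length(rows)) out[rows, ] <- counts[rows, , b, drop = FALSE]
  }
  out
}

#' Discover variant sites and build the genotype matrix
#'
#' Every tallied position where at least one sample carries a
#' non-reference base meeting the genotype-call thresholds becomes a site.
#' The site's alternative allele is the most frequent non-reference base
#' summed across samples; sites coinciding with a panel probe's target SNP
#' are flagged `target`, all others `non-target` (accessory discoveries in
#' the readout windows). Genotypes follow [callGenotype()]; samples whose
#' top bases involve a third allele are set to missing and the event is
#' logged.
#'
#' @param depths an [AlleleDepthTable].
#' @param panel the [ProbePanel].
#' @param config a [SpetConfig].
#' @return a [SpetGenotypes].
#' @export
discoverSites <- function(depths, panel, config = spetConfig()) {
  A <- baseCounts(depths)
  sites <- siteRanges(depths)
  samples <- sampleIds(depths)
  S <- length(sites); N <- length(samples)
  empty <- function() {
    rr <- GRanges(ref = character(), alt = character(), target = logical())
    m <- matrix(NA_integer_, 0L, N, dimnames = list(NULL, samples))
    newSpetGenotypes(rr, m, matrix(0L, 0L, N,
                                   dimnames = list(NULL, samples)))
  }
  if (S == 0L || N == 0L) return(empty())
  ref_idx <- match(mcols(sites)$ref, c("A", "C", "G", "T"))
  d <- rowSums(A, dims = 2L)
  v <- lapply(1:4, function(b) A[, , b, drop = TRUE])
  v <- lapply(v, function(m) matrix(m, S, N))
  m1 <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  cnt_max <- (v[[1]] == m1) + (v[[2]] == m1) + (v[[3]] == m1) +
    (v[[4]] == m1)
  masked <- lapply(1:4, function(b) {
    x <- v[[b]]; x[x == m1] <- -1L; x
  })
  second <- pmax(masked[[1]], masked[[2]], masked[[3]], masked[[4]])
  second[cnt_max >= 2L] <- m1[cnt_max >= 2L]
  second[second < 0L] <- 0L
  f <- ifelse(d > 0, second / d, 0)
  c_ref <- .slice_by_row(A, ref_idx)
  deep <- d >= config@minDepthCall

  carrier <- deep & ((f <= config@homMaxFrac & c_ref < m1) |
                     (f >= config@hetMinFrac & f <= config@hetMaxFrac))
  keep <- which(rowSums(carrier) > 0L)
  if (length(keep) == 0L) return(empty())

  # alt allele: most frequent non-reference base across samples
  tot <- vapply(1:4, function(b) rowSums(matrix(v[[b]][keep, ],
                                                length(keep), N)),
                numeric(length(keep)))
  tot <- matrix(tot, length(keep), 4L)
  tot[cbind(seq_along(keep), ref_idx[keep])] <- -1
  alt_idx <- max.col(tot, ties.method = "first")

  sub <- function(m) matrix(m[keep, ], length(keep), N)
  d_k <- sub(d); f_k <- sub(f); m1_k <- sub(m1)
  c_ref_k <- sub(c_ref)
  c_alt_k <- .slice_by_row(A[keep, , , drop = FALSE], alt_idx)
  other_max <- matrix(-1L, length(keep), N)
  for (b in 1:4) {
    rows <- which(ref_idx[keep] != b & alt_idx != b)
    if (length(rows))
      other_max[rows, ] <- pmax(other_max[rows, , drop = FALSE],
                                matrix(v[[b]][keep[rows], ],
                                       length(rows), N))
  }
  geno <- matrix(NA_integer_, length(keep), N,
                 dimnames = list(NULL, samples))
  deep_k <- d_k >= config@minDepthCall
  hom <- deep_k & f_k <= config@homMaxFrac
  geno[hom & c_ref_k == m1_k] <- 0L
  geno[hom & c_ref_k < m1_k & c_alt_k == m1_k] <- 2L
  het_ok <- deep_k & f_k >= config@hetMinFrac & f_k <= config@hetMaxFrac &
    other_max < pmin(c_ref_k, c_alt_k)
  geno[het_ok] <- 1L
  n_third <- sum(deep_k & f_k >= config@hetMinFrac &
                 f_k <= config@hetMaxFrac & !het_ok) +
    sum(hom & c_ref_k < m1_k & c_alt_k < m1_k)
  if (n_third > 0L)
    spetLog(n_third, " genotype(s) involved a third allele; set to missing")

  probes <- probeRanges(panel)
  target_key <- paste(as.character(seqnames(probes)), probes$target_pos)
  site_key <- paste(as.character(seqnames(sites))[keep],
                    start(sites)[keep])
  rr <- GRanges(seqnames(sites)[keep],
                IRanges(start(sites)[keep], width = 1L),
                ref = mcols(sites)$ref[keep],
                alt = c("A", "C", "G", "T")[alt_idx],
                target = site_key %in% target_key)
  newSpetGenotypes(rr, geno, matrix(as.integer(d_k), length(keep), N,
                                    dimnames = list(NULL, samples)))
}

#' High-confidence site filter
#'
#' Keeps sites with (i) mean depth across all samples (zero-depth samples
#' included) of at least `minMeanDepth`, (ii) a fraction of non-missing
#' calls of at least `maxMissing` (vcftools `--max-missing` semantics:
#' larger is stricter), and (iii) at least one non-reference allele among
#' the calls.
#'
#' @param genotypes a [SpetGenotypes].
#' @param config a [SpetConfig].
#' @return the filtered [SpetGenotypes]; per-stage counts are stored in
#'   `metadata(x)$high_confidence_report`.
#' @export
filterHighConfidence <- function(genotypes, config = spetConfig()) {
  g <- genoCalls(genotypes)
  d <- siteDepth(genotypes)
  mean_depth <- rowMeans(d)
  called_frac <- rowMeans(!is.na(g))
  nonref <- rowSums(g > 0L, na.rm = TRUE) >= 1L
  keep <- mean_depth >= config@minMeanDepth &
    called_frac >= config@maxMissing & nonref
  out <- genotypes[keep, ]
  metadata(out)$high_confidence_report <- data.frame(
    total = nrow(g), retained = sum(keep),
    fail_depth = sum(mean_depth < config@minMeanDepth),
    fail_missing = sum(called_frac < config@maxMissing),
    fail_monomorphic = sum(!nonref))
  out
}

#' Re-call genotyping-ratio filter
#'
#' Drops sites where fewer than `genotypingRatio` (default 80%, inclusive
#' at the boundary) of the samples have a callable (non-missing) genotype
#' under the call thresholds.
#'
#' @param genotypes a [SpetGenotypes].
#' @param config a [SpetConfig].
#' @return the filtered [SpetGenotypes]; `metadata(x)$recall_report` holds
#'   `retained`, `total` and the retention fraction.
#' @export
recallFilter <- function(genotypes, config = spetConfig()) {
  g <- genoCalls(genotypes)
  callable <- rowMeans(!is.na(g))
  keep <- callable >= config@genotypingRatio
  out <- genotypes[keep, ]
  metadata(out)$recall_report <- data.frame(
    retained = sum(keep), total = nrow(g),
    retention = if (nrow(g)) sum(keep) / nrow(g) else NA_real_)
  out
}

#' Recall-filter report accessor
#' @param genotypes a [SpetGenotypes] returned by [recallFilter()].
#' @return the report data.frame, or `NULL`.
#' @export
recallReport <- function(genotypes) metadata(genotypes)$recall_report

#' Full genotyping pipeline on simulated reads
#'
#' Convenience wrapper: tally, discover sites, apply the high-confidence
#' and re-call filters.
#'
#' @param reads a [ReadBatch].
#' @param panel the [ProbePanel].
#' @param genome the [GenomeRef].
#' @param config a [SpetConfig].
#' @return a filtered [SpetGenotypes].
#' @export
genotypeReads <- function(reads, panel, genome, config = spetConfig()) {
  depths <- tallyAlleles(reads, panel, genome)
  gm <- discoverSites(depths, panel, config)
  gm <- filterHighConfidence(gm, config)
  recallFilter(gm, config)
}
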