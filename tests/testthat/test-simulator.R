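test_that("reference generation is deterministic and gene models are disjoint", {
  a <- generateReference(nContigs = 1L, contigLength = 60000L,
                         nGenes = 8L, seed = 3L)
  b <- generateReference(nContigs = 1L, contigLength = 60000L,
                         nGenes = 8L, seed = 3L)
  expect_identical(as.character(genomeSequences(a$genome)),
                   as.character(genomeSequences(b$genome)))
  expect_identical(S4Vectors::mcols(a$annotation)$gene_id,
                   S4Vectors::mcols(b$annotation)$gene_id)
  # features of all gene models are mutually non-overlapping
  expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(a$annotation))),
               sum(GenomicRanges::width(a$annotation)))
  expect_equal(length(unique(S4Vectors::mcols(a$annotation)$gene_id)), 8L)
})

test_that("zero gene density yields an empty annotation", {
  r <- generateReference(nContigs = 1L, contigLength = 20000L,
                         nGenes = 0L, seed = 1L)
  expect_length(r$annotation, 0L)
  pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100L, width = 1L))
  expect_equal(classifyFeature(pos, r$annotation), "intergenic")
})

test_that("infeasible gene geometry is rejected", {
  expect_error(generateReference(nContigs = 1L, contigLength = 3000L,
                                 nGenes = 10L, seed = 1L),
               "infeasible")
})

test_that("divergence 0 and diversity 0 reproduce the reference exactly", {
  ref <- generateReference(nContigs = 1L, contigLength = 30000L,
                           nGenes = 0L, seed = 2L)$genome
  germ <- simulateGermplasm(ref, speciesSpec("ctrl", 0, 20L, 2L, 0),
                            seed = 4L)
  expect_equal(nrow(variantTable(germ)), 0L)
  truth <- truthGenotypes(germ)
  expect_equal(nrow(truth), 0L)
})

test_that("selfing erodes heterozygosity by halves per generation", {
  ref <- generateReference(nContigs = 1L, contigLength = 200000L,
                           nGenes = 0L, seed = 5L)$genome
  het_frac <- function(g, seed) {
    germ <- simulateGermplasm(
      ref, speciesSpec("sp", 0, g, 1L, diversity = 0.02), seed = seed)
    v <- variantTable(germ)
    sum(v$h1 != v$h2)
  }
  h0 <- het_frac(0L, 11L)
  h1 <- het_frac(1L, 12L)
  h20 <- het_frac(20L, 13L)
  # one generation leaves ~1/2 the het sites, twenty leaves ~2^-20
  expect_gt(h0, 2000)
  expect_lt(abs(h1 / h0 - 0.5), 0.1)
  expect_lt(h20 / h0, 0.01)
})

test_that("backbone divergence scales mean distance from the reference", {
  ref <- generateReference(nContigs = 1L, contigLength = 100000L,
                           nGenes = 0L, seed = 6L)$genome
  diffs <- vapply(1:8, function(s) {
    germ <- simulateGermplasm(
      ref, rbind(speciesSpec("lo", 0.005, 0L, 1L, 0),
                 speciesSpec("hi", 0.030, 0L, 1L, 0)), seed = 100L + s)
    v <- variantTable(germ)
    lo <- sum(v$accession == "lo_01")
    hi <- sum(v$accession == "hi_01")
    c(lo, hi)
  }, numeric(2))
  expect_gt(mean(diffs[2, ]), mean(diffs[1, ]))
  # Poisson means 500 vs 3000: 3 standard errors apart by far
  expect_gt(mean(diffs[2, ]) - mean(diffs[1, ]),
            3 * sqrt(3000 / 8 + 500 / 8))
})

test_that("biallelic consistency holds across species at shared positions", {
  fx <- spet_fixture()
  v <- variantTable(fx$germplasm)
  per_pos <- tapply(v$alt, paste(v$contig, v$pos),
                    function(x) length(unique(x)))
  expect_true(all(per_pos == 1L))
})

test_that("fixed depth with no hybridization failure yields full coverage", {
  fx <- spet_fixture()
  one <- referenceAccessions(fx$genome, "ctrl")
  reads <- simulateReads(fx$panel, one, seed = 21L, meanDepth = 17,
                         lambda = 0, epsilon = 0, depthModel = "fixed")
  r <- readTable(reads)
  per_probe <- tapply(r$n, r$probe_id, sum)
  expect_equal(length(per_probe), length(probeIds(fx$panel)))
  expect_true(all(per_probe == 17L))
  expect_true(all(r$n_errors == 0L))
})

test_that("per-read hybridization success follows (1 - lambda)^mismatches", {
  ref <- GenomeRef(c(chr1 = strrep("ACGT", 500)))  # 2 kb
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 140L))
  S4Vectors::mcols(probes) <- S4Vectors::DataFrame(
    probe_id = "p1", orientation = "readout-right", target_pos = 141L,
    sequence = substr(strrep("ACGT", 500), 101, 140),
    window_start = 141L, window_end = 250L, feature_class = "CDS")
  panel <- new("ProbePanel", probes = probes, probeLength = 40L,
               targetWindow = 25L, readoutLength = 110L)
  # accession with two homozygous mismatches inside the probe footprint
  acc <- new("GermplasmSet", reference = ref,
             accessions = data.frame(accession = "a1", species = "s",
                                     divergence = 0,
                                     selfing_generations = 0L),
             variants = data.frame(accession = "a1", contig = "chr1",
                                   pos = c(110L, 120L), ref = c("C", "T"),
                                   alt = c("A", "A"), h1 = 1L, h2 = 1L))
  n <- 2000L
  reads <- simulateReads(panel, acc, seed = 33L, meanDepth = n,
                         lambda = 0.3, epsilon = 0, depthModel = "fixed")
  surv <- sum(readTable(reads)$n)
  p <- (1 - 0.3)^2  # 0.49
  expect_lt(abs(surv - n * p), 4 * sqrt(n * p * (1 - p)))
})

test_that("sequencing errors are injected at the configured rate", {
  fx <- spet_fixture()
  one <- referenceAccessions(fx$genome, "ctrl")
  reads <- simulateReads(fx$panel, one, seed = 22L, meanDepth = 40,
                         lambda = 0, epsilon = 5e-3, depthModel = "fixed")
  r <- readTable(reads)
  total_bases <- sum(r$n * nchar(r$seq))
  err <- sum(r$n_errors * r$n)
  expect_gt(err, 0)
  expect_lt(abs(err / total_bases - 5e-3), 2e-3)
})

test_that("read length is truncated at the contig edge", {
  ref <- GenomeRef(c(chr1 = strrep("ACGT", 100)))  # 400 bp
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301L, 340L))
  S4Vectors::mcols(probes) <- S4Vectors::DataFrame(
    probe_id = "p1", orientation = "readout-right", target_pos = 341L,
    sequence = substr(strrep("ACGT", 100), 301, 340),
    window_start = 341L, window_end = 400L, feature_class = "CDS")
  panel <- new("ProbePanel", probes = probes, probeLength = 40L,
               targetWindow = 25L, readoutLength = 110L)
  reads <- simulateReads(panel, referenceAccessions(ref, "c"),
                         seed = 1L, meanDepth = 5, lambda = 0,
                         epsilon = 0, depthModel = "fixed")
  expect_true(all(nchar(readTable(reads)$seq) == 60L))
})

test_that("missingness grows with divergence from the reference", {
  # reduced-scale gradient check (the full 20-seed ladder runs in the
  # acceptance suite)
  fx <- spet_fixture()
  acc <- accessionTable(fx$germplasm)
  run <- spet_run()
  st <- accessionStats(run$gm)
  st$divergence <- acc$divergence[match(st$accession, acc$accession)]
  agg <- aggregate(missing_pct ~ divergence, st, mean)
  expect_gt(agg$missing_pct[nrow(agg)], agg$missing_pct[1])
})

test_that("fixture directories are reproducible and self-checking", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- makeFixture(d1, seed = 17L, nContigs = 1L,
                    contigLength = 120000L, nGenes = 15L, fastq = FALSE)
  m2 <- makeFixture(d2, seed = 17L, nContigs = 1L,
                    contigLength = 120000L, nGenes = 15L, fastq = FALSE)
  expect_identical(m1$md5, m2$md5)
  expect_true(checkFixture(d1))
  # files parse back through the readers
  g <- readGenome(file.path(d1, "reference.fasta"))
  expect_s4_class(g, "GenomeRef")
  ann <- readAnnotation(file.path(d1, "annotation.gff3"))
  expect_true(all(ann$class %in% c("CDS", "intron", "UTR")))
  cands <- readCandidateVcf(file.path(d1, "candidates.vcf"))
  expect_gt(length(cands), 0L)
})

test_that("ascertainment hides wild-only variants from the candidate set", {
  fx <- spet_fixture()
  acc <- accessionTable(fx$germplasm)
  crop_only <- ascertainCandidates(
    fx$germplasm, acc$accession[acc$species == "crop"])
  truth <- truthGenotypes(fx$germplasm)
  rr <- SummarizedExperiment::rowRanges(truth)
  truth_key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr))
  cand_key <- paste(GenomicRanges::seqnames(crop_only),
                    GenomicRanges::start(crop_only))
  # candidates are a strict subset of truth: wild-only variants missing
  expect_true(all(cand_key %in% truth_key))
  wild_cols <- acc$accession[acc$species != "crop"]
  g <- genoCalls(truth)
  wild_only <- truth_key[rowSums(g[, wild_cols, drop = FALSE]) > 0 &
                         rowSums(g[, setdiff(colnames(g), wild_cols),
                                   drop = FALSE]) == 0]
  expect_gt(length(wild_only), 0L)
  expect_false(any(wild_only %in% cand_key))
})

test_that("annotation written as GFF3 reads back identically", {
  fx <- spet_fixture()
  f <- tempfile(fileext = ".gff3")
  writeAnnotationGff3(fx$annotation, f)
  back <- readAnnotation(f)
  orig <- sort(fx$annotation)
  expect_equal(length(back), length(orig))
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(orig))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(orig))
  expect_identical(S4Vectors::mcols(back)$class,
                   S4Vectors::mcols(orig)$class)
})
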