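ref400 <- strrep("ACGT", 100)

tiny_panel <- function() {
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 140L))
  S4Vectors::mcols(probes) <- S4Vectors::DataFrame(
    probe_id = "p1", orientation = "readout-right", target_pos = 141L,
    sequence = substr(ref400, 101, 140),
    window_start = 141L, window_end = 250L, feature_class = "CDS")
  new("ProbePanel", probes = probes, probeLength = 40L,
      targetWindow = 25L, readoutLength = 110L)
}

tiny_batch <- function(rows) {
  new("ReadBatch", reads = rows, readoutLength = 110L)
}

tiny_genome <- GenomeRef(c(chr1 = ref400))

test_that("one read contributes one count at each covered position", {
  win_seq <- substr(ref400, 141, 250)
  reads <- tiny_batch(data.frame(
    probe_id = "p1", accession = "a1", haplotype = 1L, seq = win_seq,
    n = 1L, n_errors = 0L))
  tab <- tallyAlleles(reads, tiny_panel(), tiny_genome)
  expect_length(siteRanges(tab), 110L)
  expect_equal(sum(baseCounts(tab)), 110L)
  d <- rowSums(baseCounts(tab), dims = 2)
  expect_true(all(d == 1L))
  # every counted base equals the reference at that position
  ref_b <- S4Vectors::mcols(siteRanges(tab))$ref
  hit <- baseCounts(tab)[cbind(seq_len(110), 1L,
                               match(ref_b, c("A", "C", "G", "T")))]
  expect_true(all(hit == 1L))
})

test_that("disagreeing reads split counts at the divergent offset", {
  win_seq <- substr(ref400, 141, 250)
  mut <- win_seq
  substr(mut, 30, 30) <- "T"  # reference base at offset 30 is not T
  expect_false(substr(win_seq, 30, 30) == "T")
  reads <- tiny_batch(data.frame(
    probe_id = "p1", accession = "a1", haplotype = c(1L, 2L),
    seq = c(win_seq, mut), n = 1L, n_errors = 0L))
  tab <- tallyAlleles(reads, tiny_panel(), tiny_genome)
  at <- which(GenomicRanges::start(siteRanges(tab)) == 170L)  # 141+29
  cnt <- baseCounts(tab)[at, 1L, ]
  expect_equal(sort(cnt[cnt > 0]), c(1L, 1L), ignore_attr = TRUE)
})

test_that("empty batches tally to an empty table", {
  reads <- tiny_batch(data.frame(
    probe_id = character(), accession = character(),
    haplotype = integer(), seq = character(), n = integer(),
    n_errors = integer()))
  tab <- tallyAlleles(reads, tiny_panel(), tiny_genome)
  expect_length(siteRanges(tab), 0L)
})

test_that("reads from unknown probes are rejected", {
  reads <- tiny_batch(data.frame(
    probe_id = "ghost", accession = "a1", haplotype = 1L,
    seq = strrep("A", 110), n = 1L, n_errors = 0L))
  expect_error(tallyAlleles(reads, tiny_panel(), tiny_genome), "ghost")
})

test_that("genotype calls follow the depth and allele-balance rules", {
  cfg <- spetConfig()
  cnt <- function(A = 0, C = 0, G = 0, T = 0)
    c(A = A, C = C, G = G, T = T)
  expect_equal(callGenotype(cnt(A = 12), "A", "G", cfg), "hom-ref")
  expect_equal(callGenotype(cnt(A = 9), "A", "G", cfg), "missing")
  expect_equal(callGenotype(cnt(A = 12, G = 8), "A", "G", cfg), "het")
  expect_equal(callGenotype(cnt(G = 12), "A", "G", cfg), "hom-alt")
  # minor fraction between hom and het windows is ambiguous
  expect_equal(callGenotype(cnt(A = 18, G = 2), "A", "G", cfg), "missing")
  # a third allele cannot be called
  expect_equal(callGenotype(cnt(T = 12), "A", "G", cfg), "missing")
  expect_equal(callGenotype(cnt(A = 10, T = 10), "A", "G", cfg),
               "missing")
  # 4% minor fraction is still homozygous (inclusive)
  expect_equal(callGenotype(cnt(A = 96, G = 4), "A", "G", cfg), "hom-ref")
})

test_that("site discovery separates target and accessory SNPs", {
  cfg <- spetConfig()
  # 3 samples; variant at the target position 141 and another at 170
  pos <- c(141L, 170L, 200L)
  refb <- c("A", "C", "G")
  zero <- matrix(0L, 3, 3)
  A <- rbind(c(30, 30, 0), c(0, 0, 0), c(0, 0, 0))
  C <- rbind(c(0, 0, 0), c(30, 15, 30), c(0, 0, 0))
  G <- rbind(c(0, 0, 30), c(0, 15, 0), c(30, 30, 30))
  tab <- toy_depths(list(A = A, C = C, G = G, T = zero), pos, refb)
  gm <- discoverSites(tab, tiny_panel(), cfg)
  expect_equal(nrow(gm), 2L)
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(gm)),
               c(141L, 170L))
  expect_equal(isTargetSite(gm), c(TRUE, FALSE))
  expect_equal(unname(genoCalls(gm)[1, ]), c(0L, 0L, 2L))
  expect_equal(unname(genoCalls(gm)[2, ]), c(0L, 1L, 0L))
})

test_that("sites with no non-reference base produce an empty matrix", {
  tab <- toy_depths(list(A = matrix(30L, 2, 2)), c(141L, 142L),
                    c("A", "A"))
  gm <- discoverSites(tab, tiny_panel(), spetConfig())
  expect_equal(nrow(gm), 0L)
})

test_that("triallelic positions keep the two most frequent alleles", {
  cfg <- spetConfig()
  # ref A; sample 1 and 2 hom G (most frequent alt), sample 3 hom T
  A <- matrix(0L, 1, 3)
  G <- matrix(c(30L, 30L, 0L), 1, 3)
  T <- matrix(c(0L, 0L, 30L), 1, 3)
  tab <- toy_depths(list(A = A, G = G, T = T), 150L, "A")
  gm <- discoverSites(tab, tiny_panel(), cfg)
  expect_equal(nrow(gm), 1L)
  expect_equal(S4Vectors::mcols(
    SummarizedExperiment::rowRanges(gm))$alt, "G")
  expect_equal(unname(genoCalls(gm)[1, ]), c(2L, 2L, NA))
})

test_that("high-confidence and re-call filters retain the hand-computed set", {
  toy <- toy_filter_table()
  cfg <- spetConfig("tomato-like")  # max-missing 0.80
  hc <- filterHighConfidence(toy$genotypes, cfg)
  expect_equal(
    GenomicRanges::start(SummarizedExperiment::rowRanges(hc)),
    GenomicRanges::start(
      SummarizedExperiment::rowRanges(toy$genotypes))[toy$expected_hc])
  rc <- recallFilter(hc, cfg)
  expect_equal(nrow(rc), length(toy$expected_recall))
  rep <- recallReport(rc)
  expect_equal(rep$retained, nrow(rc))
  expect_equal(rep$retention, 1)
})

test_that("the eggplant-like missingness threshold is stricter", {
  toy <- toy_filter_table()
  hc <- filterHighConfidence(toy$genotypes, spetConfig("eggplant-like"))
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(hc)) / 100L
  # 0.95 max-missing drops the 8/10 and 9/10 sites as well
  expect_false(any(c(2L, 3L, 7L) %in% pos))
  expect_true(5L %in% pos)
})

test_that("filters are idempotent and counts monotone", {
  run <- spet_run()
  cfg <- run$fx$config
  hc1 <- filterHighConfidence(run$gm, cfg)
  hc2 <- filterHighConfidence(hc1, cfg)
  expect_equal(nrow(hc1), nrow(hc2))
  expect_identical(genoCalls(hc1), genoCalls(hc2))
  rc1 <- recallFilter(hc1, cfg)
  rc2 <- recallFilter(rc1, cfg)
  expect_equal(nrow(rc1), nrow(rc2))
  expect_true(nrow(run$gm) >= nrow(hc1))
  expect_true(nrow(hc1) >= nrow(rc1))
})

test_that("target sites form a subset of panel target positions", {
  run <- spet_run()
  rr <- SummarizedExperiment::rowRanges(run$gm)
  targets <- rr[S4Vectors::mcols(rr)$target]
  probes <- probeRanges(run$fx$panel)
  expect_lte(length(targets), length(probes))
  tkey <- paste(GenomicRanges::seqnames(targets),
                GenomicRanges::start(targets))
  pkey <- paste(GenomicRanges::seqnames(probes), probes$target_pos)
  expect_true(all(tkey %in% pkey))
})

test_that("error-free reads at full depth recover the simulated truth", {
  fx <- spet_fixture()
  reads <- simulateReads(fx$panel, fx$germplasm, seed = 41L,
                         meanDepth = 30, lambda = 0, epsilon = 0,
                         depthModel = "fixed")
  depths <- tallyAlleles(reads, fx$panel, fx$genome)
  gm <- discoverSites(depths, fx$panel, fx$config)
  truth <- truthGenotypes(fx$germplasm)
  rr_t <- SummarizedExperiment::rowRanges(truth)
  truth_key <- paste(GenomicRanges::seqnames(rr_t),
                     GenomicRanges::start(rr_t))
  rr_g <- SummarizedExperiment::rowRanges(gm)
  called_key <- paste(GenomicRanges::seqnames(rr_g),
                      GenomicRanges::start(rr_g))
  tgt <- which(S4Vectors::mcols(rr_g)$target)
  idx <- match(called_key[tgt], truth_key)
  expect_false(any(is.na(idx)))
  g_called <- genoCalls(gm)[tgt, colnames(genoCalls(truth))]
  g_truth <- genoCalls(truth)[idx, ]
  ok <- is.na(g_called) | g_called == g_truth
  expect_true(all(ok))
  expect_gt(mean(!is.na(g_called)), 0.99)
})
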