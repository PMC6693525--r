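ann_toy <- local({
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(100L, 150L, 300L, 400L),
                     c(200L, 250L, 350L, 500L)),
    class = c("CDS", "UTR", "intron", "CDS"),
    gene_id = "g1")
  gr
})

test_that("feature classification follows CDS > UTR > intron priority", {
  pos <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(160L, 230L, 320L, 900L), width = 1L))
  expect_equal(classifyFeature(pos, ann_toy),
               c("CDS", "UTR", "intron", "intergenic"))
})

test_that("classification errors on contigs absent from the genome", {
  g <- GenomeRef(c(chr1 = strrep("A", 100)))
  pos <- GenomicRanges::GRanges("chrX", IRanges::IRanges(5L, width = 1L))
  expect_error(classifyFeature(pos, ann_toy, g), "chrX")
})

cand <- function(alt_count, maf = 0.3, feature = "CDS", anchored = TRUE,
                 pos = NULL) {
  n <- length(alt_count)
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos %||% (seq_len(n) * 1000L), width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = "A", alt = "G", alt_count = as.integer(alt_count),
    maf = rep_len(maf, n), feature_class = rep_len(feature, n),
    anchored = rep_len(anchored, n))
  gr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tomato-like eligibility uses a strict alt-count threshold", {
  snps <- cand(c(8L, 9L))
  kept <- filterEligible(snps, spetConfig("tomato-like"))
  expect_equal(kept$alt_count, 9L)
})

test_that("eggplant-like eligibility combines count and MAF rules", {
  cfg <- spetConfig("eggplant-like")
  expect_length(filterEligible(cand(4L, maf = 0.30), cfg), 1L)
  expect_length(filterEligible(cand(4L, maf = 0.25), cfg), 0L)  # strict
  expect_length(filterEligible(cand(3L, maf = 0.30), cfg), 0L)
})

test_that("unanchored and intergenic candidates are dropped", {
  expect_length(filterEligible(cand(20L, anchored = FALSE)), 0L)
  expect_length(filterEligible(cand(20L, feature = "intergenic")), 0L)
})

test_that("spacing keeps CDS pairs at exactly 5 kbp and drops closer ones", {
  cfg <- spetConfig()
  two <- cand(c(10L, 10L), pos = c(1000L, 6000L))
  expect_length(enforceSpacing(two, cfg), 2L)
  close <- cand(c(10L, 10L), pos = c(1000L, 5999L))
  expect_equal(GenomicRanges::start(enforceSpacing(close, cfg)), 1000L)
})

test_that("intron/UTR SNPs need 15 kbp even against CDS SNPs", {
  cfg <- spetConfig()
  snps <- cand(c(10L, 10L), pos = c(1000L, 11000L))
  S4Vectors::mcols(snps)$feature_class <- c("CDS", "intron")
  kept <- enforceSpacing(snps, cfg)
  expect_equal(kept$feature_class, "CDS")
  far <- cand(c(10L, 10L), pos = c(1000L, 16000L))
  S4Vectors::mcols(far)$feature_class <- c("CDS", "intron")
  expect_length(enforceSpacing(far, cfg), 2L)
})

test_that("contigs are spaced independently", {
  gr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                               IRanges::IRanges(c(1000L, 1500L), width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = "A", alt = "G", alt_count = 10L, maf = 0.3,
    feature_class = "CDS", anchored = TRUE)
  expect_length(enforceSpacing(gr, spetConfig()), 2L)
})

test_that("greedy spacing is valid and maximal on random instances", {
  cfg <- spetConfig()
  set.seed(31)
  for (i in 1:30) {
    snps <- random_candidates(sample(50:400, 1))
    sel <- enforceSpacing(snps, cfg)
    expect_identical(spacing_violations(sel, cfg), 0L)
    # maximality: every rejected SNP conflicts with the selection
    sel_key <- paste(GenomicRanges::seqnames(sel),
                     GenomicRanges::start(sel))
    rej <- snps[!paste(GenomicRanges::seqnames(snps),
                       GenomicRanges::start(snps)) %in% sel_key]
    for (k in seq_along(rej)) {
      expect_gt(spacing_violations(c(sel, rej[k]), cfg), 0L)
    }
  }
})

test_that("random-order spacing selection is seed-reproducible and valid", {
  cfg <- spetConfig(seed = 42L)
  set.seed(99)
  snps <- random_candidates(300)
  a <- enforceSpacing(snps, cfg, order = "random")
  b <- enforceSpacing(snps, cfg, order = "random")
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(spacing_violations(a, cfg), 0L)
})

test_that("probes sit immediately left of a readout-right target", {
  set.seed(5)
  g <- GenomeRef(c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000,
                                       replace = TRUE), collapse = "")))
  snp <- cand(10L, pos = 1000L)
  pr <- designProbe(snp, g)
  expect_equal(GenomicRanges::start(pr), 960L)
  expect_equal(GenomicRanges::end(pr), 999L)
  expect_equal(pr$orientation, "readout-right")
  expect_equal(spetkit:::probeTargetOffset(pr), 1L)
  expect_equal(pr$sequence,
               substr(as.character(genomeSequences(g)[["chr1"]]),
                      960, 999))
  expect_equal(c(pr$window_start, pr$window_end), c(1000L, 1109L))
})

test_that("near-edge SNPs use the feasible side or fail", {
  set.seed(6)
  g <- GenomeRef(c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000,
                                       replace = TRUE), collapse = "")))
  pr <- designProbe(cand(10L, pos = 20L), g)  # no left flank for a probe
  expect_equal(pr$orientation, "readout-left")
  expect_equal(GenomicRanges::start(pr), 21L)
  expect_equal(pr$window_start, 1L)  # readout truncated at contig edge
  # SNP on a contig too short for either side
  tiny <- GenomeRef(c(c1 = strrep("ACGT", 10)))
  snp <- GenomicRanges::GRanges("c1", IRanges::IRanges(20L, width = 1L))
  S4Vectors::mcols(snp) <- S4Vectors::DataFrame(
    ref = "A", alt = "G", alt_count = 10L, maf = 0.3,
    feature_class = "CDS", anchored = TRUE)
  expect_null(designProbe(snp, tiny))
})

test_that("probes containing reference N are rejected", {
  g <- GenomeRef(c(chr1 = paste0(strrep("N", 60), strrep("ACGT", 50))))
  snp <- cand(10L, pos = 100L)  # left flank [60,99] contains N
  pr <- designProbe(snp, g)
  expect_equal(pr$orientation, "readout-left")
  g2 <- GenomeRef(c(chr1 = paste0(strrep("N", 60), strrep("ACGT", 10),
                                  strrep("N", 100))))
  expect_null(designProbe(cand(10L, pos = 100L), g2))
})

test_that("the target-window validator is inclusive at 25 bp", {
  probe_at <- function(off) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(960L, 999L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      probe_id = "p", orientation = "readout-right",
      target_pos = 999L + off, sequence = strrep("A", 40),
      window_start = 1000L, window_end = 1109L, feature_class = "CDS")
    gr
  }
  cfg <- spetConfig()
  expect_true(validateProbeWindow(probe_at(1L), cfg))
  expect_true(validateProbeWindow(probe_at(25L), cfg))
  expect_false(validateProbeWindow(probe_at(26L), cfg))
})

test_that("pilot coverage filtering matches the published rules", {
  probes <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(100L, 200L), width = 40L))
  S4Vectors::mcols(probes) <- S4Vectors::DataFrame(
    probe_id = c("p1", "p2"), orientation = "readout-right",
    target_pos = c(140L, 240L), sequence = strrep("A", 40),
    window_start = c(141L, 241L), window_end = c(250L, 350L),
    feature_class = "CDS")
  tomato <- spetConfig("tomato-like")
  # mean exactly 46, no low samples: retained (inclusive bound)
  cov <- rbind(p1 = rep(46, 24), p2 = rep(60, 24))
  expect_equal(pilotCoverageFilter(probes, cov, tomato)$probe_id,
               c("p1", "p2"))
  # four samples at depth five ("five or less") is one too many
  cov2 <- rbind(p1 = c(rep(5, 4), rep(80, 20)), p2 = rep(60, 24))
  expect_equal(pilotCoverageFilter(probes, cov2, tomato)$probe_id, "p2")
  egg <- spetConfig("eggplant-like")
  # eggplant counts depths strictly below 5; two such samples pass
  cov3 <- rbind(p1 = c(4, 4, rep(100, 22)), p2 = rep(100, 24))
  expect_equal(pilotCoverageFilter(probes, cov3, egg)$probe_id,
               c("p1", "p2"))
  cov4 <- rbind(p1 = c(4, 4, 4, rep(100, 21)), p2 = rep(100, 24))
  expect_equal(pilotCoverageFilter(probes, cov4, egg)$probe_id, "p2")
  expect_error(pilotCoverageFilter(probes, cov3[1, , drop = FALSE], egg),
               "p2")
})

test_that("panel design stage counts are monotone and seed-reproducible", {
  fx <- spet_fixture()
  expect_true(all(diff(fx$report$count) <= 0))
  des2 <- designPanel(fx$candidates, fx$genome, fx$annotation,
                      config = fx$config)
  expect_identical(probeIds(des2$panel), probeIds(fx$panel))
  # down-sampling to a target size under the seed
  n_cap <- max(1L, length(probeRanges(fx$panel)) - 5L)
  des3 <- designPanel(fx$candidates, fx$genome, fx$annotation,
                      config = fx$config, targetSize = n_cap)
  expect_length(probeRanges(des3$panel), n_cap)
  expect_true(all(probeIds(des3$panel) %in% probeIds(fx$panel)))
})

test_that("every probe sequence re-extracts exactly from the reference", {
  fx <- spet_fixture()
  p <- probeRanges(fx$panel)
  seqs <- genomeSequences(fx$genome)
  for (ct in unique(as.character(GenomicRanges::seqnames(p)))) {
    idx <- as.character(GenomicRanges::seqnames(p)) == ct
    ref_str <- as.character(seqs[[ct]])
    expect_identical(
      p$sequence[idx],
      substring(ref_str, GenomicRanges::start(p)[idx],
                GenomicRanges::end(p)[idx]))
  }
})
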