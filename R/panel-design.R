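#' Classify genomic positions against a gene annotation
#'
#' A position is `CDS` if it overlaps any CDS feature, else `UTR` if it
#' overlaps any UTR, else `intron` if it overlaps any derived intron, else
#' `intergenic`.
#'
#' @param pos a [GenomicRanges::GRanges] of positions (width 1 or wider;
#'   any overlap counts).
#' @param annotation annotation [GenomicRanges::GRanges] from
#'   [readAnnotation()].
#' @param genome optional [GenomeRef]; when supplied, positions on contigs
#'   absent from the genome raise an error.
#' @return character vector of feature classes, one per position.
#' @export
classifyFeature <- function(pos, annotation, genome = NULL) {
  if (!is.null(genome)) {
    unknown <- setdiff(unique(as.character(seqnames(pos))),
                       names(genomeSequences(genome)))
    if (length(unknown))
      stop("unknown contig(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  out <- rep("intergenic", length(pos))
  if (length(annotation) == 0L || length(pos) == 0L) return(out)
  for (cls in c("intron", "UTR", "CDS")) {  # ascending priority
    feat <- annotation[mcols(annotation)$class == cls]
    if (length(feat)) {
      hit <- IRanges::overlapsAny(pos, feat, ignore.strand = TRUE)
      out[hit] <- cls
    }
  }
  out
}

#' Filter candidate SNPs for panel eligibility
#'
#' Tomato-like mode keeps SNPs with an alternative cohort-wise allele
#' count strictly greater than 8; eggplant-like mode keeps SNPs with an
#' alternative allele count of at least 4 and a minor allele frequency
#' greater than 0.25. Both modes require anchored contigs and drop
#' intergenic SNPs. Input order is preserved.
#'
#' @param snps candidate-SNP [GenomicRanges::GRanges] with metadata
#'   columns `alt_count`, `maf`, `feature_class`, `anchored`.
#' @param config a [SpetConfig].
#' @return the eligible subset, in input order.
#' @export
filterEligible <- function(snps, config = spetConfig()) {
  if (length(snps) == 0L) return(snps)
  m <- mcols(snps)
  keep <- !is.na(m$anchored) & m$anchored &
    !is.na(m$feature_class) & m$feature_class != "intergenic" &
    m$alt_count >= config@minAltCount
  if (!is.na(config@minMaf))
    keep <- keep & !is.na(m$maf) & m$maf > config@minMaf
  out <- snps[keep]
  if (length(out) == 0L) spetLog("no SNPs survived eligibility filtering")
  out
}

# Minimum distance required between two selected SNPs given their classes:
# the stricter 15 kbp applies whenever either member is intron/UTR.
requiredSpacing <- function(classA, classB, config) {
  ifelse(classA == "CDS" & classB == "CDS",
         config@spacingCds, config@spacingIntronUtr)
}

#' Enforce minimum spacing between selected SNPs
#'
#' Selects a subset such that every same-contig pair (a, b) satisfies
#' `|pos(a) - pos(b)| >= required(a, b)`, where the requirement is 5 kbp
#' for a CDS-CDS pair and 15 kbp whenever either member is an intron/UTR
#' SNP. Selection is greedy: by default left-to-right within each contig
#' (CDS given priority at equal positions); `order = "random"` processes
#' candidates in a seed-determined random order instead, echoing a
#' randomised panel selection. The result is maximal with respect to the
#' processing order: every rejected SNP conflicts with at least one
#' selected SNP.
#'
#' @param snps eligible candidate [GenomicRanges::GRanges] with a
#'   `feature_class` metadata column (classes `CDS`, `intron`, `UTR`).
#' @param config a [SpetConfig].
#' @param order `"position"` (default) or `"random"`.
#' @return the selected subset, sorted by (contig, position).
#' @export
enforceSpacing <- function(snps, config = spetConfig(),
                           order = c("position", "random")) {
  order <- match.arg(order)
  if (length(snps) <= 1L) return(snps)
  contig <- as.character(seqnames(snps))
  pos <- start(snps)
  cls <- mcols(snps)$feature_class
  is_cds <- cls == "CDS"
  if (order == "position") {
    # CDS first at equal positions
    o <- order(contig, pos, !is_cds)
  } else {
    o <- withSeed(deriveSeed(config@seed, 7L), sample.int(length(snps)))
  }
  keep <- logical(length(snps))
  sel <- list()  # per contig: list(pos=, cds=)
  for (i in o) {
    ct <- contig[i]
    s <- sel[[ct]]
    ok <- TRUE
    if (!is.null(s) && length(s$pos)) {
      req <- ifelse(is_cds[i] & s$cds, config@spacingCds,
                    config@spacingIntronUtr)
      ok <- all(abs(pos[i] - s$pos) >= req)
    }
    if (ok) {
      keep[i] <- TRUE
      sel[[ct]] <- list(pos = c(s$pos, pos[i]), cds = c(s$cds, is_cds[i]))
    }
  }
  sort(snps[keep])
}

# Candidate probe placements for one side; returns NULL when infeasible.
.probe_side <- function(p, contig_len, side, config) {
  L <- config@probeLength
  R <- config@readoutLength
  if (side == "readout-right") {
    if (p - L < 1L) return(NULL)
    list(start = p - L, end = p - 1L, orientation = side,
         wstart = p, wend = min(p + R - 1L, contig_len),
         full = (p + R - 1L) <= contig_len)
  } else {
    if (p + L > contig_len) return(NULL)
    list(start = p + 1L, end = p + L, orientation = side,
         wstart = max(p - R + 1L, 1L), wend = p,
         full = (p - R + 1L) >= 1L)
  }
}

#' Design a probe adjacent to a target SNP
#'
#' Places a probe of `probeLength` reference bases immediately adjacent to
#' the SNP (so the target lies at offset 1 from the probe 3' end), on the
#' side chosen by: (1) prefer a side whose full readout window stays
#' on-contig; (2) among equally feasible sides, prefer the probe GC
#' fraction nearest 0.5; (3) finally prefer `readout-right`. Probes whose
#' reference sequence contains `N` are rejected. The readout window is
#' recorded truncated at the contig edge.
#'
#' @param snp a single-row candidate [GenomicRanges::GRanges] (metadata
#'   `feature_class` used if present).
#' @param genome a [GenomeRef].
#' @param config a [SpetConfig].
#' @return a single-probe [GenomicRanges::GRanges] (the `probes` layout of
#'   [ProbePanel]), or `NULL` when neither side is feasible.
#' @export
designProbe <- function(snp, genome, config = spetConfig()) {
  stopifnot(length(snp) == 1L)
  res <- designProbes(snp, genome, config)
  if (length(res) == 0L) NULL else res
}

# Vectorised probe design over many SNPs; returns a probes GRanges
# (possibly shorter than input; failures are logged).
designProbes <- function(snps, genome, config = spetConfig()) {
  seqs <- genomeSequences(genome)
  rows <- vector("list", length(snps))
  contig <- as.character(seqnames(snps))
  pos <- start(snps)
  cls <- mcols(snps)$feature_class %||% rep(NA_character_, length(snps))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  chars <- new.env(parent = emptyenv())  # lazily cached contig strings
  getseq <- function(ct, a, b) {
    if (is.null(chars[[ct]])) chars[[ct]] <- as.character(seqs[[ct]])
    substr(chars[[ct]], a, b)
  }
  n_fail <- 0L
  for (i in seq_along(snps)) {
    ct <- contig[i]
    cands <- list()
    for (side in c("readout-right", "readout-left")) {
      cand <- .probe_side(pos[i], lens[[ct]], side, config)
      if (is.null(cand)) next
      cand$seq <- getseq(ct, cand$start, cand$end)
      if (grepl("N", cand$seq, fixed = TRUE)) next
      cands[[length(cands) + 1L]] <- cand
    }
    if (length(cands) == 0L) { n_fail <- n_fail + 1L; next }
    if (length(cands) == 2L) {
      full <- vapply(cands, `[[`, logical(1), "full")
      if (xor(full[1], full[2])) {
        cands <- cands[full]
      } else {
        gc <- vapply(cands, function(x) gcFraction(x$seq), numeric(1))
        d <- abs(gc - 0.5)
        cands <- if (d[2] < d[1] - 1e-12) cands[2] else cands[1]
      }
    }
    c1 <- cands[[1]]
    rows[[i]] <- data.frame(contig = ct, start = c1$start, end = c1$end,
                            orientation = c1$orientation,
                            target_pos = pos[i], sequence = c1$seq,
                            window_start = c1$wstart, window_end = c1$wend,
                            feature_class = cls[i])
  }
  if (n_fail) spetLog("probe design failed for ", n_fail, " SNP(s)")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(GRanges(probe_id = character(), orientation = character(),
                   target_pos = integer(), sequence = character(),
                   window_start = integer(), window_end = integer(),
                   feature_class = character()))
  df <- do.call(rbind, rows)
  gr <- GRanges(df$contig, IRanges(df$start, df$end))
  mcols(gr) <- DataFrame(
    probe_id = sprintf("probe_%s_%d", df$contig, df$target_pos),
    orientation = df$orientation, target_pos = as.integer(df$target_pos),
    sequence = df$sequence, window_start = as.integer(df$window_start),
    window_end = as.integer(df$window_end),
    feature_class = df$feature_class)
  gr
}

#' Validate the probe-to-target placement
#'
#' `TRUE` iff the target SNP lies within the first `targetWindow` bp after
#' the probe 3' end (offset between 1 and `targetWindow`, inclusive).
#'
#' @param probe a probes [GenomicRanges::GRanges] (one or more rows).
#' @param config a [SpetConfig].
#' @return logical vector, one per probe.
#' @export
validateProbeWindow <- function(probe, config = spetConfig()) {
  off <- probeTargetOffset(probe)
  off >= 1L & off <= config@targetWindow
}

#' Filter probes on pilot-experiment coverage
#'
#' Keeps probes whose pilot mean depth lies within the configured window
#' (inclusive) and which have at most `maxLowSamples` low-coverage pilot
#' samples. In tomato-like mode a sample is low at depth <= 5 and up to 3
#' low samples are tolerated ("less than four samples having five or less
#' mapped reads"); in eggplant-like mode a sample is low at depth < 5 and
#' probes with 3 or more low samples are excluded.
#'
#' @param probes a probes [GenomicRanges::GRanges] or [ProbePanel].
#' @param coverage numeric matrix of pilot per-sample depths with probe
#'   ids as row names (one row per probe, one column per pilot sample).
#' @param config a [SpetConfig].
#' @return the retained probes, same class as the input.
#' @export
pilotCoverageFilter <- function(probes, coverage, config = spetConfig()) {
  panel <- NULL
  if (is(probes, "ProbePanel")) { panel <- probes; probes <- probeRanges(probes) }
  ids <- probes$probe_id
  missing_ids <- setdiff(ids, rownames(coverage))
  if (length(missing_ids))
    stop("no pilot coverage for probe(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  cov <- coverage[ids, , drop = FALSE]
  mean_depth <- rowMeans(cov)
  low <- if (config@lowDepthInclusive) cov <= config@lowDepthCutoff
         else cov < config@lowDepthCutoff
  n_low <- rowSums(low)
  keep <- mean_depth >= config@covMin & mean_depth <= config@covMax &
    n_low <= config@maxLowSamples
  out <- probes[keep]
  if (!is.null(panel)) { panel@probes <- out; validObject(panel); return(panel) }
  out
}

#' Design a complete SPET probe panel
#'
#' Runs the full design pipeline: feature classification, eligibility
#' filtering, spacing enforcement, probe placement, target-window
#' validation, optional pilot-coverage filtering, and optional uniform
#' random down-sampling to a target panel size under the configuration
#' seed. A stage report logs the number of candidates surviving each step.
#'
#' @param snps candidate [GenomicRanges::GRanges] from
#'   [readCandidateVcf()].
#' @param genome a [GenomeRef].
#' @param annotation annotation [GenomicRanges::GRanges] from
#'   [readAnnotation()].
#' @param coverage optional pilot coverage matrix (see
#'   [pilotCoverageFilter()]).
#' @param config a [SpetConfig].
#' @param targetSize optional final panel size; when fewer probes survive,
#'   all are kept.
#' @param order spacing selection order, `"position"` or `"random"`.
#' @return a list with elements `panel` (a [ProbePanel]) and `report`
#'   (data.frame of stage counts).
#' @export
designPanel <- function(snps, genome, annotation, coverage = NULL,
                        config = spetConfig(), targetSize = NULL,
                        order = "position") {
  mcols(snps)$feature_class <- classifyFeature(snps, annotation, genome)
  anchored <- isAnchored(genome)
  mcols(snps)$anchored <- unname(anchored[as.character(seqnames(snps))])
  stages <- c(candidates = length(snps))

  eligible <- filterEligible(snps, config)
  stages["eligible"] <- length(eligible)

  spaced <- enforceSpacing(eligible, config, order = order)
  stages["spaced"] <- length(spaced)

  probes <- designProbes(spaced, genome, config)
  probes <- probes[validateProbeWindow(probes, config)]
  stages["probes"] <- length(probes)

  if (!is.null(coverage)) {
    probes <- pilotCoverageFilter(probes, coverage, config)
    stages["coverage_filtered"] <- length(probes)
  }
  if (!is.null(targetSize) && length(probes) > targetSize) {
    idx <- withSeed(deriveSeed(config@seed, 11L),
                    sort(sample.int(length(probes), targetSize)))
    probes <- probes[idx]
  }
  stages["final"] <- length(probes)

  report <- data.frame(stage = names(stages), count = unname(stages))
  spetLog("panel design: ",
          paste(report$stage, report$count, sep = "=", collapse = ", "))
  panel <- new("ProbePanel", probes = probes,
               probeLength = config@probeLength,
               targetWindow = config@targetWindow,
               readoutLength = config@readoutLength)
  list(panel = panel, report = report)
}
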