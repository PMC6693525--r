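#' Run configuration for panel design and genotyping
#'
#' All numeric thresholds used by the panel-design and genotyping stages,
#' with defaults taken from the published tomato-like or eggplant-like
#' assay set-ups. Every threshold can be overridden individually for a
#' custom mode.
#'
#' @slot mode one of `"tomato-like"`, `"eggplant-like"`, `"custom"`.
#' @slot seed integer random seed recorded in all output headers.
#' @slot probeLength probe length in bp (40).
#' @slot targetWindow max distance (bp) of the target SNP from the probe
#'   3' end (25).
#' @slot readoutLength usable readout length beyond the probe 3' end (110).
#' @slot minAltCount minimum cohort-wise alternative allele count for an
#'   eligible candidate SNP: 9 in tomato-like mode (count strictly greater
#'   than 8), 4 in eggplant-like mode.
#' @slot minMaf minor allele frequency must exceed this for eligibility;
#'   `NA` disables the check (tomato-like). Eggplant-like: 0.25 (strict).
#' @slot spacingCds minimum distance (bp) between two selected CDS SNPs
#'   (5000).
#' @slot spacingIntronUtr minimum distance (bp) for any pair involving an
#'   intron/UTR SNP (15000).
#' @slot covMin,covMax inclusive pilot mean-depth window for probe
#'   retention (tomato-like 46-90, eggplant-like 79-130).
#' @slot lowDepthCutoff per-sample pilot depth at/below (tomato-like,
#'   inclusive) or below (eggplant-like, exclusive) which a sample counts
#'   as low-coverage (5).
#' @slot lowDepthInclusive whether `lowDepthCutoff` itself counts as low.
#' @slot maxLowSamples maximum tolerated number of low-coverage pilot
#'   samples per probe (3 tomato-like: "less than four"; 2 eggplant-like:
#'   probes with three or more are excluded).
#' @slot minDepthCall minimum reads to call a genotype (10).
#' @slot homMaxFrac maximum minor-base fraction for a homozygous call
#'   (0.04); minor fractions in (homMaxFrac, hetMinFrac) are ambiguous and
#'   yield missing.
#' @slot hetMinFrac,hetMaxFrac minor-base fraction window for a
#'   heterozygous call (0.25-0.5).
#' @slot minMeanDepth minimum mean site depth across all samples for a
#'   high-confidence site (30).
#' @slot maxMissing minimum fraction of non-missing calls per
#'   high-confidence site, vcftools `--max-missing` semantics (0.80
#'   tomato-like, 0.95 eggplant-like).
#' @slot genotypingRatio minimum fraction of callable samples for the
#'   re-call filter (0.80, inclusive).
#' @slot duplicateThreshold pairwise discordance below which two
#'   accessions are flagged as duplicates (0.002).
#' @slot mislabelMargin an accession is flagged as mislabeled when its
#'   nearest group is not its passport group and the nearest-group mean
#'   discordance is below `mislabelMargin` times the passport-group mean
#'   (0.5).
#'
#' @seealso [spetConfig()]
#' @export
setClass("SpetConfig",
  representation(
    mode = "character", seed = "integer",
    probeLength = "integer", targetWindow = "integer",
    readoutLength = "integer",
    minAltCount = "integer", minMaf = "numeric",
    spacingCds = "numeric", spacingIntronUtr = "numeric",
    covMin = "numeric", covMax = "numeric",
    lowDepthCutoff = "numeric", lowDepthInclusive = "logical",
    maxLowSamples = "integer",
    minDepthCall = "integer", homMaxFrac = "numeric",
    hetMinFrac = "numeric", hetMaxFrac = "numeric",
    minMeanDepth = "numeric", maxMissing = "numeric",
    genotypingRatio = "numeric",
    duplicateThreshold = "numeric", mislabelMargin = "numeric"))

setValidity("SpetConfig", function(object) {
  msg <- character()
  chk <- function(cond, what) if (!cond) msg <<- c(msg, what)
  chk(object@mode %in% c("tomato-like", "eggplant-like", "custom"),
      "mode must be tomato-like, eggplant-like or custom")
  chk(object@probeLength > 0L, "probeLength must be positive")
  chk(object@targetWindow > 0L, "targetWindow must be positive")
  chk(object@readoutLength > 0L, "readoutLength must be positive")
  chk(object@minAltCount >= 0L, "minAltCount must be >= 0")
  chk(is.na(object@minMaf) ||
        (object@minMaf >= 0 && object@minMaf <= 0.5),
      "minMaf must be in [0, 0.5] or NA")
  chk(object@spacingCds >= 0 && object@spacingIntronUtr >= 0,
      "spacing thresholds must be >= 0")
  chk(object@covMin <= object@covMax, "covMin must be <= covMax")
  chk(object@maxLowSamples >= 0L, "maxLowSamples must be >= 0")
  chk(object@minDepthCall >= 1L, "minDepthCall must be >= 1")
  chk(object@homMaxFrac >= 0 && object@homMaxFrac < object@hetMinFrac,
      "homMaxFrac must be in [0, hetMinFrac)")
  chk(object@hetMinFrac <= object@hetMaxFrac && object@hetMaxFrac <= 0.5,
      "het fraction window must satisfy hetMinFrac <= hetMaxFrac <= 0.5")
  chk(object@minMeanDepth >= 0, "minMeanDepth must be >= 0")
  chk(object@maxMissing >= 0 && object@maxMissing <= 1,
      "maxMissing must be in [0, 1]")
  chk(object@genotypingRatio >= 0 && object@genotypingRatio <= 1,
      "genotypingRatio must be in [0, 1]")
  chk(object@duplicateThreshold >= 0, "duplicateThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a run configuration
#'
#' Returns a [SpetConfig] whose thresholds default to the published values
#' for the chosen crop mode; any threshold can be overridden by name.
#' `"custom"` starts from the tomato-like defaults.
#'
#' @param mode `"tomato-like"`, `"eggplant-like"` or `"custom"`.
#' @param seed integer seed recorded in output headers and used for the
#'   randomised panel down-sampling.
#' @param ... named overrides for any [SpetConfig] slot.
#'
#' @return a validated [SpetConfig].
#' @examples
#' cfg <- spetConfig("eggplant-like")
#' cfg@minAltCount  # 4
#' @export
spetConfig <- function(mode = c("tomato-like", "eggplant-like", "custom"),
                       seed = 1L, ...) {
  mode <- match.arg(mode)
  base <- list(
    probeLength = 40L, targetWindow = 25L, readoutLength = 110L,
    spacingCds = 5000, spacingIntronUtr = 15000,
    lowDepthCutoff = 5, minDepthCall = 10L,
    homMaxFrac = 0.04, hetMinFrac = 0.25, hetMaxFrac = 0.5,
    minMeanDepth = 30, genotypingRatio = 0.80,
    duplicateThreshold = 0.002, mislabelMargin = 0.5)
  per_mode <- if (mode == "eggplant-like") {
    list(minAltCount = 4L, minMaf = 0.25, covMin = 79, covMax = 130,
         lowDepthInclusive = FALSE, maxLowSamples = 2L, maxMissing = 0.95)
  } else {
    # tomato-like defaults, also the base for "custom"
    list(minAltCount = 9L, minMaf = NA_real_, covMin = 46, covMax = 90,
         lowDepthInclusive = TRUE, maxLowSamples = 3L, maxMissing = 0.80)
  }
  args <- utils::modifyList(c(base, per_mode), list(...))
  int_slots <- c("probeLength", "targetWindow", "readoutLength",
                 "minAltCount", "maxLowSamples", "minDepthCall")
  for (s in int_slots) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SpetConfig", mode = mode, seed = as.integer(seed)),
                 args))
}

#' @describeIn spetConfig compact threshold listing
#' @param object a [SpetConfig]
#' @export
setMethod("show", "SpetConfig", function(object) {
  cat("SpetConfig <", object@mode, "> seed=", object@seed, "\n", sep = "")
  cat("  eligibility: alt count >=", object@minAltCount,
      if (!is.na(object@minMaf)) paste0(", MAF > ", object@minMaf), "\n")
  cat("  spacing: CDS", object@spacingCds, "bp; intron/UTR",
      object@spacingIntronUtr, "bp\n")
  cat("  probe:", object@probeLength, "bp, target window",
      object@targetWindow, "bp, readout", object@readoutLength, "bp\n")
  cat("  pilot coverage: mean in [", object@covMin, ",", object@covMax,
      "], low-depth samples <=", object@maxLowSamples, "\n")
  cat("  calls: depth >=", object@minDepthCall, ", hom f <=",
      object@homMaxFrac, ", het f in [", object@hetMinFrac, ",",
      object@hetMaxFrac, "]\n")
  cat("  site filters: mean depth >=", object@minMeanDepth,
      ", called fraction >=", object@maxMissing,
      ", genotyping ratio >=", object@genotypingRatio, "\n")
})

configHeader <- function(config) {
  sprintf("seed=%d mode=%s minAltCount=%d minMaf=%s spacingCds=%g spacingIntronUtr=%g minDepthCall=%d homMaxFrac=%g hetFrac=[%g,%g] minMeanDepth=%g maxMissing=%g genotypingRatio=%g",
          config@seed, config@mode, config@minAltCount,
          ifelse(is.na(config@minMaf), "NA", format(config@minMaf)),
          config@spacingCds, config@spacingIntronUtr, config@minDepthCall,
          config@homMaxFrac, config@hetMinFrac, config@hetMaxFrac,
          config@minMeanDepth, config@maxMissing, config@genotypingRatio)
}
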