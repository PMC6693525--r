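#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Reference genome with anchoring status
#'
#' Holds the reference contig sequences together with a flag distinguishing
#' anchored chromosomes from unplaced scaffolds. Panel design only places
#' probes on anchored contigs.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of uppercase contig
#'   sequences (alphabet restricted to A, C, G, T, N).
#' @slot anchored named logical vector, one entry per contig; `TRUE` for
#'   anchored chromosomes.
#'
#' @seealso [readGenome()], [genomeSequences()], [isAnchored()]
#' @export
setClass("GenomeRef",
  representation(sequences = "DNAStringSet", anchored = "logical"))

setValidity("GenomeRef", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "contig ids must be present and unique")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "genome must contain at least one contig")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "contig sequences must be non-empty")
  bad <- vapply(seq_along(object@sequences), function(i) {
    f <- Biostrings::alphabetFrequency(object@sequences[[i]])
    sum(f[c("A", "C", "G", "T", "N")]) != sum(f)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, paste0("non-DNA characters in record(s): ",
                         paste(ids[bad], collapse = ", ")))
  if (!identical(sort(names(object@anchored)), sort(ids)))
    msg <- c(msg, "anchored flags must cover exactly the contig ids")
  if (length(msg)) msg else TRUE
})

#' SPET probe panel
#'
#' A set of single-primer probes, each a 40-base (by default) stretch of the
#' forward reference strand placed immediately adjacent to its target SNP.
#' The readout window is the usable sequenced region beyond the probe 3'
#' end. Probes and windows are always stored in forward-strand coordinates;
#' `orientation` records whether the readout extends towards higher
#' (`readout-right`) or lower (`readout-left`) coordinates.
#'
#' @slot probes a [GenomicRanges::GRanges] of probe intervals with metadata
#'   columns `probe_id`, `orientation`, `target_pos`, `sequence`,
#'   `window_start`, `window_end`, `feature_class`.
#' @slot probeLength integer probe length in bp.
#' @slot targetWindow integer; the target SNP must lie within this many bp
#'   of the probe 3' end.
#' @slot readoutLength integer; nominal usable readout length in bp.
#'
#' @seealso [designPanel()], [writePanel()]
#' @export
setClass("ProbePanel",
  representation(probes = "GRanges", probeLength = "integer",
                 targetWindow = "integer", readoutLength = "integer"))

setValidity("ProbePanel", function(object) {
  msg <- character()
  p <- object@probes
  need <- c("probe_id", "orientation", "target_pos", "sequence",
            "window_start", "window_end", "feature_class")
  if (!all(need %in% names(mcols(p))))
    return(paste("probe metadata must contain:", paste(need, collapse = ", ")))
  if (length(p)) {
    if (anyDuplicated(p$probe_id)) msg <- c(msg, "probe ids must be unique")
    if (!all(width(p) == object@probeLength))
      msg <- c(msg, "all probe intervals must have length probeLength")
    if (!all(p$orientation %in% c("readout-right", "readout-left")))
      msg <- c(msg, "orientation must be readout-right or readout-left")
    if (!all(nchar(p$sequence) == object@probeLength))
      msg <- c(msg, "probe sequences must have length probeLength")
    off <- probeTargetOffset(p)
    if (any(off < 1L | off > object@targetWindow))
      msg <- c(msg, "target SNP must lie within targetWindow bp of the 3' end")
  }
  if (length(msg)) msg else TRUE
})

#' Per-site, per-sample, per-base read tallies
#'
#' Read counts from SPET readouts, organised as a sites x samples x base
#' (A, C, G, T) integer array. Site ranges carry the reference base.
#'
#' @slot sites a [GenomicRanges::GRanges] of single-base positions with a
#'   metadata column `ref` (reference base).
#' @slot samples character vector of accession ids.
#' @slot counts integer array of dimension (sites, samples, 4).
#'
#' @seealso [tallyAlleles()], [discoverSites()]
#' @export
setClass("AlleleDepthTable",
  representation(sites = "GRanges", samples = "character", counts = "array"))

setValidity("AlleleDepthTable", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[1] != length(object@sites) ||
      d[2] != length(object@samples) || d[3] != 4L)
    return("counts must be a (sites x samples x 4) array")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(dimnames(object@counts)[[3]], c("A", "C", "G", "T")))
    return("third dimension must be named A, C, G, T")
  if (!"ref" %in% names(mcols(object@sites)))
    return("sites must carry a 'ref' metadata column")
  TRUE
})

#' Genotype matrix for a SPET run
#'
#' Sites x accessions genotype calls stored as a
#' [SummarizedExperiment::RangedSummarizedExperiment] with two assays:
#' `geno` (integer alt-allele dosage: 0 hom-ref, 1 het, 2 hom-alt, `NA`
#' missing) and `depth` (total read depth per cell). Row ranges carry the
#' `ref` and `alt` alleles and a logical `target` flag marking sites that
#' coincide with a panel probe's target SNP (all other sites are accessory,
#' non-target discoveries in the readout windows).
#'
#' @seealso [discoverSites()], [filterHighConfidence()], [recallFilter()]
#' @export
setClass("SpetGenotypes", contains = "RangedSummarizedExperiment")

setValidity("SpetGenotypes", function(object) {
  msg <- character()
  if (!all(c("geno", "depth") %in%
           SummarizedExperiment::assayNames(object)))
    return("assays 'geno' and 'depth' are required")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!all(c("ref", "alt", "target") %in% names(mcols(rr))))
    return("row ranges must carry 'ref', 'alt' and 'target' columns")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "geno values must be 0, 1, 2 or NA")
  if (length(rr) && any(mcols(rr)$ref == mcols(rr)$alt, na.rm = TRUE))
    msg <- c(msg, "ref and alt alleles must differ")
  if (length(msg)) msg else TRUE
})

#' Simulated germplasm set
#'
#' Accession haplotypes simulated against a reference genome: a species
#' backbone of homozygous substitutions shared within each species, plus
#' per-accession variants whose heterozygosity has been eroded by the
#' requested number of selfing generations.
#'
#' @slot reference the [GenomeRef] the haplotypes are expressed against.
#' @slot accessions data.frame with columns `accession`, `species`,
#'   `divergence`, `selfing_generations`.
#' @slot variants data.frame of substitutions with columns `accession`,
#'   `contig`, `pos`, `ref`, `alt`, `h1`, `h2` (0/1 presence of the alt
#'   allele on each haplotype).
#'
#' @seealso [simulateGermplasm()], [truthGenotypes()]
#' @export
setClass("GermplasmSet",
  representation(reference = "GenomeRef", accessions = "data.frame",
                 variants = "data.frame"))

setValidity("GermplasmSet", function(object) {
  msg <- character()
  if (!all(c("accession", "species", "divergence", "selfing_generations")
           %in% names(object@accessions)))
    msg <- c(msg, "accessions table lacks required columns")
  need <- c("accession", "contig", "pos", "ref", "alt", "h1", "h2")
  if (!all(need %in% names(object@variants)))
    msg <- c(msg, "variants table lacks required columns")
  else {
    v <- object@variants
    if (nrow(v)) {
      if (!all(v$h1 %in% 0:1 & v$h2 %in% 0:1))
        msg <- c(msg, "h1/h2 must be 0/1")
      if (any(v$h1 + v$h2 == 0L))
        msg <- c(msg, "variant rows must carry the alt allele on >= 1 haplotype")
      if (!all(v$contig %in% names(object@reference@sequences)))
        msg <- c(msg, "variant contigs must exist in the reference")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Batch of simulated SPET reads
#'
#' Reads are stored aggregated: one row per distinct (probe, accession,
#' haplotype, sequence) combination with a multiplicity `n`. Sequences are
#' forward-strand copies of the probe's readout window with sequencing
#' errors applied; `n_errors` records how many error bases each row carries
#' for truth tracking.
#'
#' @slot reads data.frame with columns `probe_id`, `accession`,
#'   `haplotype`, `seq`, `n`, `n_errors`.
#' @slot readoutLength integer nominal readout length.
#'
#' @seealso [simulateReads()], [tallyAlleles()]
#' @export
setClass("ReadBatch",
  representation(reads = "data.frame", readoutLength = "integer"))

setValidity("ReadBatch", function(object) {
  need <- c("probe_id", "accession", "haplotype", "seq", "n", "n_errors")
  if (!all(need %in% names(object@reads)))
    return(paste("reads table must contain:", paste(need, collapse = ", ")))
  if (nrow(object@reads) && any(object@reads$n < 1L))
    return("read multiplicities must be >= 1")
  TRUE
})

#' Principal component analysis of a genotype matrix
#'
#' @slot loadings accession x component matrix of orthonormal loadings.
#' @slot varianceFraction fraction of genetic variance per component, for
#'   all components (sums to 1); only the first `ncol(loadings)` components
#'   are returned as loadings.
#'
#' @seealso [pcaGenotypes()]
#' @export
setClass("SpetPCA",
  representation(loadings = "matrix", varianceFraction = "numeric"))

setValidity("SpetPCA", function(object) {
  if (any(object@varianceFraction < -1e-12 | object@varianceFraction > 1 + 1e-12))
    return("variance fractions must lie in [0, 1]")
  if (is.unsorted(rev(object@varianceFraction), strictly = FALSE))
    return("variance fractions must be non-increasing")
  TRUE
})
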