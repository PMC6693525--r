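#' @include AllClasses.R
NULL

#' Accessors for spetkit objects
#'
#' Small accessor generics exposing the slots of the core classes without
#' `@` access.
#'
#' @param x a spetkit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname accessors
#' @export
setMethod("genomeSequences", "GenomeRef", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("isAnchored", function(x) standardGeneric("isAnchored"))

#' @rdname accessors
#' @export
setMethod("isAnchored", "GenomeRef", function(x)
  x@anchored[names(x@sequences)])

#' @rdname accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))

#' @rdname accessors
#' @export
setMethod("probeRanges", "ProbePanel", function(x) x@probes)

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname accessors
#' @export
setMethod("probeIds", "ProbePanel", function(x) x@probes$probe_id)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "AlleleDepthTable", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleIds", "GermplasmSet", function(x) x@accessions$accession)

#' @rdname accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname accessors
#' @export
setMethod("siteRanges", "AlleleDepthTable", function(x) x@sites)

#' @rdname accessors
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))

#' @rdname accessors
#' @export
setMethod("baseCounts", "AlleleDepthTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("accessionTable", function(x) standardGeneric("accessionTable"))

#' @rdname accessors
#' @export
setMethod("accessionTable", "GermplasmSet", function(x) x@accessions)

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setMethod("variantTable", "GermplasmSet", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("readTable", function(x) standardGeneric("readTable"))

#' @rdname accessors
#' @export
setMethod("readTable", "ReadBatch", function(x) x@reads)

#' Genotype-call matrix of a [SpetGenotypes] object
#'
#' @param x a [SpetGenotypes].
#' @return integer matrix (0 hom-ref, 1 het, 2 hom-alt, NA missing) with
#'   sites as rows and accessions as columns.
#' @export
genoCalls <- function(x) SummarizedExperiment::assay(x, "geno")

#' Per-cell total read depth of a [SpetGenotypes] object
#' @param x a [SpetGenotypes].
#' @return integer matrix of total depths.
#' @export
siteDepth <- function(x) SummarizedExperiment::assay(x, "depth")

#' Target-site flags of a [SpetGenotypes] object
#' @param x a [SpetGenotypes].
#' @return logical vector, `TRUE` where the site is a panel target SNP.
#' @export
isTargetSite <- function(x)
  mcols(SummarizedExperiment::rowRanges(x))$target

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setMethod("pcaLoadings", "SpetPCA", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname accessors
#' @export
setMethod("varianceFraction", "SpetPCA", function(x) x@varianceFraction)

setMethod("show", "GenomeRef", function(object) {
  cat("GenomeRef:", length(object@sequences), "contig(s),",
      sum(Biostrings::width(object@sequences)), "bp total;",
      sum(object@anchored), "anchored\n")
})

setMethod("show", "ProbePanel", function(object) {
  cat("ProbePanel:", length(object@probes), "probes (",
      object@probeLength, "bp, readout", object@readoutLength, "bp)\n")
  if (length(object@probes)) {
    tab <- table(object@probes$feature_class)
    cat("  feature classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "AlleleDepthTable", function(object) {
  cat("AlleleDepthTable:", length(object@sites), "positions x",
      length(object@samples), "samples; total reads-bases",
      sum(object@counts), "\n")
})

setMethod("show", "GermplasmSet", function(object) {
  cat("GermplasmSet:", nrow(object@accessions), "accessions in",
      length(unique(object@accessions$species)), "species;",
      nrow(object@variants), "haplotype variant records\n")
})

setMethod("show", "ReadBatch", function(object) {
  cat("ReadBatch:", sum(object@reads$n), "reads (",
      nrow(object@reads), "distinct) of", object@readoutLength, "bp\n")
})

setMethod("show", "SpetPCA", function(object) {
  k <- ncol(object@loadings)
  cat("SpetPCA:", nrow(object@loadings), "accessions,", k,
      "components returned\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", utils::head(object@varianceFraction, k)),
            collapse = ", "), "\n")
})
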