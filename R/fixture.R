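#' Ascertain candidate SNPs from a subset of accessions
#'
#' Builds the candidate-SNP set a resequencing experiment on the given
#' accessions would discover: every truth variant segregating in the
#' subset, with cohort-wise allele counts computed over the subset only.
#' Restricting the subset to the cultivated species reproduces panel
#' ascertainment bias (wild-only variants are invisible to the panel).
#'
#' @param germplasm a [GermplasmSet].
#' @param accessions accession ids to ascertain from (default: all).
#' @return candidate [GenomicRanges::GRanges] in the layout of
#'   [readCandidateVcf()].
#' @export
ascertainCandidates <- function(germplasm,
                                accessions = sampleIds(germplasm)) {
  truth <- truthGenotypes(germplasm)
  g <- genoCalls(truth)[, accessions, drop = FALSE]
  ac <- rowSums(g)
  an <- 2L * length(accessions)
  keep <- ac > 0L
  rr <- SummarizedExperiment::rowRanges(truth)[keep]
  out <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L))
  mcols(out)$ref <- mcols(rr)$ref
  mcols(out)$alt <- mcols(rr)$alt
  mcols(out)$alt_count <- as.integer(ac[keep])
  mcols(out)$maf <- pmin(ac[keep], an - ac[keep]) / an
  mcols(out)$an <- an
  mcols(out)$feature_class <- NA_character_
  mcols(out)$anchored <- NA
  out
}

#' Write candidate SNPs as a VCF
#'
#' @param candidates candidate [GenomicRanges::GRanges] with `ref`,
#'   `alt`, `alt_count`, `maf` metadata columns.
#' @param path output path.
#' @param an total allele number of the ascertainment cohort (for the
#'   `AN` INFO field); derived from `alt_count`/`maf` when omitted.
#' @param config a [SpetConfig] (seed recorded in the header).
#' @return invisibly, `path`.
#' @export
writeCandidateVcf <- function(candidates, path, an = NULL,
                              config = spetConfig()) {
  m <- mcols(candidates)
  if (is.null(an))
    an <- if ("an" %in% names(m)) m$an else 2L * pmax(m$alt_count, 1L)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=spetkit candidates; ", configHeader(config)),
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternative allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- if (length(candidates))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
            as.character(seqnames(candidates)), start(candidates),
            m$ref, m$alt, m$alt_count, as.integer(an))
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' Emits gene/mRNA/exon/CDS/UTR features such that [readAnnotation()]
#' recovers the same classified intervals (exons are the union of CDS and
#' UTR intervals; introns are re-derived as exon gaps).
#'
#' @param annotation annotation [GenomicRanges::GRanges] with `class` and
#'   `gene_id` columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAnnotationGff3 <- function(annotation, path) {
  lines <- "##gff-version 3"
  for (gid in unique(mcols(annotation)$gene_id)) {
    feats <- annotation[mcols(annotation)$gene_id == gid]
    ct <- as.character(seqnames(feats))[1]
    lo <- min(start(feats)); hi <- max(end(feats))
    mid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tspetkit\tgene\t%d\t%d\t.\t+\t.\tID=%s", ct, lo, hi, gid),
      sprintf("%s\tspetkit\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
              ct, lo, hi, mid, gid))
    exonic <- IRanges::reduce(feats[mcols(feats)$class != "intron"])
    lines <- c(lines,
      sprintf("%s\tspetkit\texon\t%d\t%d\t.\t+\t.\tParent=%s",
              ct, start(exonic), end(exonic), mid))
    for (cls in c("CDS", "UTR")) {
      sub <- feats[mcols(feats)$class == cls]
      if (length(sub))
        lines <- c(lines,
          sprintf("%s\tspetkit\t%s\t%d\t%d\t.\t+\t%s\tParent=%s",
                  ct, cls, start(sub), end(sub),
                  if (cls == "CDS") "0" else ".", mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Germplasm set containing reference-identical inbred accessions
#'
#' Accessions with divergence 0 and full selfing: their haplotypes equal
#' the reference everywhere (the role of an inbred reference control).
#'
#' @param reference a [GenomeRef].
#' @param names accession ids.
#' @return a [GermplasmSet].
#' @export
referenceAccessions <- function(reference, names = "control") {
  acc <- data.frame(accession = names, species = "control",
                    divergence = 0, selfing_generations = 20L)
  vars <- data.frame(accession = character(), contig = character(),
                     pos = integer(), ref = character(), alt = character(),
                     h1 = integer(), h2 = integer())
  new("GermplasmSet", reference = reference, accessions = acc,
      variants = vars)
}

#' Merge germplasm sets sharing one reference
#'
#' @param ... [GermplasmSet] objects on the same reference.
#' @return the combined [GermplasmSet].
#' @export
combineGermplasm <- function(...) {
  sets <- list(...)
  ref <- sets[[1]]@reference
  new("GermplasmSet", reference = ref,
      accessions = do.call(rbind, lapply(sets, accessionTable)),
      variants = do.call(rbind, lapply(sets, variantTable)))
}

#' Combine read batches
#'
#' @param ... [ReadBatch] objects with equal readout length.
#' @param rename optional named character vector applied to accession ids
#'   of the batches (old = name, new = value), e.g. to label two
#'   independent runs of the same accession as replicates.
#' @return the combined [ReadBatch].
#' @export
combineReads <- function(..., rename = NULL) {
  batches <- list(...)
  rl <- unique(vapply(batches, function(b) b@readoutLength, integer(1)))
  stopifnot(length(rl) == 1L)
  tabs <- lapply(batches, readTable)
  r <- do.call(rbind, tabs)
  if (!is.null(rename)) {
    hit <- r$accession %in% names(rename)
    r$accession[hit] <- unname(rename[r$accession[hit]])
  }
  new("ReadBatch", reads = r, readoutLength = rl)
}

#' Default in-memory simulation fixture
#'
#' Generates the full study scene at desk scale: a two-contig reference
#' with gene models, the default four-species germplasm ladder (a selfing
#' crop plus three progressively diverged outcrossing wild relatives),
#' candidate SNPs ascertained from the crop and nearest wild species
#' (panel ascertainment bias), and a designed probe panel.
#'
#' @param seed integer seed controlling every stage.
#' @param config a [SpetConfig] (tomato-like by default).
#' @param nContigs,contigLength,nGenes reference geometry.
#' @param species species ladder data.frame ([speciesSpec()] rows).
#' @param ascertainSpecies species whose accessions form the resequencing
#'   (ascertainment) cohort.
#' @return list with `genome`, `annotation`, `germplasm`, `candidates`,
#'   `panel`, `report`, `config`.
#' @export
defaultFixture <- function(seed = 1L,
                           config = spetConfig("tomato-like", seed = seed),
                           nContigs = 2L, contigLength = 400000L,
                           nGenes = 40L,
                           species = defaultSpeciesLadder(),
                           ascertainSpecies = c("crop", "wild_near")) {
  ref <- generateReference(nContigs = nContigs,
                           contigLength = contigLength,
                           nGenes = nGenes, seed = seed)
  germ <- simulateGermplasm(ref$genome, species, seed = seed)
  acc <- accessionTable(germ)
  subset <- acc$accession[acc$species %in% ascertainSpecies]
  cands <- ascertainCandidates(germ, subset)
  des <- designPanel(cands, ref$genome, ref$annotation, config = config)
  list(genome = ref$genome, annotation = ref$annotation, germplasm = germ,
       candidates = cands, panel = des$panel, report = des$report,
       config = config)
}

#' Materialise a simulation fixture on disk
#'
#' Writes the reference FASTA, GFF3 annotation, candidate VCF (ascertained
#' from the configured subset), panel BED/FASTA/TSV, simulated reads
#' (FASTQ, optional) and truth VCF, plus a manifest of md5 checksums.
#' Identical seeds yield identical manifests.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @param config a [SpetConfig].
#' @param fastq also emit reads as FASTQ (default `TRUE`).
#' @param ... passed to [defaultFixture()].
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
makeFixture <- function(outDir, seed = 1L,
                        config = spetConfig("tomato-like", seed = seed),
                        fastq = TRUE, ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fx <- defaultFixture(seed = seed, config = config, ...)
  paths <- c(reference = "reference.fasta", annotation = "annotation.gff3",
             candidates = "candidates.vcf", truth = "truth.vcf",
             reads = "reads.fastq")
  Biostrings::writeXStringSet(genomeSequences(fx$genome),
                              file.path(outDir, paths["reference"]))
  writeAnnotationGff3(fx$annotation, file.path(outDir, paths["annotation"]))
  writeCandidateVcf(fx$candidates, file.path(outDir, paths["candidates"]),
                    config = config)
  writePanel(fx$panel, file.path(outDir, "panel"), config = config)
  truth <- truthGenotypes(fx$germplasm)
  writeGenotypeVcf(truth, file.path(outDir, paths["truth"]),
                   config = config)
  files <- c(paths[c("reference", "annotation", "candidates", "truth")],
             "panel.bed", "panel.fasta", "panel.tsv")
  if (fastq) {
    reads <- simulateReads(fx$panel, fx$germplasm, seed = seed)
    writeFastq(reads, file.path(outDir, paths["reads"]))
    files <- c(files, paths["reads"])
  }
  manifest <- data.frame(
    file = unname(files),
    md5 = unname(tools::md5sum(file.path(outDir, files))))
  utils::write.table(manifest, file.path(outDir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Verify a fixture directory against its manifest
#'
#' @param dir fixture directory containing `MANIFEST.tsv`.
#' @return `TRUE` if every checksum matches; otherwise an error naming the
#'   mismatching files.
#' @export
checkFixture <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "MANIFEST.tsv"))
  now <- unname(tools::md5sum(file.path(dir, manifest$file)))
  bad <- manifest$file[is.na(now) | now != manifest$md5]
  if (length(bad))
    stop("fixture checksum mismatch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  TRUE
}
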