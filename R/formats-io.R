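#' Read candidate SNPs from a VCF file
#'
#' Loads a VCF 4.x of candidate variants and keeps only simple biallelic
#' SNPs (single-base REF and ALT, one ALT allele). Cohort-wise alternative
#' allele counts are taken from the `AC`/`AN` INFO fields when present, and
#' otherwise computed from the sample genotypes.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [GenomicRanges::GRanges] of width-1 candidate sites with
#'   metadata columns `ref`, `alt`, `alt_count`, `maf`, `feature_class`
#'   (`NA` until classified against an annotation) and `anchored` (`NA`
#'   until resolved against a genome).
#' @seealso [classifyFeature()], [designPanel()]
#' @export
readCandidateVcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && !is.matrix(fix))  # single-row VCFs drop to vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) {
    warning("VCF '", path, "' has an empty body; no candidate SNPs read")
    return(GRanges(ref = character(), alt = character(),
                   alt_count = integer(), maf = numeric(),
                   feature_class = character(), anchored = logical()))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop)
    spetLog("dropped ", n_drop, " non-biallelic-SNP row(s) from ", path)

  ac <- suppressWarnings(vcfR::extract.info(vcf, "AC", as.numeric = TRUE))
  an <- suppressWarnings(vcfR::extract.info(vcf, "AN", as.numeric = TRUE))
  if (is.null(ac) || all(is.na(ac)) || is.null(an) || all(is.na(an))) {
    if (ncol(vcf@gt %||% matrix(nrow = 0, ncol = 0)) < 2L)
      stop("VCF '", path, "' carries neither AC/AN INFO fields nor sample ",
           "genotypes; provide genotype columns so allele counts can be ",
           "computed", call. = FALSE)
    gt <- vcfR::extract.gt(vcf, "GT")
    alleles <- gsub("[^01.]", "/", gt)
    cnt <- function(x, a) sum(strsplit(paste(x[!is.na(x)], collapse = "/"),
                                       "/")[[1]] == a)
    ac <- apply(alleles, 1L, cnt, a = "1")
    an <- apply(alleles, 1L, function(x)
      cnt(x, "0") + cnt(x, "1"))
  }
  keep <- which(is_snp)
  gr <- GRanges(fix$CHROM[keep],
                IRanges(as.integer(fix$POS[keep]), width = 1L))
  mcols(gr)$ref <- fix$REF[keep]
  mcols(gr)$alt <- fix$ALT[keep]
  mcols(gr)$alt_count <- as.integer(ac[keep])
  an_k <- as.numeric(an[keep])
  mcols(gr)$maf <- ifelse(an_k > 0,
                          pmin(ac[keep], an_k - ac[keep]) / an_k, NA_real_)
  mcols(gr)$feature_class <- NA_character_
  mcols(gr)$anchored <- NA
  gr
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file of contig sequences.
#' @param anchoredPattern regular expression matched (case-insensitively)
#'   against contig ids; matching contigs are flagged as anchored
#'   chromosomes, the rest as unplaced scaffolds. The default accepts
#'   `chr`-prefixed and purely numeric ids.
#' @return a [GenomeRef]; sequences are stored uppercase.
#' @export
readGenome <- function(path, anchoredPattern = "^(chr\\S*|[0-9]+)$") {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     stop("cannot read FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    stop("FASTA '", path, "' contains zero records", call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig ids in '", path, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("non-DNA characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  up <- Biostrings::DNAStringSet(chars)
  names(up) <- names(seqs)
  anchored <- grepl(anchoredPattern, names(up), ignore.case = TRUE)
  names(anchored) <- names(up)
  new("GenomeRef", sequences = up, anchored = anchored)
}

#' Construct a GenomeRef from in-memory sequences
#'
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet] of contig sequences.
#' @param anchored named logical vector (defaults to all `TRUE`).
#' @return a [GenomeRef].
#' @export
GenomeRef <- function(sequences, anchored = NULL) {
  seqs <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  names(seqs) <- names(sequences)
  if (is.null(anchored))
    anchored <- stats::setNames(rep(TRUE, length(seqs)), names(seqs))
  new("GenomeRef", sequences = seqs, anchored = anchored)
}

#' Read gene annotation from GFF3
#'
#' Loads CDS and UTR features as given and derives introns as the gaps
#' between consecutive exons of each mRNA. Coordinates are kept 1-based
#' inclusive. Everything not covered by a CDS, UTR or intron feature is
#' intergenic by omission.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS/UTR features.
#' @return a [GenomicRanges::GRanges] with metadata columns `class`
#'   (`"CDS"`, `"intron"`, `"UTR"`) and `gene_id`.
#' @export
readAnnotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gff$type)
  parent_of <- function(x) {
    p <- mcols(x)$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  mrna <- gff[typ %in% c("mRNA", "transcript")]
  mrna_gene <- stats::setNames(
    ifelse(is.na(parent_of(mrna)), mrna$ID, parent_of(mrna)), mrna$ID)

  exons <- gff[typ == "exon"]
  introns <- GRanges()
  if (length(exons)) {
    par <- parent_of(exons)
    for (tx in unique(par)) {
      ex <- sort(exons[par == tx])
      if (length(ex) >= 2L) {
        if (!all(start(ex)[-1] > end(ex)[-length(ex)]))
          stop("overlapping exons within mRNA '", tx, "'", call. = FALSE)
        gaps <- GRanges(seqnames(ex)[-1],
                        IRanges(end(ex)[-length(ex)] + 1L,
                                start(ex)[-1] - 1L))
        gaps$tx <- tx
        introns <- c(introns, gaps)
      }
    }
  }
  cds <- gff[typ == "CDS"]
  utr <- gff[typ %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  gene_for <- function(x, parents) {
    g <- mrna_gene[parents]
    ifelse(is.na(g), parents, g)
  }
  out <- c(
    if (length(cds)) {
      g <- GRanges(seqnames(cds), IRanges(start(cds), end(cds)))
      g$class <- "CDS"; g$gene_id <- gene_for(cds, parent_of(cds)); g
    } else GRanges(),
    if (length(utr)) {
      g <- GRanges(seqnames(utr), IRanges(start(utr), end(utr)))
      g$class <- "UTR"; g$gene_id <- gene_for(utr, parent_of(utr)); g
    } else GRanges(),
    if (length(introns)) {
      g <- GRanges(seqnames(introns), IRanges(start(introns), end(introns)))
      g$class <- "intron"; g$gene_id <- gene_for(introns, introns$tx); g
    } else GRanges())
  sort(out)
}

#' Write a probe panel to BED, FASTA and TSV
#'
#' Emits `<prefix>.bed` (probe intervals, 0-based half-open),
#' `<prefix>.fasta` (probe sequences) and `<prefix>.tsv` (probe id, target
#' SNP position, orientation, feature class, readout window). The BED and
#' TSV headers record the configuration seed and thresholds.
#'
#' @param panel a [ProbePanel].
#' @param outPrefix output path prefix.
#' @param config the [SpetConfig] of the run (for the header).
#' @return invisibly, the three file paths.
#' @export
writePanel <- function(panel, outPrefix, config = spetConfig()) {
  p <- probeRanges(panel)
  hdr <- paste0("# spetkit panel; ", configHeader(config))
  bed <- file.path(paste0(outPrefix, ".bed"))
  tsv <- file.path(paste0(outPrefix, ".tsv"))
  fa <- file.path(paste0(outPrefix, ".fasta"))

  bed_lines <- c(hdr, if (length(p))
    sprintf("%s\t%d\t%d\t%s\t0\t%s",
            as.character(seqnames(p)), start(p) - 1L, end(p), p$probe_id,
            ifelse(p$orientation == "readout-right", "+", "-")))
  writeLines(bed_lines, bed)

  tsv_lines <- c(hdr,
    paste("probe_id", "contig", "probe_start", "probe_end", "orientation",
          "target_pos", "feature_class", "window_start", "window_end",
          sep = "\t"),
    if (length(p))
      sprintf("%s\t%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d",
              p$probe_id, as.character(seqnames(p)), start(p), end(p),
              p$orientation, p$target_pos, p$feature_class,
              p$window_start, p$window_end))
  writeLines(tsv_lines, tsv)

  seqs <- Biostrings::DNAStringSet(if (length(p)) p$sequence else character())
  names(seqs) <- p$probe_id
  Biostrings::writeXStringSet(seqs, fa)
  invisible(c(bed = bed, fasta = fa, tsv = tsv))
}

.GENO_GT <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a genotype matrix as VCF
#'
#' Emits a VCF 4.2 with per-sample `GT:DP` fields, a `TARGET` INFO flag on
#' panel target sites, and a header recording the configuration seed and
#' thresholds.
#'
#' @param genotypes a [SpetGenotypes].
#' @param path output path.
#' @param config the [SpetConfig] of the run.
#' @return invisibly, `path`.
#' @export
writeGenotypeVcf <- function(genotypes, path, config = spetConfig()) {
  rr <- SummarizedExperiment::rowRanges(genotypes)
  g <- genoCalls(genotypes)
  dp <- siteDepth(genotypes)
  stopifnot(nrow(g) == length(rr), all(dim(g) == dim(dp)))
  samples <- colnames(g)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=spetkit; ", configHeader(config)),
           "##INFO=<ID=TARGET,Number=0,Type=Flag,Description=\"Site is a panel target SNP\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- if (length(rr)) {
    gt <- matrix(.GENO_GT[as.character(g)], nrow = nrow(g))
    gt[is.na(g)] <- "./."
    dp_chr <- matrix(ifelse(is.na(dp), ".", as.character(dp)), nrow = nrow(g))
    cells <- matrix(paste0(gt, ":", dp_chr), nrow = nrow(g))
    apply(cbind(as.character(seqnames(rr)), start(rr), ".",
                mcols(rr)$ref, mcols(rr)$alt, ".", "PASS",
                ifelse(mcols(rr)$target, "TARGET", "."), "GT:DP", cells),
          1L, paste, collapse = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spetkit genotype VCF back into a SpetGenotypes object
#'
#' Inverse of [writeGenotypeVcf()]; any VCF with `GT` (and optionally
#' `DP`) per-sample fields and biallelic SNP rows is accepted. Sites whose
#' INFO field carries the `TARGET` flag are marked as target sites.
#'
#' @param path VCF path.
#' @return a [SpetGenotypes].
#' @export
readGenotypeVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (!is.matrix(fix))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  info <- fix$INFO %||% rep(".", nrow(fix))
  info[is.na(info)] <- "."
  rr <- GRanges(fix$CHROM, IRanges(as.integer(fix$POS), width = 1L),
                ref = fix$REF, alt = fix$ALT,
                target = grepl("(^|;)TARGET(;|$)", info))
  newSpetGenotypes(rr, code, matrix(as.integer(dp), nrow(dp), ncol(dp),
                                    dimnames = list(NULL, colnames(gt))))
}

#' Construct a SpetGenotypes object
#'
#' @param rowRanges width-1 [GenomicRanges::GRanges] with `ref`, `alt`
#'   and `target` metadata columns.
#' @param geno integer matrix of calls (0 hom-ref, 1 het, 2 hom-alt, `NA`
#'   missing), sites x accessions, with accession column names.
#' @param depth integer matrix of per-cell total read depths.
#' @param colData optional accession annotation
#'   ([S4Vectors::DataFrame]).
#' @return a [SpetGenotypes].
#' @export
SpetGenotypes <- function(rowRanges, geno, depth, colData = NULL)
  newSpetGenotypes(rowRanges, geno, depth, colData)

newSpetGenotypes <- function(rowRanges, geno, depth, colData = NULL) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno, depth = depth),
    rowRanges = rowRanges,
    colData = colData %||% DataFrame(row.names = colnames(geno)))
  new("SpetGenotypes", se)
}

# bracket expression matching newick-reserved characters (']' listed first)
.NEWICK_RESERVED_RE <- "[][(),:;'\"\t]"

#' Write a tree in newick format
#'
#' Branch lengths are preserved and integer bootstrap supports (if present
#' as node labels) are written on internal nodes. Taxon labels containing
#' newick-reserved characters are single-quoted (the serializer is the
#' package's own, so labels are written verbatim rather than sanitized).
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeNewick <- function(tree, path) {
  writeLines(newickString(tree), path)
  invisible(path)
}

# serialize a phylo to newick, quoting reserved characters
newickString <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(lab) {
    needs <- grepl(.NEWICK_RESERVED_RE, lab)
    lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
    lab
  }
  fmt_len <- function(x) if (is.null(x)) "" else paste0(":", format(x, digits = 10))
  rec <- function(node, incoming) {
    if (node <= n) {
      return(paste0(quote_label(tree$tip.label[node]),
                    fmt_len(tree$edge.length[incoming])))
    }
    parts <- vapply(kids[[as.character(node)]], function(e)
      rec(tree$edge[e, 2], e), character(1))
    lab <- if (!is.null(tree$node.label)) {
      nl <- tree$node.label[node - n]
      if (is.na(nl)) "" else quote_label(nl)
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", lab,
           fmt_len(if (is.null(incoming)) NULL
                   else tree$edge.length[incoming]))
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  paste0(rec(root, NULL), ";")
}

#' Read a newick tree
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Read a probe panel written by writePanel
#'
#' Rebuilds a [ProbePanel] from the `<prefix>.tsv` table; probe sequences
#' are re-extracted from the reference genome.
#'
#' @param prefix the path prefix used by [writePanel()] (or the `.tsv`
#'   path itself).
#' @param genome the [GenomeRef] the panel was designed against.
#' @param config a [SpetConfig] giving probe geometry.
#' @return a [ProbePanel].
#' @export
readPanel <- function(prefix, genome, config = spetConfig()) {
  path <- if (grepl("\\.tsv$", prefix)) prefix else paste0(prefix, ".tsv")
  tab <- utils::read.delim(path, comment.char = "#")
  gr <- GRanges(tab$contig, IRanges(tab$probe_start, tab$probe_end))
  seqs <- genomeSequences(genome)
  seq_chr <- vapply(seq_len(nrow(tab)), function(i)
    as.character(Biostrings::subseq(seqs[[tab$contig[i]]],
                                    tab$probe_start[i], tab$probe_end[i])),
    character(1))
  mcols(gr) <- DataFrame(
    probe_id = tab$probe_id, orientation = tab$orientation,
    target_pos = as.integer(tab$target_pos), sequence = seq_chr,
    window_start = as.integer(tab$window_start),
    window_end = as.integer(tab$window_end),
    feature_class = tab$feature_class)
  new("ProbePanel", probes = gr, probeLength = config@probeLength,
      targetWindow = config@targetWindow,
      readoutLength = config@readoutLength)
}

#' Read SPET reads from a FASTQ written by writeFastq
#'
#' Read ids must follow the `probe|accession|haplotype|index` convention
#' used by [writeFastq()]; identical sequences are re-aggregated.
#'
#' @param path FASTQ path.
#' @param readoutLength nominal readout length of the panel.
#' @return a [ReadBatch] (error annotations are not recoverable from
#'   FASTQ and are reported as zero).
#' @export
readSpetFastq <- function(path, readoutLength = 110L) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path, call. = FALSE)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  parts <- strsplit(ids, "|", fixed = TRUE)
  dt <- data.table(
    probe_id = vapply(parts, `[`, character(1), 1L),
    accession = vapply(parts, `[`, character(1), 2L),
    haplotype = as.integer(sub("^h", "",
                               vapply(parts, `[`, character(1), 3L))),
    seq = seqs)
  agg <- dt[, .(n = .N), by = .(probe_id, accession, haplotype, seq)]
  agg[, n_errors := 0L]
  new("ReadBatch", reads = as.data.frame(agg),
      readoutLength = as.integer(readoutLength))
}
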