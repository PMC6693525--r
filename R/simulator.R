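#' @importFrom data.table data.table as.data.table := .N .SD setorder rbindlist
NULL

#' Describe one simulated species
#'
#' @param name species label.
#' @param divergence expected substitutions per site separating the
#'   species backbone from the reference lineage.
#' @param selfingGenerations integer >= 0; generations of selfing applied
#'   to each accession (each halves residual heterozygosity).
#' @param nAccessions number of accessions to simulate.
#' @param diversity within-species nucleotide diversity: the expected
#'   per-site difference between two random haplotypes of the species
#'   (realised through a segregating-site pool, see
#'   [simulateGermplasm()]).
#' @return a one-row data.frame; several can be `rbind`ed into a ladder.
#' @export
speciesSpec <- function(name, divergence, selfingGenerations = 0L,
                        nAccessions = 2L, diversity = 0) {
  stopifnot(divergence >= 0, diversity >= 0, selfingGenerations >= 0)
  data.frame(name = name, divergence = divergence,
             selfing_generations = as.integer(selfingGenerations),
             n_accessions = as.integer(nAccessions),
             diversity = diversity)
}

#' Default four-species germplasm ladder
#'
#' A low-diversity autogamous crop plus three progressively diverged,
#' outcrossing wild relatives — the structure of a crop genepool panel
#' (cultivated accessions, a close wild ancestor, and more distant
#' relatives), with divergence increasing along the ladder.
#'
#' @param nCrop,nWild accessions per species for the crop and each wild
#'   species.
#' @return data.frame of species specifications.
#' @export
defaultSpeciesLadder <- function(nCrop = 6L, nWild = 3L) {
  rbind(
    speciesSpec("crop",      divergence = 0.002, selfingGenerations = 20L,
                nAccessions = nCrop, diversity = 0.001),
    speciesSpec("wild_near", divergence = 0.006, selfingGenerations = 0L,
                nAccessions = nWild, diversity = 0.003),
    speciesSpec("wild_mid",  divergence = 0.015, selfingGenerations = 0L,
                nAccessions = nWild, diversity = 0.004),
    speciesSpec("wild_far",  divergence = 0.030, selfingGenerations = 0L,
                nAccessions = nWild, diversity = 0.005))
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

#' Generate a synthetic reference genome and annotation
#'
#' Uniform-random DNA contigs carrying non-overlapping gene models, each
#' with UTR/CDS/intron intervals: genes consist of 2-5 exons separated by
#' introns; the leading and trailing portions of the terminal exons are
#' UTR, the remainder CDS. Deterministic under `seed`.
#'
#' @param nContigs number of contigs.
#' @param contigLength length of each contig in bp.
#' @param nGenes number of gene models per contig.
#' @param seed integer seed.
#' @param exonLength,intronLength mean exon/intron lengths in bp.
#' @param utrLength UTR length at each gene end in bp.
#' @return list with `genome` (a [GenomeRef], all contigs anchored) and
#'   `annotation` (a [GenomicRanges::GRanges] as from [readAnnotation()]).
#' @export
generateReference <- function(nContigs = 2L, contigLength = 400000L,
                              nGenes = 40L, seed = 1L,
                              exonLength = 250L, intronLength = 400L,
                              utrLength = 150L) {
  withSeed(deriveSeed(seed, 1L), {
    seqs <- stats::setNames(
      vapply(seq_len(nContigs), function(i) .random_dna(contigLength),
             character(1)),
      paste0("chr", seq_len(nContigs)))
    genome <- GenomeRef(seqs)
    feats <- list()
    for (ct in names(seqs)) {
      # draw gene geometries, then place them non-overlapping
      genes <- lapply(seq_len(nGenes), function(g) {
        n_ex <- sample(2:5, 1L)
        ex <- pmax(50L, stats::rpois(n_ex, exonLength))
        intr <- pmax(50L, stats::rpois(n_ex - 1L, intronLength))
        list(n_ex = n_ex, ex = ex, intr = intr,
             len = sum(ex) + sum(intr))
      })
      total <- sum(vapply(genes, `[[`, numeric(1), "len"))
      slack <- contigLength - total
      if (slack < nGenes)
        stop("infeasible geometry: genes do not fit on contig ", ct,
             call. = FALSE)
      # distribute slack as random inter-gene gaps
      gaps <- sort(sample.int(slack - 1L, nGenes))
      gaps <- diff(c(0L, gaps))
      cursor <- 0L
      for (gi in seq_len(nGenes)) {
        cursor <- cursor + gaps[gi]
        gene_start <- cursor + 1L
        gid <- sprintf("%s_g%03d", ct, gi)
        p <- gene_start
        for (e in seq_len(genes[[gi]]$n_ex)) {
          ex_start <- p
          ex_end <- p + genes[[gi]]$ex[e] - 1L
          if (e == 1L) {
            u_end <- min(ex_start + utrLength - 1L, ex_end - 1L)
            feats[[length(feats) + 1L]] <-
              data.frame(contig = ct, start = ex_start, end = u_end,
                         class = "UTR", gene_id = gid)
            cds_start <- u_end + 1L
          } else cds_start <- ex_start
          if (e == genes[[gi]]$n_ex) {
            u_start <- max(ex_end - utrLength + 1L, cds_start + 1L)
            feats[[length(feats) + 1L]] <-
              data.frame(contig = ct, start = u_start, end = ex_end,
                         class = "UTR", gene_id = gid)
            cds_end <- u_start - 1L
          } else cds_end <- ex_end
          if (cds_end >= cds_start)
            feats[[length(feats) + 1L]] <-
              data.frame(contig = ct, start = cds_start, end = cds_end,
                         class = "CDS", gene_id = gid)
          if (e < genes[[gi]]$n_ex) {
            feats[[length(feats) + 1L]] <-
              data.frame(contig = ct, start = ex_end + 1L,
                         end = ex_end + genes[[gi]]$intr[e],
                         class = "intron", gene_id = gid)
            p <- ex_end + genes[[gi]]$intr[e] + 1L
          } else p <- ex_end + 1L
        }
        cursor <- cursor + genes[[gi]]$len
      }
    }
    ann <- if (length(feats)) {
      df <- do.call(rbind, feats)
      gr <- GRanges(df$contig, IRanges(df$start, df$end),
                    class = df$class, gene_id = df$gene_id)
      sort(gr)
    } else GRanges(class = character(), gene_id = character())
    list(genome = genome, annotation = ann)
  })
}

# transition partner used when no alt base is registered yet
.substitute_bases <- function(ref_bases) {
  vapply(ref_bases, function(b) sample(setdiff(.BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Simulate a multi-species germplasm set
#'
#' Each species receives a backbone of `Poisson(divergence x genome
#' length)` homozygous substitutions shared by its accessions, plus a
#' within-species polymorphism pool of `Poisson(3 x diversity x genome
#' length)` segregating sites with allele frequencies drawn uniformly
#' (so that `diversity` equals the expected per-site difference between
#' two random haplotypes of the species). Each accession draws its two
#' haplotypes independently from the pool frequencies; `g` generations of
#' selfing then fix each heterozygous site to one of its alleles (chosen
#' uniformly) with probability `1 - 2^-g`. Biallelic consistency is
#' enforced: the first alternative base drawn at a position is reused by
#' any later mutation there.
#'
#' @param reference a [GenomeRef].
#' @param species data.frame of species specifications
#'   ([speciesSpec()] rows).
#' @param seed integer seed.
#' @return a [GermplasmSet].
#' @export
simulateGermplasm <- function(reference, species = defaultSpeciesLadder(),
                              seed = 1L) {
  seqs <- genomeSequences(reference)
  lens <- Biostrings::width(seqs)
  L <- sum(lens)
  contigs <- names(seqs)
  contig_chars <- lapply(seq_along(seqs),
                         function(i) as.character(seqs[[i]]))
  names(contig_chars) <- contigs
  draw_sites <- function(n) {
    # uniform positions over the concatenated genome, no repeat mutation
    g <- sort(sample.int(L, min(n, L)))
    ct_idx <- findInterval(g - 1L, cumsum(c(0L, lens))[seq_along(lens)],
                           rightmost.closed = FALSE)
    offs <- g - cumsum(c(0L, lens))[ct_idx]
    data.table(contig = contigs[ct_idx], pos = as.integer(offs))
  }
  refbase_at <- function(dt)
    vapply(seq_len(nrow(dt)), function(i)
      substr(contig_chars[[dt$contig[i]]], dt$pos[i], dt$pos[i]),
      character(1))

  withSeed(deriveSeed(seed, 2L), {
    acc_rows <- list(); var_rows <- list()
    for (si in seq_len(nrow(species))) {
      sp <- species[si, ]
      bb_n <- stats::rpois(1L, sp$divergence * L)
      backbone <- draw_sites(bb_n)
      if (nrow(backbone)) {
        backbone[, ref := refbase_at(backbone)]
        backbone[, alt := .substitute_bases(ref)]
      }
      # within-species segregating pool: uniform frequencies give an
      # expected per-site haplotype difference of 1/3 per pool site
      pool_n <- stats::rpois(1L, 3 * sp$diversity * L)
      pool <- draw_sites(pool_n)
      if (nrow(pool)) {
        pool[, ref := refbase_at(pool)]
        pool[, alt := .substitute_bases(ref)]
        pool[, freq := stats::runif(.N)]
      }
      for (ai in seq_len(sp$n_accessions)) {
        acc <- sprintf("%s_%02d", sp$name, ai)
        acc_rows[[length(acc_rows) + 1L]] <-
          data.frame(accession = acc, species = sp$name,
                     divergence = sp$divergence,
                     selfing_generations = sp$selfing_generations)
        if (nrow(pool)) {
          own <- pool[, .(contig, pos, ref, alt)]
          own[, `:=`(h1 = stats::rbinom(.N, 1L, pool$freq),
                     h2 = stats::rbinom(.N, 1L, pool$freq))]
          # selfing: fix each het site with prob 1 - 2^-g
          if (sp$selfing_generations > 0L) {
            het <- own$h1 != own$h2
            fix <- het &
              stats::runif(nrow(own)) < 1 - 2^(-sp$selfing_generations)
            to_alt <- stats::rbinom(nrow(own), 1L, 0.5) == 1L
            own[fix & to_alt, `:=`(h1 = 1L, h2 = 1L)]
            own[fix & !to_alt, `:=`(h1 = 0L, h2 = 0L)]
          }
          own <- own[h1 + h2 > 0L]
        } else own <- data.table(contig = character(), pos = integer(),
                                 ref = character(), alt = character(),
                                 h1 = integer(), h2 = integer())
        both <- if (nrow(backbone))
          rbind(backbone[, .(contig, pos, ref, alt, h1 = 1L, h2 = 1L)], own)
        else own
        if (nrow(both)) {
          both[, accession := acc]
          # a backbone and an accession variant can coincide: keep hom-alt
          both <- both[order(contig, pos, -(h1 + h2))]
          both <- both[!duplicated(both[, .(contig, pos)])]
          var_rows[[length(var_rows) + 1L]] <- both
        }
      }
    }
    vars <- if (length(var_rows)) as.data.frame(rbindlist(var_rows))
            else data.frame(accession = character(), contig = character(),
                            pos = integer(), ref = character(),
                            alt = character(), h1 = integer(),
                            h2 = integer())
    if (nrow(vars)) {
      # biallelic consistency across species: first alt drawn wins
      vt <- as.data.table(vars)
      setorder(vt, contig, pos)
      vt[, alt := alt[1L], by = .(contig, pos)]
      vars <- as.data.frame(
        vt[, .(accession, contig, pos, ref, alt, h1, h2)])
    }
    new("GermplasmSet", reference = reference,
        accessions = do.call(rbind, acc_rows), variants = vars)
  })
}

#' True genotypes of a germplasm set
#'
#' @param germplasm a [GermplasmSet].
#' @return a [SpetGenotypes] over every simulated variant position (depth
#'   assay is `NA`; `target` flags are `FALSE` until a panel is known).
#'   Genotypes are alt-allele dosages from the two haplotypes.
#' @export
truthGenotypes <- function(germplasm) {
  v <- as.data.table(variantTable(germplasm))
  accs <- sampleIds(germplasm)
  if (nrow(v) == 0L) {
    rr <- GRanges(ref = character(), alt = character(), target = logical())
    m <- matrix(0L, 0L, length(accs), dimnames = list(NULL, accs))
    return(newSpetGenotypes(rr, m, m))
  }
  sites <- unique(v[, .(contig, pos, ref, alt)])
  setorder(sites, contig, pos)
  key <- paste(sites$contig, sites$pos)
  geno <- matrix(0L, nrow(sites), length(accs),
                 dimnames = list(NULL, accs))
  idx <- match(paste(v$contig, v$pos), key)
  geno[cbind(idx, match(v$accession, accs))] <- v$h1 + v$h2
  rr <- GRanges(sites$contig, IRanges(sites$pos, width = 1L),
                ref = sites$ref, alt = sites$alt,
                target = rep(FALSE, nrow(sites)))
  depth <- matrix(NA_integer_, nrow(sites), length(accs),
                  dimnames = list(NULL, accs))
  newSpetGenotypes(rr, geno, depth)
}

# Apply an accession's haplotype substitutions to the reference substring
# [a, b] of one contig (forward strand).
.hap_window_seq <- function(ref_str, a, b, pos, alt) {
  s <- substr(ref_str, a, b)
  if (length(pos)) {
    ch <- strsplit(s, "")[[1]]
    ch[pos - a + 1L] <- alt
    s <- paste(ch, collapse = "")
  }
  s
}

#' Simulate SPET reads for a germplasm set
#'
#' Per probe and accession, the read count is drawn from a negative
#' binomial with the configured mean depth and dispersion (or held fixed
#' when `depthModel = "fixed"`). Each read originates from a random
#' haplotype; hybridization succeeds with probability `(1 - lambda)^m`,
#' where `m` is the number of mismatches between the probe sequence and
#' that haplotype over the probe footprint, and failed reads are
#' discarded — this is what makes probe dropout grow with divergence from
#' the reference. Surviving reads copy the haplotype's readout window
#' (forward strand, truncated at the contig edge) with a per-base error
#' rate `epsilon`.
#'
#' @param panel a [ProbePanel].
#' @param germplasm a [GermplasmSet] simulated on the same reference.
#' @param seed integer seed.
#' @param meanDepth mean reads per probe per accession (default 60).
#' @param dispersion negative-binomial size parameter (default 3).
#' @param lambda per-mismatch hybridization failure rate (default 0.3).
#' @param epsilon per-base sequencing error rate (default 2e-4).
#' @param depthModel `"nbinom"` or `"fixed"` (exactly `meanDepth` reads).
#' @return a [ReadBatch].
#' @export
simulateReads <- function(panel, germplasm, seed = 1L, meanDepth = 60,
                          dispersion = 3, lambda = 0.3, epsilon = 2e-4,
                          depthModel = c("nbinom", "fixed")) {
  depthModel <- match.arg(depthModel)
  probes <- probeRanges(panel)
  if (length(probes) == 0L)
    return(new("ReadBatch",
               reads = data.frame(probe_id = character(),
                                  accession = character(),
                                  haplotype = integer(), seq = character(),
                                  n = integer(), n_errors = integer()),
               readoutLength = panel@readoutLength))
  seqs <- genomeSequences(germplasm@reference)
  contig_chars <- lapply(seq_along(seqs), function(i) as.character(seqs[[i]]))
  names(contig_chars) <- names(seqs)
  vars <- as.data.table(variantTable(germplasm))
  accs <- sampleIds(germplasm)

  p_dt <- data.table(
    probe_id = probes$probe_id, contig = as.character(seqnames(probes)),
    p_start = start(probes), p_end = end(probes),
    w_start = probes$window_start, w_end = probes$window_end)

  withSeed(deriveSeed(seed, 3L), {
    out <- vector("list", length(accs) * nrow(p_dt))
    k <- 0L
    for (acc in accs) {
      av <- vars[accession == acc]
      for (pi in seq_len(nrow(p_dt))) {
        pr <- p_dt[pi]
        n <- if (depthModel == "fixed") as.integer(round(meanDepth))
             else stats::rnbinom(1L, size = dispersion, mu = meanDepth)
        if (n == 0L) next
        n1 <- stats::rbinom(1L, n, 0.5)  # haplotype of origin per read
        nh <- c(n1, n - n1)
        # mismatches over the probe footprint, per haplotype
        pv <- av[contig == pr$contig & pos >= pr$p_start & pos <= pr$p_end]
        m <- c(sum(pv$h1), sum(pv$h2))
        surv <- stats::rbinom(2L, nh, (1 - lambda)^m)
        if (sum(surv) == 0L) next
        wv <- av[contig == pr$contig & pos >= pr$w_start & pos <= pr$w_end]
        rl <- pr$w_end - pr$w_start + 1L
        for (h in 1:2) {
          if (surv[h] == 0L) next
          hp <- if (h == 1L) wv[h1 == 1L] else wv[h2 == 1L]
          hseq <- .hap_window_seq(contig_chars[[pr$contig]], pr$w_start,
                                  pr$w_end, hp$pos, hp$alt)
          n_err_bases <- stats::rbinom(1L, surv[h] * rl, epsilon)
          err_read <- if (n_err_bases > 0L)
            sample.int(surv[h], n_err_bases, replace = TRUE) else integer()
          n_clean <- surv[h] - length(unique(err_read))
          k <- k + 1L
          rows <- list()
          if (n_clean > 0L)
            rows[[1L]] <- data.frame(probe_id = pr$probe_id,
                                     accession = acc, haplotype = h,
                                     seq = hseq, n = n_clean, n_errors = 0L)
          for (r in unique(err_read)) {
            e_pos <- sample.int(rl, sum(err_read == r), replace = FALSE)
            ch <- strsplit(hseq, "")[[1]]
            ch[e_pos] <- vapply(ch[e_pos], function(b)
              sample(setdiff(.BASES, b), 1L), character(1))
            rows[[length(rows) + 1L]] <-
              data.frame(probe_id = pr$probe_id, accession = acc,
                         haplotype = h, seq = paste(ch, collapse = ""),
                         n = 1L, n_errors = length(e_pos))
          }
          out[[k]] <- do.call(rbind, rows)
        }
      }
    }
    reads <- if (k) do.call(rbind, out[seq_len(k)])
             else data.frame(probe_id = character(), accession = character(),
                             haplotype = integer(), seq = character(),
                             n = integer(), n_errors = integer())
    new("ReadBatch", reads = reads, readoutLength = panel@readoutLength)
  })
}

#' Write a read batch as FASTQ
#'
#' Reads are expanded to one record each with a constant quality string;
#' read ids encode probe, accession and haplotype of origin.
#'
#' @param reads a [ReadBatch].
#' @param path output FASTQ path.
#' @return invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
  r <- readTable(reads)
  con <- file(path, "w")
  on.exit(close(con))
  idx <- 0L
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(r$n[i])) {
      idx <- idx + 1L
      writeLines(c(sprintf("@%s|%s|h%d|%d", r$probe_id[i], r$accession[i],
                           r$haplotype[i], idx),
                   r$seq[i], "+",
                   strrep("I", nchar(r$seq[i]))), con)
    }
  }
  invisible(path)
}
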