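#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_j^2)` over the allele frequencies at a site. For a
#' biallelic site the maximum is 0.5 at equifrequency.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return the PIC value.
#' @examples
#' pic(c(0.5, 0.5))  # 0.5
#' pic(c(0.9, 0.1))  # 0.18
#' @export
pic <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")",
         call. = FALSE)
  1 - sum(freqs^2)
}

#' Per-site diversity statistics
#'
#' Allele frequencies are computed from called genotypes only (missing
#' calls are excluded, so frequencies sum to 1).
#'
#' @param genotypes a [SpetGenotypes].
#' @return a data.frame with columns `contig`, `pos`, `target`, `p_ref`,
#'   `p_alt`, `pic`, `mean_depth`, `missing_frac`.
#' @export
siteStats <- function(genotypes) {
  g <- genoCalls(genotypes)
  d <- siteDepth(genotypes)
  rr <- SummarizedExperiment::rowRanges(genotypes)
  n_called <- rowSums(!is.na(g))
  p_alt <- ifelse(n_called > 0,
                  rowSums(g, na.rm = TRUE) / (2 * n_called), NA_real_)
  data.frame(
    contig = as.character(seqnames(rr)), pos = start(rr),
    target = mcols(rr)$target,
    p_ref = 1 - p_alt, p_alt = p_alt,
    pic = ifelse(is.na(p_alt), NA_real_, 1 - ((1 - p_alt)^2 + p_alt^2)),
    mean_depth = rowMeans(d),
    missing_frac = rowMeans(is.na(g)))
}

#' Per-accession summary statistics
#'
#' Missing % is computed over all sites; heterozygosity % and
#' reference-identity % over non-missing calls only. Identity counts
#' hom-ref calls (a heterozygous call is not identical to the reference).
#'
#' @param genotypes a [SpetGenotypes].
#' @return a data.frame with columns `accession`, `missing_pct`,
#'   `het_pct`, `ref_identity_pct` (all in `[0, 100]`; `NaN` with a
#'   warning for accessions with zero non-missing calls).
#' @export
accessionStats <- function(genotypes) {
  g <- genoCalls(genotypes)
  n_sites <- nrow(g)
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L))
    warning("accession(s) with zero non-missing calls: ",
            paste(colnames(g)[n_called == 0L], collapse = ", "),
            "; het and identity are undefined")
  data.frame(
    accession = colnames(g),
    missing_pct = 100 * colSums(is.na(g)) / n_sites,
    het_pct = 100 * colSums(g == 1L, na.rm = TRUE) / n_called,
    ref_identity_pct = 100 * colSums(g == 0L, na.rm = TRUE) / n_called,
    row.names = NULL)
}

#' Pairwise genotype discordance between accessions
#'
#' For each pair, the fraction of sites non-missing in both accessions
#' where the genotype calls differ. Replicate samples of one accession are
#' expected near zero; the published replicate range is 0.1 to just under
#' 0.2%.
#'
#' @param genotypes a [SpetGenotypes] with at least 2 accessions.
#' @return symmetric numeric matrix with zero diagonal (`NA` with a
#'   warning for pairs with zero co-called sites).
#' @export
pairwiseDiscordance <- function(genotypes) {
  g <- genoCalls(genotypes)
  stopifnot(ncol(g) >= 2L)
  n <- ncol(g)
  D <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      cc <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(cc)) {
        warning("zero co-called sites for pair ", colnames(g)[i], " / ",
                colnames(g)[j])
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- mean(g[cc, i] != g[cc, j])
      }
    }
  }
  D
}

#' Flag duplicate accessions
#'
#' Pairs with discordance strictly below the threshold are flagged and
#' grouped into connected components (duplicate groups).
#'
#' @param discordance matrix from [pairwiseDiscordance()].
#' @param threshold discordance threshold (default 0.002, motivated by
#'   replicate discordance below 0.2%).
#' @return list with `pairs` (data.frame `a`, `b`, `discordance`) and
#'   `groups` (list of accession-id vectors, one per duplicate group).
#' @export
flagDuplicates <- function(discordance, threshold = 0.002) {
  idx <- which(upper.tri(discordance) & discordance < threshold,
               arr.ind = TRUE)
  pairs <- data.frame(
    a = rownames(discordance)[idx[, 1]],
    b = colnames(discordance)[idx[, 2]],
    discordance = discordance[idx])
  groups <- list()
  if (nrow(pairs)) {
    gr <- igraph::graph_from_data_frame(pairs[, c("a", "b")],
                                        directed = FALSE)
    comp <- igraph::components(gr)
    groups <- split(names(comp$membership), comp$membership)
    names(groups) <- NULL
  }
  list(pairs = pairs, groups = groups)
}

#' Flag putatively mislabeled accessions
#'
#' For each accession the mean discordance to every passport group
#' (excluding itself) is computed. An accession is flagged when its
#' nearest group differs from its passport group and the nearest-group
#' mean discordance is below `margin` times the passport-group mean.
#' Accessions whose passport group has no other member are skipped with a
#' warning.
#'
#' @param genotypes a [SpetGenotypes] (used to compute discordances), or a
#'   precomputed discordance matrix.
#' @param labels named character vector mapping accession id to passport
#'   group; at least 2 groups with 2 or more members are required.
#' @param margin flagging margin (default 0.5).
#' @return data.frame with columns `accession`, `passport_group`,
#'   `nearest_group`, `passport_mean`, `nearest_mean` for flagged
#'   accessions (zero rows when none).
#' @export
flagMislabels <- function(genotypes, labels, margin = 0.5) {
  D <- if (is.matrix(genotypes)) genotypes
       else pairwiseDiscordance(genotypes)
  accs <- rownames(D)
  stopifnot(all(accs %in% names(labels)))
  grp <- labels[accs]
  sizes <- table(grp)
  empty <- data.frame(accession = character(),
                      passport_group = character(),
                      nearest_group = character(),
                      passport_mean = numeric(),
                      nearest_mean = numeric())
  if (sum(sizes >= 2L) < 2L) {
    warning("fewer than 2 labeled groups with 2 or more members; ",
            "no mislabel assessment possible")
    return(empty)
  }
  out <- list()
  for (i in seq_along(accs)) {
    own <- grp[i]
    if (sizes[[own]] < 2L) {
      warning("accession ", accs[i], " is the only member of group '",
              own, "'; skipped")
      next
    }
    means <- vapply(names(sizes), function(gname) {
      members <- setdiff(accs[grp == gname], accs[i])
      if (length(members) == 0L) return(NA_real_)
      mean(D[i, members])
    }, numeric(1))
    nearest <- names(which.min(means))
    if (nearest != own && means[[nearest]] < margin * means[[own]])
      out[[length(out) + 1L]] <- data.frame(
        accession = accs[i], passport_group = unname(own),
        nearest_group = nearest,
        passport_mean = unname(means[[own]]),
        nearest_mean = unname(means[[nearest]]))
  }
  if (length(out)) do.call(rbind, out) else empty
}
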