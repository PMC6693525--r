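#' Allele-sharing genetic distance
#'
#' For each pair of accessions, over sites co-called in both: a site
#' contributes 1 to the shared-allele fraction when the genotypes are
#' identical, 0.5 when one is heterozygous and the other homozygous, and 0
#' for opposite homozygotes. The distance is one minus the mean share.
#'
#' @param genotypes a [SpetGenotypes] with at least 2 accessions.
#' @return symmetric distance matrix with zero diagonal.
#' @export
geneticDistance <- function(genotypes) {
  g <- genoCalls(genotypes)
  stopifnot(ncol(g) >= 2L)
  n <- ncol(g)
  D <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      cc <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(cc))
        stop("zero co-called sites for pair ", colnames(g)[i], " / ",
             colnames(g)[j], call. = FALSE)
      D[i, j] <- D[j, i] <- mean(abs(g[cc, i] - g[cc, j])) / 2
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on the Q-criterion. Ties are
#' broken by the lowest node-index pair (original taxa first, then
#' internal nodes in creation order). Negative branch-length estimates are
#' clamped to zero with the deficit transferred to the sister branch, so
#' pairwise path lengths are preserved.
#'
#' @param dist symmetric distance matrix with taxon row/column names and
#'   at least 3 taxa.
#' @return an unrooted [ape::phylo] tree (basal trifurcation).
#' @export
njTree <- function(dist) {
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(dist)
  stopifnot(n >= 3L)
  taxa <- rownames(dist) %||% paste0("t", seq_len(n))
  # node bookkeeping: tips 1..n; internal nodes appended as created
  children <- list()   # per internal node id: integer children ids
  brlen <- list()      # per internal node id: branch lengths to children
  active <- seq_len(n)
  D <- dist
  rownames(D) <- colnames(D) <- as.character(active)
  next_id <- n
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (a in seq_len(m - 1L)) {
      for (b in seq((a + 1L), m)) {
        if (Q[a, b] < best_q - 1e-12) { best_q <- Q[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    d_ab <- D[a, b]
    la <- d_ab / 2 + (r[a] - r[b]) / (2 * (m - 2))
    lb <- d_ab - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    next_id <- next_id + 1L
    u <- next_id
    children[[u - n]] <- c(active[a], active[b])
    brlen[[u - n]] <- c(la, lb)
    d_new <- (D[a, ] + D[b, ] - d_ab) / 2
    d_new <- d_new[-c(a, b)]
    D <- D[-c(a, b), -c(a, b), drop = FALSE]
    D <- rbind(cbind(D, d_new), c(d_new, 0))
    active <- c(active[-c(a, b)], u)
    rownames(D) <- colnames(D) <- as.character(active)
  }
  # join the last three nodes at a central trifurcation
  x <- active[1]; y <- active[2]; z <- active[3]
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(lx, ly, lz), 0)
  next_id <- next_id + 1L
  root <- next_id
  children[[root - n]] <- c(x, y, z)
  brlen[[root - n]] <- ls
  .build_phylo(taxa, children, brlen, root)
}

# Assemble an ape phylo from the recorded merge structure.
.build_phylo <- function(taxa, children, brlen, root) {
  n <- length(taxa)
  n_internal <- length(children)
  # ape numbering: tips 1..n; internal nodes n+1.. in preorder from root
  ape_id <- integer(n + n_internal)
  ape_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edges <- matrix(0L, 0L, 2L); lens <- numeric()
  # assign preorder ids
  assign_ids <- function(node) {
    if (node <= n) return(invisible())
    counter <<- counter + 1L
    ape_id[node] <<- counter
    for (ch in children[[node - n]]) assign_ids(ch)
  }
  assign_ids(root)
  for (v in seq_len(n_internal)) {
    node <- n + v
    for (k in seq_along(children[[v]])) {
      edges <- rbind(edges, c(ape_id[node], ape_id[children[[v]][k]]))
      lens <- c(lens, brlen[[v]][k])
    }
  }
  tr <- list(edge = edges, edge.length = lens, tip.label = taxa,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Implemented by accumulating tip sets over the edge matrix (own
# traversal; ape is used only as the container).
bipartitionSet <- function(tree) {
  n <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  tipsets <- .clade_tipsets(tree)
  keys <- character()
  for (node in names(tipsets)) {
    clade <- tipsets[[node]]
    if (length(clade) < 2L || length(clade) > n - 2L) next
    side <- if (anchor %in% clade) setdiff(taxa, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# tip labels descending from each internal node (excluding the root node,
# whose clade is trivial)
.clade_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  kids <- split(edge[, 2], edge[, 1])
  sets <- list()
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    out <- unlist(lapply(kids[[as.character(node)]], rec))
    sets[[as.character(node)]] <<- out
    out
  }
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  rec(root[1])
  sets[setdiff(names(sets), as.character(root[1]))]
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of non-trivial bipartitions, plus a
#' normalized version. For two binary unrooted trees on `n` taxa the
#' normalizing constant is `2(n - 3)`; with polytomies it is the total
#' number of resolvable (internal) edges across both trees.
#'
#' @param t1,t2 [ape::phylo] trees over identical taxon sets.
#' @return list with `rf` (even integer) and `normalized` (in `[0, 1]`).
#' @export
robinsonFoulds <- function(t1, t2) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2))
    stop("taxon sets differ: ",
         paste(c(setdiff(s1, s2), setdiff(s2, s1)), collapse = ", "),
         call. = FALSE)
  b1 <- bipartitionSet(t1)
  b2 <- bipartitionSet(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  denom <- length(b1) + length(b2)
  list(rf = rf, normalized = if (denom > 0) rf / denom else 0)
}

#' Bootstrap supports for the neighbor-joining tree
#'
#' Sites are resampled with replacement `replicates` times; each replicate
#' matrix is rebuilt into an NJ tree, and the support of every internal
#' edge of the full-data tree is the percentage of replicates whose tree
#' contains the same bipartition. Supports are stored as integer node
#' labels (ape convention); the basal trifurcation carries no support.
#'
#' @param genotypes a [SpetGenotypes].
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return the full-data NJ [ape::phylo] tree with `node.label` supports.
#' @export
bootstrapSupport <- function(genotypes, replicates = 100L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  main <- njTree(geneticDistance(genotypes))
  n <- length(main$tip.label)
  main_sets <- .clade_tipsets(main)
  taxa <- sort(main$tip.label)
  anchor <- taxa[1]
  key_of <- function(clade) {
    side <- if (anchor %in% clade) setdiff(taxa, clade) else clade
    paste(sort(side), collapse = "|")
  }
  counts <- stats::setNames(numeric(length(main_sets)), names(main_sets))
  withSeed(deriveSeed(seed, 5L), {
    for (b in seq_len(replicates)) {
      idx <- sample.int(nrow(genotypes), replace = TRUE)
      rep_tree <- njTree(geneticDistance(genotypes[idx, ]))
      rep_keys <- bipartitionSet(rep_tree)
      for (nd in names(main_sets)) {
        if (key_of(main_sets[[nd]]) %in% rep_keys)
          counts[nd] <- counts[nd] + 1
      }
    }
  })
  support <- round(100 * counts / replicates)
  # node.label[i] belongs to internal node n + i
  labs <- character(main$Nnode)
  root <- setdiff(unique(main$edge[, 1]), main$edge[, 2])[1]
  for (v in seq_len(main$Nnode)) {
    node <- n + v
    labs[v] <- if (node == root) ""
               else as.character(support[[as.character(node)]])
  }
  main$node.label <- labs
  main
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are encoded as alt-allele dosage (0/1/2), missing cells are
#' imputed with the site mean, sites are centered and scaled by
#' `sqrt(p(1 - p))` with `p` the alt-allele frequency (sites monomorphic
#' after imputation are dropped by the zero-variance guard), and the
#' accession covariance is eigendecomposed via the singular value
#' decomposition.
#'
#' @param genotypes a [SpetGenotypes] with >= 2 accessions and >= 1
#'   polymorphic site.
#' @param k number of components to return (truncated to the matrix rank
#'   with a warning if larger).
#' @return a [SpetPCA].
#' @export
pcaGenotypes <- function(genotypes, k = 2L) {
  g <- genoCalls(genotypes)
  stopifnot(ncol(g) >= 2L)
  X <- t(g)  # accessions x sites
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
  p <- mu / 2
  sdv <- sqrt(p * (1 - p))
  keep <- sdv > 1e-12 & apply(X, 2L, stats::var) > 1e-12
  if (!any(keep)) stop("no polymorphic sites after imputation",
                       call. = FALSE)
  X <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  X <- sweep(X, 2L, sdv[keep], `/`)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-9
  var_frac <- sv$d^2 / sum(sv$d^2)
  rank <- sum(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(g)
  colnames(loadings) <- paste0("PC", seq_len(k))
  new("SpetPCA", loadings = loadings, varianceFraction = var_frac)
}
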