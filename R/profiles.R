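#' Z-score expression profiles
#'
#' Per gene: centre by the mean and scale by the standard deviation
#' across samples, so positive values mark samples above the gene's
#' average expression.  Constant genes cannot be scaled; they become
#' all-zero rows and are flagged.
#'
#' @param expr Numeric matrix, genes x samples (typically
#'   surrogate-corrected VST values).
#' @param genes Optional character vector of row names to restrict to.
#' @return Matrix of z-scores with attribute \code{constant} (logical
#'   vector flagging zero-variance genes).
#' @export
zscore_profiles <- function(expr, genes = NULL) {
  if (!is.null(genes)) {
    if (length(genes) == 0L) stop("empty gene set")
    missing_g <- setdiff(genes, rownames(expr))
    if (length(missing_g))
      stop("genes not in matrix: ", paste(missing_g, collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  if (nrow(expr) == 0L) stop("empty gene set")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  constant <- sdv < 1e-12
  z <- (expr - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}

#' Cluster genes by condition-level expression profiles
#'
#' Gene z-scores are first averaged over the design cells (the 8
#' factor-level combinations in the default design), then clustered
#' agglomeratively with correlation distance (1 - Pearson r between cell
#' profiles, average linkage).  The tree is cut at the k in [2, k_max]
#' maximising the mean silhouette width; clusters smaller than
#' \code{min_size} are dissolved and their genes reported as unassigned.
#' Gene order is normalised internally so memberships do not depend on
#' input order.
#'
#' @param z Z-score matrix from [zscore_profiles()], genes x samples.
#' @param design Sample design matching the columns of \code{z}.
#' @param min_size Minimum reported cluster size (default 10, >= 2).
#' @param k_max Largest number of clusters tried (default 8).
#' @param seed Integer seed (the procedure is deterministic; the seed
#'   guards any downstream stochastic use and is recorded).
#' @return List of class \code{facstress_clusters}: \code{membership}
#'   (named integer vector, NA = unassigned), \code{clusters} (list of
#'   gene-id vectors), \code{unassigned}, \code{cell_means} (clusters x
#'   cells mean z), \code{k}, \code{silhouette}.
#' @export
cluster_profiles <- function(z, design, min_size = 10L, k_max = 8L,
                             seed = 1L) {
  if (min_size < 2L) stop("'min_size' must be at least 2")
  if (ncol(z) != nrow(design))
    stop("z columns do not match design samples")
  factors <- design_factors(design)
  cell <- interaction(design[, factors, drop = FALSE], sep = ":",
                      lex.order = TRUE)
  ord <- order(rownames(z))
  z <- z[ord, , drop = FALSE]
  genes <- rownames(z)
  cell_profile <- t(apply(z, 1L, function(r) tapply(r, cell, mean)))
  colnames(cell_profile) <- levels(cell)

  empty <- function() structure(
    list(membership = stats::setNames(rep(NA_integer_, length(genes)), genes),
         clusters = list(), unassigned = genes,
         cell_means = matrix(numeric(0), 0L, ncol(cell_profile),
                             dimnames = list(NULL, colnames(cell_profile))),
         k = 0L, silhouette = NA_real_),
    class = "facstress_clusters")
  if (length(genes) < min_size) return(empty())

  cp_sd <- apply(cell_profile, 1L, stats::sd)
  cor_ok <- cp_sd > 1e-12
  d_mat <- matrix(2, length(genes), length(genes))
  if (any(cor_ok)) {
    cr <- stats::cor(t(cell_profile[cor_ok, , drop = FALSE]))
    d_mat[cor_ok, cor_ok] <- 1 - cr
  }
  diag(d_mat) <- 0
  d <- stats::as.dist(d_mat)
  if (max(d) < 1e-8) {   # all profiles share one shape: a single cluster
    membership <- stats::setNames(rep(1L, length(genes)), genes)
    return(structure(
      list(membership = membership, clusters = list(`1` = genes),
           unassigned = character(0),
           cell_means = matrix(colMeans(cell_profile), 1L,
                               dimnames = list("1", colnames(cell_profile))),
           k = 1L, silhouette = NA_real_),
      class = "facstress_clusters"))
  }
  hc <- stats::hclust(d, method = "average")

  ks <- seq(2L, max(2L, min(k_max, length(genes) - 1L)))
  sil <- vapply(ks, function(k) {
    memb <- stats::cutree(hc, k = k)
    if (length(unique(memb)) < 2L) return(-Inf)
    mean(cluster::silhouette(memb, d)[, "sil_width"])
  }, numeric(1L))
  best_k <- ks[which.max(sil)]
  memb <- stats::cutree(hc, k = best_k)

  # dissolve undersized clusters; relabel survivors compactly by size
  sizes <- table(memb)
  keep_ids <- names(sizes)[sizes >= min_size]
  membership <- rep(NA_integer_, length(genes))
  if (length(keep_ids)) {
    keep_ids <- keep_ids[order(-sizes[keep_ids], as.integer(keep_ids))]
    for (i in seq_along(keep_ids))
      membership[memb == as.integer(keep_ids[i])] <- i
  }
  names(membership) <- genes
  clusters <- split(genes[!is.na(membership)],
                    membership[!is.na(membership)])
  cell_means <- do.call(rbind, lapply(clusters, function(g)
    colMeans(cell_profile[g, , drop = FALSE])))
  structure(list(membership = membership, clusters = clusters,
                 unassigned = genes[is.na(membership)],
                 cell_means = cell_means, k = length(clusters),
                 silhouette = max(sil)),
            class = "facstress_clusters")
}
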