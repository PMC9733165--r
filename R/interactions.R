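#' @title Synergistic / antagonistic interaction classification
#' @description Under treatment coding the expected combined effect of a
#'   stressor combination is the sum of its lower-order log2 fold
#'   changes; the interaction coefficient is the additional LFC observed
#'   beyond that expectation.  An interaction that pushes expression
#'   further in the expected direction is synergistic (S+ upward, S-
#'   downward); one that pulls it back toward zero is antagonistic (A+
#'   when the expectation was upward, A- when downward).
#' @name interactions
NULL

interaction_combos <- function(factors = c("Salinity", "Sediment", "Flow")) {
  terms <- factorial_terms(factors)
  terms[grepl(":", terms, fixed = TRUE)]
}

#' Expected combined log2 fold change of a stressor combination
#'
#' For a pairwise combination A:B the expectation under no interaction is
#' \code{beta_A + beta_B}; for the three-way combination it is the sum of
#' all three main effects and all three pairwise interaction LFCs (every
#' lower-order term).
#'
#' @param fit Named coefficient vector for one gene (log2 scale), or a
#'   \code{facstress_fit} (then a genes-long vector is returned).
#' @param combo Combination name, e.g. \code{"Salinity:Flow"} or
#'   \code{"Salinity:Sediment:Flow"}.
#' @return Expected combined LFC (scalar, or vector across genes).
#' @export
expected_combined_lfc <- function(fit, combo) {
  beta <- if (inherits(fit, "facstress_fit")) fit$beta else fit
  nm <- if (is.matrix(beta)) colnames(beta) else names(beta)
  if (!combo %in% nm) stop("unknown combination: ", combo)
  parts <- strsplit(combo, ":", fixed = TRUE)[[1L]]
  lower <- nm[vapply(strsplit(nm, ":", fixed = TRUE), function(tp)
    length(tp) < length(parts) && all(tp %in% parts), logical(1L))]
  if (is.matrix(beta)) rowSums(beta[, lower, drop = FALSE])
  else sum(beta[lower])
}

#' Classify one interaction as synergistic or antagonistic
#'
#' Given the expected combined LFC and the (significant) interaction LFC:
#' an interaction with the same sign as a non-zero expectation amplifies
#' it (S+ / S-), an opposite-signed interaction dampens it (A+ / A-).
#' When the expectation is zero within \code{eps}, any deviation is
#' synergistic by convention (S+ for positive, S- for negative
#' interaction).  Callers must pre-filter by significance: an interaction
#' within \code{eps} of zero is an error.
#'
#' @param expected Expected combined LFC (log2).
#' @param interaction Interaction coefficient LFC (log2), non-zero.
#' @param eps Numerical tolerance for "zero" (default 1e-6 log2 units).
#' @return One of \code{"S+"}, \code{"S-"}, \code{"A+"}, \code{"A-"}
#'   (vectorised over inputs).
#' @export
classify_interaction <- function(expected, interaction, eps = 1e-6) {
  if (any(abs(interaction) <= eps))
    stop("interaction LFC within eps of zero; classify significant ",
         "interactions only")
  up <- interaction > 0
  cls <- ifelse(expected >= eps,  ifelse(up, "S+", "A+"),
         ifelse(expected <= -eps, ifelse(up, "A-", "S-"),
                                  ifelse(up, "S+", "S-")))
  as.character(cls)
}

#' Call and classify significant interactions from a factorial fit
#'
#' For every interaction term with adjusted p below the threshold,
#' records the expected combined LFC, the interaction LFC, and the
#' S+/S-/A+/A- class.  Shrunken LFCs may be supplied and are then used
#' for both quantities; raw coefficients are used otherwise.
#'
#' @param fit A \code{facstress_fit}.
#' @param fdr Adjusted-p threshold (default 0.1).
#' @param lfc Optional genes x terms matrix of shrunken LFCs covering all
#'   factorial terms.
#' @return data.frame with columns \code{gene_id}, \code{combo},
#'   \code{expected_lfc}, \code{interaction_lfc}, \code{class},
#'   \code{padj}.
#' @export
call_interactions <- function(fit, fdr = 0.1, lfc = NULL) {
  beta <- if (is.null(lfc)) fit$beta else lfc
  combos <- intersect(colnames(fit$padj),
                      grep(":", colnames(beta), value = TRUE, fixed = TRUE))
  out <- lapply(combos, function(cb) {
    padj <- fit$padj[, cb]
    sig <- !is.na(padj) & padj < fdr
    sig <- sig & abs(beta[, cb]) > 1e-6
    if (!any(sig)) return(NULL)
    exp_lfc <- expected_combined_lfc(
      structure(list(beta = beta[sig, , drop = FALSE]),
                class = "facstress_fit"), cb)
    data.frame(gene_id = rownames(fit$beta)[sig],
               combo = cb,
               expected_lfc = unname(exp_lfc),
               interaction_lfc = unname(beta[sig, cb]),
               class = classify_interaction(exp_lfc, beta[sig, cb]),
               padj = unname(padj[sig]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), combo = character(),
                      expected_lfc = numeric(), interaction_lfc = numeric(),
                      class = character(), padj = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate interaction calls per class and combination
#'
#' Counts of S+/S-/A+/A- genes per stressor combination, with
#' per-combination totals, in the conventional column order (pairwise
#' combinations then the three-way).
#'
#' @param calls data.frame from [call_interactions()].
#' @param factors Design factor names (sets the column order).
#' @return Integer matrix, rows S+, S-, A+, A-, Total; one column per
#'   combination.
#' @export
tabulate_interactions <- function(calls,
                                  factors = c("Salinity", "Sediment", "Flow")) {
  combos <- interaction_combos(factors)
  # pairwise combinations alphabetically, then the full interaction
  ord <- order(vapply(strsplit(combos, ":"), length, 1L), combos)
  combos <- combos[ord]
  classes <- c("S+", "S-", "A+", "A-")
  tab <- matrix(0L, length(classes) + 1L, length(combos),
                dimnames = list(c(classes, "Total"), combos))
  if (nrow(calls)) {
    ct <- table(factor(calls$class, levels = classes),
                factor(calls$combo, levels = combos))
    tab[classes, ] <- as.integer(ct)
    tab["Total", ] <- colSums(tab[classes, , drop = FALSE])
  }
  tab
}

#' Exclusive intersections of gene sets
#'
#' Assigns every gene in the union of the input sets to exactly one
#' membership signature (the exact subset of sets containing it), as in
#' an UpSet plot: signatures are pairwise disjoint and jointly cover the
#' union.
#'
#' @param sets Named list of character vectors (at most 16 sets).
#' @return data.frame with columns \code{signature} (set names joined by
#'   \code{"&"}), \code{count}, and \code{genes} (list column), sorted by
#'   decreasing count.
#' @export
exclusive_intersections <- function(sets) {
  if (length(sets) > 16L) stop("at most 16 sets supported")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0L)
    return(data.frame(signature = character(), count = integer(),
                      genes = I(list())))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  sig <- apply(member, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  split_genes <- split(universe, sig)
  out <- data.frame(signature = names(split_genes),
                    count = lengths(split_genes),
                    stringsAsFactors = FALSE)
  out$genes <- I(unname(split_genes))
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treatment dendrogram from shrunken LFC profiles
#'
#' Average-linkage hierarchical clustering of the treatment combinations,
#' using Euclidean distances between their per-gene shrunken-LFC columns.
#' Non-significant entries should be zeroed beforehand so the distance
#' matrix is complete.
#'
#' @param lfc Numeric matrix, genes x treatments (>= 2 columns, no NAs).
#' @return An [stats::hclust] object.
#' @export
lfc_treatment_tree <- function(lfc) {
  if (ncol(lfc) < 2L) stop("at least two treatment columns required")
  if (anyNA(lfc)) stop("missing values; zero non-significant entries first")
  d <- stats::dist(t(lfc), method = "euclidean")
  stats::hclust(d, method = "average")
}
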