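#' @title Ontology-aware over-representation analysis
#' @description Gene-set enrichment over a term DAG: annotations are
#'   propagated to ancestors under the true-path rule, each term is
#'   tested with a one-sided hypergeometric (Fisher) test, and an
#'   elim-style pass from the leaves upward removes the genes of
#'   significant child terms from their ancestors' tests, decorrelating
#'   nested terms.
#' @name enrichment
NULL

#' Build an ontology DAG object
#'
#' @param edges data.frame with columns \code{child}, \code{parent}
#'   (directed child-to-parent term edges); may have zero rows for a flat
#'   ontology.
#' @param annotation data.frame with columns \code{gene}, \code{term}
#'   (direct annotations).
#' @return List of class \code{facstress_dag}: \code{terms},
#'   \code{parents} (term -> character vector), \code{ann} (term ->
#'   gene-id vector), \code{propagated} flag.
#' @export
ontology_dag <- function(edges, annotation) {
  if (nrow(edges) && !all(c("child", "parent") %in% names(edges)))
    stop("edges need 'child' and 'parent' columns")
  if (!all(c("gene", "term") %in% names(annotation)))
    stop("annotation needs 'gene' and 'term' columns")
  terms <- sort(unique(c(edges$child, edges$parent, annotation$term)))
  parents <- lapply(stats::setNames(terms, terms), function(tm)
    unique(edges$parent[edges$child == tm]))
  ann <- lapply(stats::setNames(terms, terms), function(tm)
    unique(annotation$gene[annotation$term == tm]))
  dag <- structure(list(terms = terms, parents = parents, ann = ann,
                        propagated = FALSE),
                   class = "facstress_dag")
  topo_order(dag)  # errors on cycles
  dag
}

# Topological order with children before parents (leaves first).
# Kahn's algorithm on child->parent edges; a leftover node means a cycle.
topo_order <- function(dag) {
  terms <- dag$terms
  children_of <- lapply(stats::setNames(terms, terms), function(x) character(0))
  indeg <- stats::setNames(integer(length(terms)), terms)  # unprocessed children
  for (tm in terms) {
    for (p in dag$parents[[tm]]) {
      if (p == tm) stop("cycle detected: ", tm, " -> ", tm)
      children_of[[p]] <- c(children_of[[p]], tm)
      indeg[p] <- indeg[p] + 1L
    }
  }
  queue <- terms[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    tm <- queue[1L]; queue <- queue[-1L]
    out <- c(out, tm)
    for (p in dag$parents[[tm]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) < length(terms)) {
    bad <- setdiff(terms, out)
    stop("cycle detected involving: ", paste(bad, collapse = ", "))
  }
  out
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' Every gene annotated to a term becomes annotated to all its ancestors,
#' with set semantics (a gene reachable through several paths of a
#' diamond is counted once).
#'
#' @param dag A \code{facstress_dag} from [ontology_dag()].
#' @return The DAG with propagated annotations (\code{propagated = TRUE}).
#' @export
propagate_annotations <- function(dag) {
  ord <- topo_order(dag)   # children first, so one sweep suffices
  ann <- dag$ann
  for (tm in ord) {
    for (p in dag$parents[[tm]])
      ann[[p]] <- unique(c(ann[[p]], ann[[tm]]))
  }
  dag$ann <- ann
  dag$propagated <- TRUE
  dag
}

#' One-sided Fisher (hypergeometric) over-representation test
#'
#' Upper-tail probability of drawing at least the observed overlap:
#' with universe size N, K universe genes annotated to the term, and a
#' study set of size n overlapping the term in k genes,
#' p = P(X >= k) for X hypergeometric(N, K, n).
#'
#' @param study Character vector of study genes (must lie in the universe).
#' @param universe Character vector; the gene universe (all tested genes).
#' @param term_genes Genes annotated to the term (intersected with the
#'   universe before testing).
#' @return p-value in [0, 1].
#' @export
fisher_term <- function(study, universe, term_genes) {
  study <- unique(study); universe <- unique(universe)
  if (!all(study %in% universe))
    stop("study set contains genes outside the universe")
  K_genes <- intersect(term_genes, universe)
  k <- length(intersect(study, K_genes))
  stats::phyper(k - 1L, length(K_genes),
                length(universe) - length(K_genes), length(study),
                lower.tail = FALSE)
}

#' Elim-style DAG-decorrelated enrichment
#'
#' Terms are processed from the leaves upward (reverse topological
#' order).  Each term is first scored with the plain Fisher test on its
#' full propagated annotation; if its current (elim-adjusted) p-value is
#' below \code{alpha_elim}, the study genes of the term are removed from
#' the annotation of all its ancestors before those are tested, so a
#' parent significant only through a significant child loses that
#' support.
#'
#' @param dag Propagated \code{facstress_dag}.
#' @param study Study gene set.
#' @param universe Gene universe (all genes tested for differential
#'   expression).
#' @param alpha_elim Elimination threshold (default 0.01); 0 disables
#'   elimination.
#' @return data.frame with one row per annotated term: \code{term},
#'   \code{k} (study hits), \code{n} (study size), \code{K} (term genes
#'   in universe), \code{N} (universe size), \code{p_fisher},
#'   \code{p_elim}, sorted by \code{p_elim}.
#' @export
elim_enrichment <- function(dag, study, universe, alpha_elim = 0.01) {
  if (!isTRUE(dag$propagated))
    stop("annotations must be propagated first (see propagate_annotations)")
  study <- unique(study); universe <- unique(universe)
  if (!all(study %in% universe))
    stop("study set contains genes outside the universe")

  ord <- topo_order(dag)
  ancestors <- ancestor_map(dag, ord)
  removed <- lapply(stats::setNames(dag$terms, dag$terms),
                    function(x) character(0))
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    tm <- ord[i]
    term_univ <- intersect(dag$ann[[tm]], universe)
    p_raw <- fisher_term(study, universe, term_univ)
    term_elim <- setdiff(term_univ, removed[[tm]])
    p_elim <- fisher_term(study, universe, term_elim)
    k <- length(intersect(study, term_elim))
    rows[[i]] <- data.frame(term = tm, k = k, n = length(study),
                            K = length(term_elim), N = length(universe),
                            p_fisher = p_raw, p_elim = p_elim,
                            stringsAsFactors = FALSE)
    if (alpha_elim > 0 && p_elim < alpha_elim) {
      hits <- intersect(study, term_elim)
      for (a in ancestors[[tm]])
        removed[[a]] <- unique(c(removed[[a]], hits))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_elim, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# term -> all ancestors; parents must be resolved before their children,
# so iterate the topological order reversed (roots first).
ancestor_map <- function(dag, ord = topo_order(dag)) {
  anc <- lapply(stats::setNames(dag$terms, dag$terms),
                function(x) character(0))
  for (tm in rev(ord)) {
    direct <- dag$parents[[tm]]
    anc[[tm]] <- unique(c(direct, unlist(anc[direct], use.names = FALSE)))
  }
  anc
}
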