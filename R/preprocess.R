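#' Summarise transcript-level counts to gene level
#'
#' Gene counts are the sum of member transcript estimated counts per
#' sample, so column totals are conserved exactly.  The per-gene,
#' per-sample average effective length is the mean of member transcript
#' lengths weighted by transcript abundance (count divided by length);
#' when all member transcripts of a gene have zero counts in a sample the
#' unweighted mean length is used.
#'
#' @param tx Transcript table from [simulate_counts()] or
#'   [read_transcript_counts()]: columns \code{transcript_id},
#'   \code{gene_id}, \code{effective_length}, then one column per sample.
#' @return List of class \code{facstress_genes} with elements
#'   \code{counts} (genes x samples numeric matrix), \code{eff_length}
#'   (matching matrix of average effective lengths) and \code{gene_id}.
#' @export
summarise_to_gene <- function(tx) {
  meta <- c("transcript_id", "gene_id", "effective_length")
  if (!all(meta %in% names(tx)))
    stop("transcript table must have transcript_id, gene_id, effective_length")
  orphan <- is.na(tx$gene_id) | tx$gene_id == ""
  if (any(orphan))
    stop("transcripts without a gene id: ",
         paste(tx$transcript_id[orphan], collapse = ", "))
  if (any(tx$effective_length <= 0))
    stop("effective lengths must be positive")

  samples <- setdiff(names(tx), meta)
  m <- as.matrix(tx[, samples, drop = FALSE])
  if (any(m < 0)) stop("negative counts are not allowed")
  gene <- factor(tx$gene_id, levels = unique(tx$gene_id))

  counts <- rowsum(m, gene)
  # abundance weights: count / length; weighted mean length =
  # sum(w * len) / sum(w) = counts / sum(count / length)
  rate <- rowsum(m / tx$effective_length, gene)
  lens <- counts / rate
  fallback <- rowsum(matrix(tx$effective_length, ncol = 1L), gene)[, 1L] /
    tabulate(gene)
  zero <- rate == 0
  if (any(zero))
    lens[zero] <- matrix(fallback, nrow(lens), ncol(lens))[zero]

  structure(list(counts = counts, eff_length = lens,
                 gene_id = levels(gene)),
            class = "facstress_genes")
}

gene_count_matrix <- function(gc) {
  if (inherits(gc, "facstress_genes")) gc$counts else as.matrix(gc)
}

#' Median-of-ratios size factors
#'
#' The reference profile is the per-gene geometric mean across samples,
#' using only genes with strictly positive counts in every sample; each
#' sample's size factor is the median across those genes of the ratio of
#' its count to the reference, rescaled so the size factors have
#' geometric mean 1.
#'
#' @param gc Gene counts ([summarise_to_gene()] result or a matrix).
#' @return Named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(gc) {
  m <- gene_count_matrix(gc)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in all samples; pre-filter the matrix")
  lm_ <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm_)
  sf <- exp(apply(lm_ - ref, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Independent expression filter on normalised counts
#'
#' Keeps genes whose normalised count (raw count divided by the sample's
#' size factor) reaches \code{min_count} in at least \code{min_samples}
#' samples; gene order is preserved.
#'
#' @param gc Gene counts object or matrix.
#' @param sf Size factors from [size_factors()].
#' @param min_count Normalised-count threshold (default 10).
#' @param min_samples Minimum number of qualifying samples (default 8).
#' @return Object of the same type as \code{gc}, restricted to the
#'   retained genes.
#' @export
filter_genes <- function(gc, sf, min_count = 10, min_samples = 8L) {
  m <- gene_count_matrix(gc)
  if (length(sf) != ncol(m))
    stop("size factors do not match samples")
  if (min_samples > ncol(m))
    stop("'min_samples' exceeds the number of samples")
  norm <- sweep(m, 2L, sf, `/`)
  keep <- rowSums(norm >= min_count) >= min_samples
  if (inherits(gc, "facstress_genes")) {
    structure(list(counts = gc$counts[keep, , drop = FALSE],
                   eff_length = gc$eff_length[keep, , drop = FALSE],
                   gene_id = gc$gene_id[keep]),
              class = "facstress_genes")
  } else {
    m[keep, , drop = FALSE]
  }
}

#' Shifted-log variance-stabilising transform
#'
#' \code{log2(count / size_factor + 1)}: monotone in counts, finite, and
#' invariant to rescaling counts and size factors together.  Used for
#' surrogate estimation, frozen correction and profile clustering.
#'
#' @inheritParams filter_genes
#' @return Numeric matrix of transformed values, genes x samples.
#' @export
vst <- function(gc, sf) {
  m <- gene_count_matrix(gc)
  if (length(sf) != ncol(m) || any(sf <= 0))
    stop("size factors must be positive, one per sample")
  log2(sweep(m, 2L, sf, `/`) + 1)
}
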