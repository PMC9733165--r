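#' Estimate latent surrogate variables by residual SVD
#'
#' Expression (variance-stabilised, genes x samples) is residualised on
#' the full factorial design; the right singular vectors of the residual
#' matrix are candidate surrogates.  The number retained, k, is decided
#' by a permutation ("parallel analysis") test: each gene's residual row
#' is permuted independently \code{n_perm} times, and the i-th component
#' is significant when its variance share exceeds the (1 - alpha)
#' quantile of the permuted i-th shares, counting leading components only.
#' Because residuals are orthogonal to the intercept, every surrogate has
#' zero mean, and SVD makes them mutually orthogonal.
#'
#' @param expr Numeric matrix, genes x samples (e.g. from [vst()]).
#' @param design Sample design; columns must match \code{expr} columns.
#' @param n_perm Number of row permutations (>= 20, default 100).
#' @param alpha Significance level for the permutation test (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return Object of class \code{facstress_sv}: list with \code{sv}
#'   (samples x k matrix, possibly k = 0), \code{var_share},
#'   \code{null_quantile} and \code{k}.
#' @export
estimate_surrogates <- function(expr, design, n_perm = 100L, alpha = 0.05,
                                seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_perm < 20L) stop("'n_perm' must be at least 20")
  if (ncol(expr) != nrow(design))
    stop("expression columns do not match design samples")
  mm <- build_model_matrix(design)
  res <- residualise(expr, mm)

  max_k <- min(nrow(res), ncol(res) - ncol(mm))
  empty <- structure(list(sv = matrix(numeric(0), nrow = ncol(expr), ncol = 0),
                          var_share = numeric(0), null_quantile = numeric(0),
                          k = 0L),
                     class = "facstress_sv")
  if (max_k < 1L || sum(res^2) < 1e-12) return(empty)

  sv_full <- svd(res, nu = 0)
  share <- sv_full$d^2 / sum(sv_full$d^2)

  n_comp <- min(length(share), max_k)
  # Null: permute each gene's residuals independently, then re-residualise
  # on the design so the null spectrum carries the same rank constraint.
  qr_mm <- qr(mm)
  null_share <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- t(apply(res, 1L, sample))
      perm <- t(qr.resid(qr_mm, t(perm)))
      d2 <- svd(perm, nu = 0, nv = 0)$d^2
      (d2 / sum(d2))[seq_len(n_comp)]
    }, numeric(n_comp))
  })
  null_share <- matrix(null_share, nrow = n_comp)
  qs <- apply(null_share, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)

  sig <- share[seq_len(n_comp)] > qs
  k <- if (sig[1L]) which.min(c(sig, FALSE)) - 1L else 0L
  if (k == 0L) return(empty)

  sv <- sv_full$v[, seq_len(k), drop = FALSE]
  rownames(sv) <- design$sample_id
  colnames(sv) <- paste0("SV", seq_len(k))
  structure(list(sv = sv, var_share = share[seq_len(n_comp)],
                 null_quantile = qs, k = k),
            class = "facstress_sv")
}

# Residuals of each gene (row) regressed on the sample-level design matrix.
residualise <- function(expr, mm) {
  qr_ <- qr(mm)
  t(qr.resid(qr_, t(expr)))
}

#' Frozen surrogate-variable correction
#'
#' For visualisation and clustering: each gene is fit by least squares on
#' the combined design-plus-surrogate matrix, and only the fitted
#' surrogate contribution is subtracted, so design-attributable signal is
#' retained.  With no surrogates the input is returned unchanged.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param design Sample design.
#' @param sv Surrogate set from [estimate_surrogates()] (or a matrix).
#' @return Corrected matrix with the same dimensions as \code{expr}.
#' @export
freeze_correct <- function(expr, design, sv) {
  svmat <- surrogate_matrix(sv)
  if (is.null(svmat)) return(expr)
  mm <- build_model_matrix(design, sv)   # validates rank
  coef <- qr.coef(qr(mm), t(expr))       # terms x genes
  sv_cols <- colnames(svmat)
  corrected <- expr - t(mm[, sv_cols, drop = FALSE] %*%
                          coef[sv_cols, , drop = FALSE])
  dimnames(corrected) <- dimnames(expr)
  corrected
}
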