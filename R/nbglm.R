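#' @title Negative-binomial GLM inference over the factorial design
#' @description Per-gene negative-binomial generalised linear models with
#'   log link and size-factor offsets, fit by Fisher-scoring IRLS with a
#'   fixed per-gene dispersion, Wald tests per model term,
#'   Benjamini-Hochberg adjustment within each term family, and adaptive
#'   (scale-mixture-of-normals) shrinkage of log2 fold changes.
#' @name nb-inference
NULL

#' Per-gene dispersion estimate
#'
#' A method-of-moments start followed (by default) by a Cox-Reid
#' adjusted profile-likelihood refinement.  The moment step fits a
#' Poisson GLM and converts the Pearson-residual excess into a
#' negative-binomial dispersion:
#' \eqn{\hat\alpha = (\sum r^2_P - df_{resid}) / \sum \hat\mu}, floored
#' at 1e-8 (under variance \eqn{\mu + \alpha\mu^2} the expected squared
#' Pearson residual is \eqn{1 + \alpha\mu}).  The refinement maximises
#' the NB profile log-likelihood in \eqn{\log\alpha} at the fitted means,
#' penalised by half the log-determinant of the Fisher information, which
#' counters the downward bias of plain ML when eight or more mean
#' parameters are estimated from 64 samples.
#'
#' @param counts Numeric vector of (estimated, possibly non-integer)
#'   counts for one gene.
#' @param mm Model matrix from [build_model_matrix()].
#' @param sf Size factors.
#' @param floor Lower bound for the estimate (default 1e-8).
#' @param refine Apply the Cox-Reid refinement (default FALSE, i.e. the
#'   moment estimate; the refinement gives a less noisy but slightly
#'   conservative estimate).
#' @return Positive scalar dispersion.
#' @export
estimate_dispersion <- function(counts, mm, sf, floor = 1e-8,
                                refine = FALSE) {
  df_resid <- length(counts) - ncol(mm)
  if (df_resid <= 0) stop("no residual degrees of freedom")
  fit <- nb_irls(counts, mm, sf, alpha = 0)
  mu <- fit$mu
  pearson <- sum((counts - mu)^2 / mu)
  a_mom <- max(floor, (pearson - df_resid) / sum(mu))
  if (!refine) return(a_mom)

  nb_fit <- nb_irls(counts, mm, sf, alpha = a_mom)
  mu <- pmax(nb_fit$mu, 1e-8)
  apl <- function(la) {
    a <- exp(la)
    w <- mu / (1 + a * mu)
    nb_loglik(counts, mu, a) -
      0.5 * as.numeric(determinant(crossprod(mm, mm * w))$modulus)
  }
  a_hat <- exp(stats::optimize(apl, c(log(1e-8), log(10)),
                               maximum = TRUE)$maximum)
  max(floor, a_hat)
}

# NB2 log-likelihood by the gamma-function form, valid for real-valued
# (estimated) counts; reduces to Poisson as alpha -> 0.
nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10)
    return(sum(y * log(mu) - mu - lgamma(y + 1)))
  r <- 1 / alpha
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        y * log(alpha * mu / (1 + alpha * mu)) - r * log1p(alpha * mu))
}

# IRLS core on the natural-log scale.  alpha = 0 gives Poisson.
# Weights mu/(1 + alpha*mu) are the Fisher information weights of the
# NB2 log-link GLM; covariance is the inverse weighted cross-product.
nb_irls <- function(y, X, sf, alpha, max_iter = 100L, tol = 1e-8) {
  offset <- log(sf)
  mu <- pmax(y, 0.1)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    wx <- X * w
    xtwx <- crossprod(X, wx)
    beta_new <- tryCatch(
      solve(xtwx, crossprod(wx, z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)   # guard against separation blow-up
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w)
  cov <- tryCatch(solve(xtwx), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), mu = mu,
       iter = iter, converged = converged)
}

#' Fit the negative-binomial GLM for one gene
#'
#' Maximises the NB log-likelihood with log link and offset
#' \code{log(sf)} by iteratively reweighted least squares (at most 100
#' iterations; convergence when the largest natural-log coefficient change
#' falls below 1e-8).  Coefficients and standard errors are reported in
#' log2 units.  Quasi-separated genes (a design cell with all-zero
#' counts) produce clamped coefficients (|LFC| capped at 10 log2 units)
#' and are flagged rather than dropped.
#'
#' @param counts Count vector for one gene (non-negative reals accepted).
#' @param mm Model matrix.
#' @param sf Size factors.
#' @param alpha Fixed positive dispersion for this gene.
#' @return List with \code{beta} (log2), \code{se} (log2), \code{z},
#'   \code{p}, \code{mu}, \code{iter}, \code{converged}, \code{flagged}.
#' @export
fit_nb_glm <- function(counts, mm, sf, alpha) {
  if (alpha <= 0) stop("'alpha' must be positive")
  if (any(counts < 0)) stop("negative counts")
  fit <- nb_irls(counts, mm, sf, alpha)
  ln2 <- log(2)
  beta2 <- fit$beta / ln2
  se2 <- fit$se / ln2
  flagged <- FALSE
  clamp <- !is.na(beta2) & abs(beta2) > 10 & seq_along(beta2) > 1L
  if (any(clamp)) {
    beta2[clamp] <- sign(beta2[clamp]) * 10
    flagged <- TRUE
  }
  if (!fit$converged || anyNA(se2) || any(se2 <= 0)) flagged <- TRUE
  names(beta2) <- names(se2) <- colnames(mm)
  wt <- wald_test(list(beta = beta2, se = se2))
  list(beta = beta2, se = se2, z = wt$z, p = wt$p, mu = fit$mu,
       iter = fit$iter, converged = fit$converged, flagged = flagged)
}

#' Wald test of GLM coefficients
#'
#' \code{z = beta / se}; two-sided p-value from the standard normal.
#'
#' @param fit List with elements \code{beta} and \code{se} (either a
#'   single-gene fit or vectors across genes).
#' @param term Optional term name to extract a single test.
#' @return List with \code{z} and \code{p} (vectors, or scalars if
#'   \code{term} given).
#' @export
wald_test <- function(fit, term = NULL) {
  beta <- fit$beta
  se <- fit$se
  if (!is.null(term)) {
    if (!term %in% names(beta)) stop("unknown term: ", term)
    beta <- beta[[term]]
    se <- se[[term]]
  }
  bad <- !is.na(se) & se <= 0
  if (any(bad)) stop("zero standard error in Wald test")
  z <- beta / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (with monotonicity
#' enforcement), applied within one family of tests.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1]; NAs pass through.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Fit the factorial NB model across all genes
#'
#' Driver: estimates a per-gene dispersion (unless supplied), fits the
#' NB GLM per gene, computes Wald statistics for every non-intercept
#' term, and adjusts p-values per term family across genes.  Because the
#' dispersion entering each standard error is itself estimated from the
#' gene's residual degrees of freedom, the Wald statistic follows a t
#' rather than a normal distribution in finite samples; p-values
#' therefore use a t reference with \code{df} degrees of freedom
#' (default: residual df, n - p), which keeps the null calibrated at
#' 64 samples where the normal reference is visibly anti-conservative.
#'
#' @param gc Gene counts ([summarise_to_gene()] result or matrix),
#'   already filtered.
#' @param mm Model matrix from [build_model_matrix()].
#' @param sf Size factors.
#' @param dispersions Optional per-gene dispersions; estimated by
#'   [estimate_dispersion()] when NULL.
#' @param df Degrees of freedom of the t reference distribution for the
#'   per-gene tests; \code{Inf} gives the asymptotic normal reference.
#' @return Object of class \code{facstress_fit}: list of gene x term
#'   matrices \code{beta}, \code{se}, \code{z}, \code{p}, \code{padj}
#'   (padj only for non-intercept terms), plus vectors
#'   \code{dispersion}, \code{converged}, \code{flagged} and the inputs
#'   \code{mm}, \code{sf}, \code{df}.
#' @export
fit_factorial_nb <- function(gc, mm, sf, dispersions = NULL,
                             df = nrow(mm) - ncol(mm)) {
  m <- gene_count_matrix(gc)
  n_genes <- nrow(m)
  terms <- colnames(mm)
  if (is.null(dispersions)) {
    dispersions <- vapply(seq_len(n_genes), function(g)
      estimate_dispersion(m[g, ], mm, sf), numeric(1L))
  }
  beta <- se <- matrix(NA_real_, n_genes, length(terms),
                       dimnames = list(rownames(m), terms))
  converged <- flagged <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    f <- fit_nb_glm(m[g, ], mm, sf, dispersions[g])
    beta[g, ] <- f$beta
    se[g, ] <- f$se
    converged[g] <- f$converged
    flagged[g] <- f$flagged
  }
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df = df)
  test_terms <- setdiff(terms, "Intercept")
  padj <- p[, test_terms, drop = FALSE]
  for (tm in test_terms) padj[, tm] <- adjust_bh(p[, tm])
  structure(list(beta = beta, se = se, z = z, p = p, padj = padj,
                 dispersion = dispersions, converged = converged,
                 flagged = flagged, mm = mm, sf = sf, df = df),
            class = "facstress_fit")
}

#' Adaptive shrinkage of log fold changes
#'
#' Fits a zero-centred scale-mixture-of-normals prior (including a point
#' mass at zero) to the observed estimates and standard errors by EM on
#' the marginal likelihood \eqn{\hat\beta_g \sim N(0, \tau_k^2 + se_g^2)},
#' then returns each gene's posterior-mean LFC.  The default grid is 0
#' plus a geometric ladder from min(se)/10 to 2 max|beta| with ratio
#' sqrt(2), mirroring the adaptive-shrinkage construction.
#'
#' @param betas Estimated coefficients (log2 scale) across genes, one term.
#' @param ses Matching positive standard errors.
#' @param grid Mixture component standard deviations; must include 0.
#' @param weights Optional fixed mixture weights (same length as
#'   \code{grid}, summing to 1); when given the EM step is skipped and
#'   the prior is used as supplied.
#' @param tol EM stops when the log-likelihood gain drops below this
#'   (default 1e-8) or after \code{max_iter} iterations.
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List of class \code{facstress_ash}: \code{posterior_mean},
#'   \code{posterior_sd}, \code{grid}, \code{weights}, \code{loglik}.
#' @export
shrink_lfc <- function(betas, ses, grid = NULL, weights = NULL, tol = 1e-8,
                       max_iter = 1000L) {
  if (any(!is.na(ses) & ses <= 0)) stop("standard errors must be positive")
  ok <- !is.na(betas) & !is.na(ses)
  if (!any(ok)) stop("no usable estimates")
  if (is.null(grid)) {
    lo <- min(ses[ok]) / 10
    hi <- max(2 * max(abs(betas[ok])), lo * 2)
    grid <- c(0, lo * sqrt(2)^(0:ceiling(2 * log2(hi / lo))))
  }
  if (length(grid) == 0L) stop("empty mixture grid")
  if (!any(grid == 0)) stop("grid must include a point mass at 0")
  if (is.null(weights)) {
    grid <- sort(unique(grid))
  } else {
    if (length(weights) != length(grid) || abs(sum(weights) - 1) > 1e-8)
      stop("'weights' must match 'grid' and sum to 1")
    ord <- order(grid)
    grid <- grid[ord]
    weights <- weights[ord]
  }

  b <- betas[ok]
  s <- ses[ok]
  K <- length(grid)
  # marginal density of each observation under each component
  var_mat <- outer(s^2, grid^2, `+`)           # genes x K
  dens <- stats::dnorm(matrix(b, length(b), K), 0, sqrt(var_mat))
  dens <- pmax(dens, 1e-300)

  if (is.null(weights)) {
    w <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      num <- sweep(dens, 2L, w, `*`)
      marg <- rowSums(num)
      ll <- sum(log(marg))
      resp <- num / marg
      w <- colMeans(resp)
      if (ll - ll_old < tol) break
      ll_old <- ll
    }
  } else {
    w <- weights
    num <- sweep(dens, 2L, pmax(w, 1e-300), `*`)
    marg <- rowSums(num)
    ll <- sum(log(marg))
    resp <- num / marg
  }

  shrink_factor <- (var_mat - s^2) / var_mat   # tau^2 / (tau^2 + se^2)
  post_mean_k <- b * shrink_factor
  pm <- rowSums(resp * post_mean_k)
  post_var_k <- shrink_factor * s^2
  psd <- sqrt(pmax(rowSums(resp * (post_var_k + post_mean_k^2)) - pm^2, 0))

  posterior_mean <- rep(NA_real_, length(betas))
  posterior_sd <- rep(NA_real_, length(betas))
  posterior_mean[ok] <- pm
  posterior_sd[ok] <- psd
  names(posterior_mean) <- names(posterior_sd) <- names(betas)
  structure(list(posterior_mean = posterior_mean, posterior_sd = posterior_sd,
                 grid = grid, weights = w, loglik = ll),
            class = "facstress_ash")
}

#' Shrunken LFC matrix for all tested terms of a factorial fit
#'
#' Runs [shrink_lfc()] separately per model term (each term has its own
#' effect-size distribution) and assembles a genes x terms matrix.
#'
#' @param fit A \code{facstress_fit} from [fit_factorial_nb()].
#' @param terms Terms to shrink (default: all non-intercept factorial terms).
#' @return Numeric matrix of posterior-mean LFCs, genes x terms.
#' @export
shrink_fit <- function(fit, terms = NULL) {
  if (is.null(terms))
    terms <- setdiff(colnames(fit$beta), c("Intercept",
      grep("^SV[0-9]+$", colnames(fit$beta), value = TRUE)))
  out <- sapply(terms, function(tm)
    shrink_lfc(fit$beta[, tm], fit$se[, tm])$posterior_mean)
  out <- matrix(out, nrow = nrow(fit$beta),
                dimnames = list(rownames(fit$beta), terms))
  out
}
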