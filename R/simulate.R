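#' @title Synthetic factorial negative-binomial data generator
#' @description Generates transcript-level estimated counts under a
#'   log-linear negative-binomial model on a full-factorial stressor
#'   design, with known (recorded) ground truth: main-effect and
#'   interaction log2 fold changes of prescribed synergistic/antagonistic
#'   class, per-gene dispersions, a latent binary batch crossed with the
#'   design, per-sample size factors, and multi-isoform genes with
#'   abundance-weighted effective lengths.
#' @name synthetic-data
NULL

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Default configuration for the truth-table sampler
#'
#' Effect sizes are drawn with random sign from N(1, 0.25^2) log2 units,
#' dispersions from a log-normal with median 0.1, and baseline means
#' log-uniformly between 5 and 5000 counts, so the expression range spans
#' the standard independent filter boundary.  30% of genes carry a latent
#' batch loading.  Any entry may be overridden.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of generator parameters.
#' @export
effect_config <- function(...) {
  cfg <- list(
    frac_de          = 0.10,  # genes with main effects only
    frac_interaction = 0.05,  # genes with an injected interaction class
    effect_mean      = 1.0,   # |log2 FC| location
    effect_sd        = 0.25,
    disp_meanlog     = log(0.1),
    disp_sdlog       = 0.5,
    mean_range       = c(5, 5000),
    batch_frac       = 0.30,
    batch_strength   = 1.0,
    class_mix        = c("S+" = 0.25, "S-" = 0.25, "A+" = 0.25, "A-" = 0.25),
    combo_mix        = NULL   # default: uniform over pairwise + three-way
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown effect_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

# |effect| ~ N(mean, sd^2), truncated away from zero, with the given sign.
draw_effect <- function(n, cfg, sign = NULL) {
  m <- abs(stats::rnorm(n, cfg$effect_mean, cfg$effect_sd))
  m <- pmax(m, 0.1)
  if (is.null(sign)) sign <- sample(c(-1, 1), n, replace = TRUE)
  sign * m
}

#' Sample a ground-truth coefficient table
#'
#' Draws per-gene model coefficients for the factorial negative-binomial
#' model: intercept (log2 baseline mean at all-ambient levels), main
#' effects, pairwise and three-way interaction log2 fold changes,
#' dispersion, and a latent batch loading.  A configurable fraction of
#' genes receives an interaction of known class: for an injected class
#' the sign pattern of main and interaction coefficients is constructed
#' so that re-deriving the class from the true coefficients with
#' [classify_interaction()] returns the stored label.
#'
#' @param n_genes Number of genes.
#' @param config List from [effect_config()].
#' @param seed Integer seed (mandatory; the draw is reproducible).
#' @param factors Design factor names (default Salinity, Sediment, Flow).
#' @return A data.frame (class \code{facstress_truth}) with columns
#'   \code{gene_id}, \code{beta0}, one \code{beta_<term>} per model term,
#'   \code{dispersion}, \code{batch_loading}, \code{status} (null / DE /
#'   interaction), \code{combo} and \code{class}.
#' @export
sample_truth <- function(n_genes, config = effect_config(), seed,
                         factors = c("Salinity", "Sediment", "Flow")) {
  if (missing(seed)) stop("'seed' is required")
  if (n_genes < 1) stop("'n_genes' must be positive")
  fr <- c(config$frac_de, config$frac_interaction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("fractions must lie in [0,1] and sum to at most 1")
  if (abs(sum(config$class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")

  terms <- factorial_terms(factors)
  pair_combos <- terms[vapply(strsplit(terms, ":"), length, 1L) == 2L]
  three_combo <- terms[vapply(strsplit(terms, ":"), length, 1L) == 3L]
  combos <- c(pair_combos, three_combo)
  combo_mix <- config$combo_mix
  if (is.null(combo_mix)) combo_mix <- rep(1 / length(combos), length(combos))

  with_seed(seed, {
    beta <- matrix(0, n_genes, length(terms),
                   dimnames = list(NULL, terms))
    lr <- log(config$mean_range)
    beta0 <- log2(exp(stats::runif(n_genes, lr[1L], lr[2L])))
    dispersion <- stats::rlnorm(n_genes, config$disp_meanlog, config$disp_sdlog)
    batch_loading <- numeric(n_genes)
    loaded <- stats::runif(n_genes) < config$batch_frac
    batch_loading[loaded] <- draw_effect(sum(loaded),
      utils::modifyList(config, list(effect_mean = config$batch_strength)))

    n_int <- round(config$frac_interaction * n_genes)
    n_de  <- round(config$frac_de * n_genes)
    status <- rep("null", n_genes)
    pick <- sample.int(n_genes, n_int + n_de)
    status[pick[seq_len(n_int)]] <- "interaction"
    if (n_de > 0) status[pick[n_int + seq_len(n_de)]] <- "DE"

    combo <- rep(NA_character_, n_genes)
    class <- rep(NA_character_, n_genes)

    for (g in which(status == "DE")) {
      on <- stats::runif(length(factors)) < 0.5
      if (!any(on)) on[sample.int(length(factors), 1L)] <- TRUE
      beta[g, factors[on]] <- draw_effect(sum(on), config)
    }

    for (g in which(status == "interaction")) {
      cb <- sample(combos, 1L, prob = combo_mix)
      cl <- sample(names(config$class_mix), 1L, prob = config$class_mix)
      parts <- strsplit(cb, ":", fixed = TRUE)[[1L]]
      main_sign <- if (cl %in% c("S+", "A+")) 1 else -1
      int_sign  <- if (cl %in% c("S+", "A-")) 1 else -1
      beta[g, parts] <- draw_effect(length(parts), config, sign = main_sign)
      beta[g, cb] <- draw_effect(1L, config, sign = int_sign)
      combo[g] <- cb
      class[g] <- cl
    }

    out <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                      beta0 = beta0, stringsAsFactors = FALSE)
    bcols <- as.data.frame(beta)
    names(bcols) <- paste0("beta_", terms)
    out <- cbind(out, bcols)
    out$dispersion <- dispersion
    out$batch_loading <- batch_loading
    out$status <- status
    out$combo <- combo
    out$class <- class
    class(out) <- c("facstress_truth", "data.frame")
    attr(out, "factors") <- factors
    out
  })
}

# Non-intercept terms of the full factorial model, fixed order.
factorial_terms <- function(factors) {
  d <- make_design(factors, replicates_per_cell = 1L)
  colnames(build_model_matrix(d))[-1L]
}

#' Simulate transcript-level estimated counts
#'
#' Gene-level counts for sample j are drawn negative-binomial with mean
#' \eqn{s_j \cdot 2^{\beta_0 + x_j^T\beta + \gamma b_j}}{sj * 2^(b0 + x'b + g*batch)}
#' and the gene's dispersion (Poisson in the limit of zero dispersion),
#' then partitioned across the gene's isoforms by Dirichlet usage
#' weights, yielding real-valued "estimated" transcript counts as an
#' upstream abundance estimator would.  Isoform effective lengths are
#' log-uniform between the configured bounds.
#'
#' @param truth Truth table from [sample_truth()].
#' @param design Sample design from [make_design()].
#' @param size_factors Per-sample positive reals, or NULL to draw
#'   log-normal factors (sdlog 0.2) rescaled to geometric mean 1.
#' @param isoform_config List with \code{max_isoforms} (default 4) and
#'   \code{length_range} in bases (default c(300, 5000)).
#' @param seed Integer seed.
#' @return A data.frame (class \code{facstress_tx}) with columns
#'   \code{transcript_id}, \code{gene_id}, \code{effective_length} and one
#'   numeric column per sample.  The drawn size factors and the design are
#'   stored as attributes \code{size_factors} and \code{design}.
#' @export
simulate_counts <- function(truth, design, size_factors = NULL,
                            isoform_config = list(max_isoforms = 4L,
                                                  length_range = c(300, 5000)),
                            seed) {
  if (missing(seed)) stop("'seed' is required")
  factors <- attr(truth, "factors")
  if (is.null(factors)) factors <- design_factors(design)
  terms <- paste0("beta_", factorial_terms(factors))
  if (!all(terms %in% names(truth)))
    stop("truth table is missing coefficient columns")
  n_genes <- nrow(truth)
  n_samp <- nrow(design)

  mm <- build_model_matrix(design)
  beta <- as.matrix(truth[, c("beta0", terms)])
  log2mu_design <- beta %*% t(mm)          # genes x samples
  log2mu <- log2mu_design +
    outer(truth$batch_loading, as.numeric(design$batch))

  with_seed(seed, {
    if (is.null(size_factors)) {
      size_factors <- stats::rlnorm(n_samp, 0, 0.2)
      size_factors <- size_factors / exp(mean(log(size_factors)))
    }
    if (length(size_factors) != n_samp || any(size_factors <= 0))
      stop("'size_factors' must be positive, one per sample")

    mu <- sweep(2^log2mu, 2L, size_factors, `*`)
    alpha <- truth$dispersion
    counts <- matrix(0, n_genes, n_samp)
    pois <- alpha < 1e-10
    if (any(pois))
      counts[pois, ] <- stats::rpois(sum(pois) * n_samp, mu[pois, ])
    if (any(!pois))
      counts[!pois, ] <- stats::rnbinom(sum(!pois) * n_samp,
                                        mu = mu[!pois, ],
                                        size = 1 / alpha[!pois])

    n_iso <- sample.int(isoform_config$max_isoforms, n_genes, replace = TRUE)
    total_tx <- sum(n_iso)
    lr <- log(isoform_config$length_range)
    lens <- exp(stats::runif(total_tx, lr[1L], lr[2L]))
    w <- stats::rgamma(total_tx, 1)        # Dirichlet(1) usage weights
    gene_of_tx <- rep(seq_len(n_genes), n_iso)
    w <- w / rep(rowsum(w, gene_of_tx)[, 1L], n_iso)

    tx_counts <- counts[gene_of_tx, , drop = FALSE] * w
    colnames(tx_counts) <- design$sample_id
    iso_idx <- sequence(n_iso)
    out <- data.frame(
      transcript_id = sprintf("%s.i%d", truth$gene_id[gene_of_tx], iso_idx),
      gene_id = truth$gene_id[gene_of_tx],
      effective_length = lens,
      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(tx_counts))
    class(out) <- c("facstress_tx", "data.frame")
    attr(out, "size_factors") <- stats::setNames(size_factors, design$sample_id)
    attr(out, "design") <- design
    out
  })
}
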