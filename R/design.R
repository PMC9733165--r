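#' Construct a balanced full-factorial sample design
#'
#' Builds the sample table for a crossed two-level multi-stressor
#' experiment.  Each combination of factor levels (a "cell") receives the
#' same number of replicate samples.  The default reproduces a 2x2x2
#' salinity x sediment x flow design with eight replicates per cell,
#' i.e. 64 libraries.
#'
#' Cells are ordered lexicographically by factor level (the last factor
#' varies fastest, \code{ambient} before \code{treated}) and replicates are
#' numbered within each cell, so the sample ordering is deterministic.
#' A balanced binary \code{batch} column (odd vs. even replicate) is
#' included; it is crossed with, never confounded with, the design and is
#' used by the simulator as the latent batch grouping.
#'
#' @param factors Character vector of factor names (1 to 4 factors).
#' @param replicates_per_cell Positive integer; replicates per design cell.
#' @param levels Character vector of length 2 giving the level names,
#'   reference level first.
#' @return A data.frame with columns \code{sample_id}, one column per
#'   factor (a factor with the given levels), \code{replicate} and
#'   \code{batch} (integer 0/1).
#' @examples
#' d <- make_design()
#' nrow(d)                      # 64
#' table(d$Salinity, d$Flow)    # balanced
#' @export
make_design <- function(factors = c("Salinity", "Sediment", "Flow"),
                        replicates_per_cell = 8L,
                        levels = c("ambient", "treated")) {
  if (length(factors) < 1L || length(factors) > 4L)
    stop("between 1 and 4 factors are supported")
  if (anyDuplicated(factors))
    stop("factor names must be unique")
  if (length(replicates_per_cell) != 1L || is.na(replicates_per_cell) ||
      replicates_per_cell < 1 || replicates_per_cell != round(replicates_per_cell))
    stop("'replicates_per_cell' must be a positive integer")
  if (length(levels) != 2L)
    stop("exactly two levels per factor are supported")
  replicates_per_cell <- as.integer(replicates_per_cell)

  # expand.grid varies the first variable fastest; feed factors reversed so
  # the LAST design factor varies fastest (lexicographic cell order).
  grid_args <- rep(list(levels), length(factors))
  names(grid_args) <- rev(factors)
  cells <- expand.grid(grid_args, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(factors)), drop = FALSE]

  idx <- rep(seq_len(nrow(cells)), each = replicates_per_cell)
  design <- cells[idx, , drop = FALSE]
  rownames(design) <- NULL
  design$replicate <- rep(seq_len(replicates_per_cell), times = nrow(cells))

  code <- apply(design[, factors, drop = FALSE], 1L, function(r)
    paste(ifelse(r == levels[2L], "T", "A"), collapse = ""))
  design$sample_id <- sprintf("%s_r%d", code, design$replicate)
  design$batch <- as.integer(design$replicate %% 2L == 0L)

  for (f in factors)
    design[[f]] <- factor(design[[f]], levels = levels)
  design[, c("sample_id", factors, "replicate", "batch")]
}

#' Model matrix for the full factorial design plus surrogate covariates
#'
#' Treatment-coded (reference level = 0) design matrix with all main
#' effects and interactions of the design factors, in a fixed column
#' order, followed by any surrogate-variable columns.  For the default
#' three-factor design the factorial columns are Intercept, Salinity,
#' Sediment, Flow, Salinity:Sediment, Salinity:Flow, Sediment:Flow,
#' Salinity:Sediment:Flow.
#'
#' @param design Sample design as returned by [make_design()].
#' @param sv Optional surrogate set from [estimate_surrogates()], or a
#'   numeric matrix with one row per sample, or NULL for none.
#' @return Numeric matrix, samples x terms, with full column rank.
#' @export
build_model_matrix <- function(design, sv = NULL) {
  factors <- design_factors(design)
  form <- stats::as.formula(paste("~", paste(factors, collapse = "*")))
  mm <- stats::model.matrix(form, data = design)
  # strip the level suffix ("Salinitytreated" -> "Salinity") for readability
  cn <- colnames(mm)
  cn[1L] <- "Intercept"
  for (f in factors) {
    lv <- levels(design[[f]])[2L]
    cn <- gsub(paste0(f, lv), f, cn, fixed = TRUE)
  }
  colnames(mm) <- cn

  svmat <- surrogate_matrix(sv)
  if (!is.null(svmat)) {
    if (nrow(svmat) != nrow(mm))
      stop("surrogate rows do not match design samples")
    mm <- cbind(mm, svmat)
  }
  if (qr(mm)$rank < ncol(mm))
    stop("model matrix is rank deficient; check design and surrogates")
  rownames(mm) <- design$sample_id
  attr(mm, "assign") <- NULL
  attr(mm, "contrasts") <- NULL
  mm
}

# Factor columns of a design table: two-level factors, excluding bookkeeping.
design_factors <- function(design) {
  keep <- vapply(design, function(x) is.factor(x) && nlevels(x) == 2L,
                 logical(1L))
  keep[names(keep) %in% c("sample_id", "replicate", "batch")] <- FALSE
  f <- names(design)[keep]
  if (length(f) == 0L)
    stop("design contains no two-level factor columns")
  f
}

# Accept a SurrogateSet, a bare matrix, or NULL.
surrogate_matrix <- function(sv) {
  if (is.null(sv)) return(NULL)
  if (inherits(sv, "facstress_sv")) sv <- sv$sv
  if (is.null(sv) || NCOL(sv) == 0L) return(NULL)
  sv <- as.matrix(sv)
  if (is.null(colnames(sv)))
    colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  sv
}
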