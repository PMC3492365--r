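#' Derive locality-quantile suitability thresholds
#'
#' From present-day model scores at the unique localities, the threshold
#' for level `l` (default levels 0.68, 0.95, 1.00) is the score of the
#' k-th highest locality with `k = ceiling(l * n)`: the cutoffs below
#' which 68% / 95% / 100% of the training localities remain classified as
#' suitable. With n = 349 localities the 0.68 level retains
#' `ceiling(237.32) = 238` localities in the optimal class. If tied
#' scores make the count exactly k unattainable, the realised count (the
#' nearest attainable from above) is recorded in `attained`.
#'
#' @param scores Numeric vector of present-day locality scores.
#' @param levels Strictly increasing quantile levels ending at 1.
#' @return A `threshold_set`: `tau_optimal`, `tau_intermediate`,
#'   `tau_marginal`, plus `levels`, `n_localities` and the `attained`
#'   counts.
#' @export
derive_thresholds <- function(scores, levels = c(0.68, 0.95, 1.00)) {
  if (!length(scores)) stop("scores must be non-empty", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE) ||
      utils::tail(levels, 1) != 1) {
    stop("levels must be strictly increasing and end at 1", call. = FALSE)
  }
  n <- length(scores)
  sorted <- sort(scores, decreasing = TRUE)
  k <- pmin(ceiling(levels * n), n)
  tau <- sorted[k]
  attained <- vapply(tau, function(t) sum(scores >= t), integer(1))
  structure(list(
    tau_optimal = tau[1], tau_intermediate = tau[2], tau_marginal = tau[3],
    levels = levels, n_localities = n,
    target_k = k, attained = attained
  ), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> n = %d | optimal > %.4g | intermediate > %.4g | marginal >= %.4g\n",
    x$n_localities, x$tau_optimal, x$tau_intermediate, x$tau_marginal))
  invisible(x)
}

#' Classify suitability scores into threshold classes
#'
#' Disjoint bins: `optimal` if score strictly above the optimal cutoff,
#' else `intermediate` if strictly above the intermediate cutoff, else
#' `marginal` if at or above the marginal cutoff (inclusive, so every
#' training locality is suitable at baseline), else `unsuitable`.
#' Degenerate ties: when adjacent cutoffs coincide (massively tied
#' training scores), a score sitting exactly on the shared cutoff belongs
#' to the higher class, so a constant score vector classifies as all
#' optimal rather than all marginal.
#'
#' @param score Numeric vector of logistic-scale scores (>= 0).
#' @param thresholds A [derive_thresholds()] result.
#' @return An ordered factor `unsuitable < marginal < intermediate <
#'   optimal`; `NA` scores give `NA`.
#' @export
classify_scores <- function(score, thresholds) {
  if (any(score < 0, na.rm = TRUE)) {
    stop("scores must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  opt_cut <- thresholds$tau_optimal
  int_cut <- thresholds$tau_intermediate
  is_opt <- score[ok] > opt_cut |
    (score[ok] == opt_cut & opt_cut == int_cut)
  is_int <- score[ok] > int_cut |
    (score[ok] == int_cut & int_cut == thresholds$tau_marginal)
  out[ok] <- ifelse(
    is_opt, "optimal",
    ifelse(is_int, "intermediate",
           ifelse(score[ok] >= thresholds$tau_marginal, "marginal",
                  "unsuitable")))
  factor(out, levels = c("unsuitable", "marginal", "intermediate",
                         "optimal"), ordered = TRUE)
}

#' Published locality-class reference counts
#'
#' The classification table from the original wild-arabica climate-change
#' assessment: number of unique localities (n = 349) in each threshold
#' class for the present day (2000) and for three emission scenarios
#' (B2A, A2A, A1B) at 2020 / 2050 / 2080. Used as in-package input for
#' arithmetic checks of the classification conventions (column sums,
#' suitable remainders, reduction percentages).
#'
#' @return A tibble: `scenario_id`, `date`, `class`, `count`.
#' @export
arabica_reference_counts <- function() {
  classes <- c("optimal", "intermediate", "marginal", "unsuitable")
  cols <- list(
    baseline_2000 = c(238, 97, 14, 0),
    B2A_2020 = c(27, 228, 61, 33),
    B2A_2050 = c(100, 52, 51, 146),
    B2A_2080 = c(26, 62, 34, 227),
    A2A_2020 = c(54, 208, 33, 54),
    A2A_2050 = c(46, 73, 45, 185),
    A2A_2080 = c(1, 34, 15, 299),
    A1B_2020 = c(165, 105, 27, 52),
    A1B_2050 = c(44, 60, 42, 203),
    A1B_2080 = c(1, 36, 14, 298)
  )
  purrr::imap_dfr(cols, function(v, nm) {
    parts <- strsplit(nm, "_")[[1]]
    tibble::tibble(scenario_id = parts[1], date = parts[2],
                   class = factor(classes,
                                  levels = c("unsuitable", "marginal",
                                             "intermediate", "optimal"),
                                  ordered = TRUE),
                   count = v)
  })
}
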