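#' Define a feature expansion for the niche model
#'
#' Feature classes follow the standard presence-background maximum-entropy
#' toolkit: per-variable linear and quadratic terms, pairwise products,
#' and forward hinge bases at evenly spaced knots. All features are
#' computed on variables rescaled to \[0, 1\] using the stored bounds, so
#' every feature value lies in \[0, 1\] as well.
#'
#' @param bounds Named list (or two-row matrix) of per-variable
#'   `c(min, max)` used for scaling; normally the training range.
#' @param linear,quadratic,product,hinge Logical flags enabling classes.
#' @param n_hinge_knots Number of interior hinge knots per variable.
#' @return A `feature_set` object.
#' @export
feature_set <- function(bounds, linear = TRUE, quadratic = TRUE,
                        product = TRUE, hinge = TRUE, n_hinge_knots = 5) {
  if (!any(linear, quadratic, product, hinge)) {
    stop("at least one feature class must be enabled", call. = FALSE)
  }
  b <- do.call(rbind, lapply(bounds, function(x) x[1:2]))
  if (any(!is.finite(b))) stop("scaling bounds must be finite",
                               call. = FALSE)
  structure(list(
    vars = names(bounds),
    min = stats::setNames(b[, 1], names(bounds)),
    max = stats::setNames(b[, 2], names(bounds)),
    linear = linear, quadratic = quadratic, product = product,
    hinge = hinge, n_hinge_knots = n_hinge_knots
  ), class = "feature_set")
}

#' Bounds helper: training range of each variable
#'
#' @param env Data frame of environment values (variables in columns).
#' @return Named list of `c(min, max)` per column.
#' @export
var_bounds <- function(env) {
  lapply(as.list(env), function(x) range(x, na.rm = TRUE))
}

#' Expand environments into the model design matrix
#'
#' Variables are scaled to \[0, 1\] with the feature-set bounds (values
#' outside the bounds are clamped — the conservative choice when
#' projecting beyond the training range), then expanded into the enabled
#' feature columns. Hinge features are
#' `max(0, (x - k) / (1 - k))` at knots `k` evenly spaced in (0, 1).
#'
#' @param env Data frame with all feature-set variables.
#' @param fs A [feature_set()].
#' @return Numeric matrix, entries in \[0, 1\]; attribute `n_clamped`
#'   counts clamped values.
#' @export
build_features <- function(env, fs) {
  missing <- setdiff(fs$vars, names(env))
  if (length(missing)) {
    stop("missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(env)
  x01 <- matrix(0, n, length(fs$vars),
                dimnames = list(NULL, fs$vars))
  n_clamped <- 0L
  for (v in fs$vars) {
    z <- (env[[v]] - fs$min[[v]]) / max(fs$max[[v]] - fs$min[[v]], 1e-12)
    n_clamped <- n_clamped + sum(z < 0 | z > 1, na.rm = TRUE)
    x01[, v] <- pmin(pmax(z, 0), 1)
  }
  cols <- list()
  if (fs$linear) for (v in fs$vars) cols[[v]] <- x01[, v]
  if (fs$quadratic) {
    for (v in fs$vars) cols[[paste0(v, "^2")]] <- x01[, v]^2
  }
  if (fs$product && length(fs$vars) > 1) {
    pairs <- utils::combn(fs$vars, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      cols[[paste0(a, "*", b)]] <- x01[, a] * x01[, b]
    }
  }
  if (fs$hinge && fs$n_hinge_knots > 0) {
    knots <- seq(0, 1, length.out = fs$n_hinge_knots + 2)
    knots <- knots[-c(1, length(knots))]
    for (v in fs$vars) {
      for (k in knots) {
        cols[[sprintf("hinge(%s,%.3f)", v, k)]] <-
          pmax(0, (x01[, v] - k) / (1 - k))
      }
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Fit the presence-background maximum-entropy niche model
#'
#' Fits the Gibbs distribution `P(x) = exp(lambda . f(x)) / Z` over the
#' background by maximising the L1-penalised presence log-likelihood
#'
#'   `mean_presence[lambda . f] - log Z - beta * sum_f s_f |lambda_f|`
#'
#' where `s_f = sd_presence(f) / sqrt(n_presence)` is the feature
#' standard-error scaling. At the optimum every feature satisfies the
#' box constraint `|E_model[f] - mean_presence[f]| <= beta * s_f`.
#' Optimisation uses L-BFGS-B on the split-variable form
#' `lambda = lambda+ - lambda-` with non-negativity bounds, which makes
#' the penalty smooth. Constant features are dropped with a warning.
#'
#' @param presence_env Data frame of environments at presence samples
#'   (>= 10 rows).
#' @param background_env Data frame of environments at background samples.
#' @param fs A [feature_set()]; defaults to all classes over the combined
#'   training range.
#' @param beta L1 regularisation multiplier (>= 0).
#' @param tol Convergence tolerance on the projected gradient norm.
#' @param max_iter Maximum L-BFGS-B iterations.
#' @return A `maxent_model`: feature set, named weights, `log_z`,
#'   `entropy`, background feature means, convergence info.
#' @export
fit_maxent <- function(presence_env, background_env, fs = NULL,
                       beta = 1, tol = 1e-6, max_iter = 500) {
  presence_env <- tibble::as_tibble(presence_env)
  background_env <- tibble::as_tibble(background_env)
  if (nrow(presence_env) < 10) {
    stop("need at least 10 presence samples", call. = FALSE)
  }
  if (is.null(fs)) {
    fs <- feature_set(var_bounds(dplyr::bind_rows(presence_env,
                                                  background_env)))
  }
  f_pres <- build_features(presence_env, fs)
  f_bg <- build_features(background_env, fs)

  const <- apply(f_bg, 2, function(x) diff(range(x)) < 1e-12)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(f_bg)[const], collapse = ", "))
    f_pres <- f_pres[, !const, drop = FALSE]
    f_bg <- f_bg[, !const, drop = FALSE]
  }
  p <- ncol(f_bg)
  m <- nrow(f_pres)
  pres_mean <- colMeans(f_pres)
  # feature standard-error scale; sd floored at 0.05 (features live in
  # [0,1]) so low-variance features keep a workable penalty bound
  s_f <- pmax(apply(f_pres, 2, stats::sd), 0.05) / sqrt(m)

  # objective on (lambda+, lambda-): negative penalised log-likelihood
  obj <- function(theta) {
    lam <- theta[1:p] - theta[p + 1:p]
    eta <- drop(f_bg %*% lam)
    mx <- max(eta)
    log_z <- mx + log(mean(exp(eta - mx)))      # log mean, uniform base
    -(sum(pres_mean * lam) - log_z) + beta * sum(s_f * (theta[1:p] +
                                                        theta[p + 1:p]))
  }
  grd <- function(theta) {
    lam <- theta[1:p] - theta[p + 1:p]
    eta <- drop(f_bg %*% lam)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    e_model <- drop(crossprod(f_bg, w))
    g <- e_model - pres_mean
    c(g + beta * s_f, -g + beta * s_f)
  }
  theta <- rep(0, 2 * p)
  for (round in 1:3) {                      # warm restarts help L-BFGS-B
    fit <- stats::optim(theta, obj, grd, method = "L-BFGS-B",
                        lower = 0,
                        control = list(maxit = max_iter, factr = 1e4,
                                       pgtol = tol))
    theta <- fit$par
    if (fit$convergence == 0) break
  }
  lam <- fit$par[1:p] - fit$par[p + 1:p]
  eta <- drop(f_bg %*% lam)
  mx <- max(eta)
  log_z_mean <- mx + log(mean(exp(eta - mx)))
  raw <- exp(eta - log_z_mean) / nrow(f_bg)    # sums to 1 over background
  entropy <- -sum(raw * log(pmax(raw, 1e-300)))
  # box-constraint residuals (diagnostic; ~0 at convergence)
  w <- raw / sum(raw)
  box_resid <- abs(drop(crossprod(f_bg, w)) - pres_mean) - beta * s_f
  if (fit$convergence != 0 && max(box_resid) > 1e-4) {
    stop(sprintf(
      "maxent fit did not converge: optim code %d, max box residual %.3g",
      fit$convergence, max(box_resid)), call. = FALSE)
  }
  structure(list(
    feature_set = fs,
    weights = stats::setNames(lam, colnames(f_bg)),
    s_f = s_f, pres_mean = pres_mean,
    log_z_mean = log_z_mean, n_background = nrow(f_bg),
    n_presence = m,
    entropy = entropy, beta = beta,
    box_residual = max(box_resid),
    convergence = fit$convergence,
    value = fit$value
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%d active), %d presences, %d background\n",
    length(x$weights), sum(x$weights != 0), x$n_presence, x$n_background))
  cat(sprintf("  entropy %.3f | beta %.2f | max box residual %.2g\n",
              x$entropy, x$beta, x$box_residual))
  invisible(x)
}

#' Predict suitability from a fitted niche model
#'
#' `raw` is the Gibbs probability over the fitting background (the raw
#' scores of the background sum to 1). `logistic` is the entropy-pivoted
#' transform `p = e^H * raw / (1 + e^H * raw)`: a cell whose raw score
#' equals `e^-H` (a "typical" presence cell) maps to 0.5.
#'
#' @param object A `maxent_model`.
#' @param env Data frame of environments.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.maxent_model <- function(object, env, type = c("logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  f <- build_features(tibble::as_tibble(env), object$feature_set)
  f <- f[, names(object$weights), drop = FALSE]
  eta <- drop(f %*% object$weights)
  raw <- exp(eta - object$log_z_mean) / object$n_background
  if (type == "raw") return(raw)
  q <- exp(object$entropy) * raw
  q / (1 + q)
}

#' Predict a suitability surface over a climate stack
#'
#' @param model A `maxent_model`.
#' @param stack A [clim_stack()] with all model variables.
#' @param type Passed to [predict.maxent_model()].
#' @return Matrix of scores on the stack's grid; `NA` where any input
#'   layer is nodata.
#' @export
predict_surface <- function(model, stack, type = "logistic") {
  env <- as_tibble.clim_stack(stack)
  missing <- setdiff(model$feature_set$vars, names(env))
  if (length(missing)) {
    stop("stack missing layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(env[model$feature_set$vars])
  scores <- rep(NA_real_, nrow(env))
  if (any(ok)) {
    scores[ok] <- predict(model, env[ok, model$feature_set$vars],
                          type = type)
  }
  matrix(scores, stack$spec$n_rows, stack$spec$n_cols)
}

#' Area under the ROC curve for presence vs background scores
#'
#' The probability that a random presence outranks a random background
#' point, ties counted 0.5 — computed exactly via the rank-sum identity.
#'
#' @param pres_scores,bg_scores Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_presence_background <- function(pres_scores, bg_scores) {
  n1 <- length(pres_scores); n2 <- length(bg_scores)
  r <- rank(c(pres_scores, bg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Evaluate a niche model with a held-out presence split
#'
#' Splits presences into train/test (seeded), refits on the training
#' share, and reports train/test AUC against the background, per-variable
#' permutation importance (drop in training AUC when the variable is
#' shuffled, normalised to sum to 100), and jackknife gains (regularised
#' training gain of the with-only and without-variable refits; gain =
#' penalised log-likelihood improvement over the uniform model,
#' `log(n_background) - H`-style).
#'
#' @param presence_env,background_env Environment data frames.
#' @param fs A [feature_set()] or `NULL` for the default.
#' @param test_fraction Held-out presence fraction (default 0.2).
#' @param beta,tol,max_iter Passed to [fit_maxent()].
#' @param seed Integer seed for the split and permutations.
#' @param jackknife Set `FALSE` to skip the per-variable refits.
#' @return A list of class `maxent_eval`: `train_auc`, `test_auc`,
#'   `contributions` (tibble, percent per variable), `jackknife`
#'   (tibble), `model` (the training-share fit), `n_train`, `n_test`.
#' @export
evaluate_model <- function(presence_env, background_env, fs = NULL,
                           test_fraction = 0.2, beta = 1, tol = 1e-6,
                           max_iter = 500, seed = 1, jackknife = TRUE) {
  n <- nrow(presence_env)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n - n_test < 10) {
    stop("split error: test or train share too small", call. = FALSE)
  }
  withr_seed(seed)
  test_idx <- sample.int(n, n_test)
  train <- presence_env[-test_idx, ]
  test <- presence_env[test_idx, ]
  if (is.null(fs)) {
    fs <- feature_set(var_bounds(dplyr::bind_rows(presence_env,
                                                  background_env)))
  }
  model <- fit_maxent(train, background_env, fs, beta, tol, max_iter)
  bg_scores <- predict(model, background_env)
  train_auc <- auc_presence_background(predict(model, train), bg_scores)
  test_auc <- auc_presence_background(predict(model, test), bg_scores)

  # permutation importance on the training AUC, averaged over replicates
  drops <- vapply(fs$vars, function(v) {
    reps <- vapply(1:5, function(r) {
      tr_p <- train; bg_p <- background_env
      tr_p[[v]] <- sample(tr_p[[v]])
      bg_p[[v]] <- sample(bg_p[[v]])
      a <- auc_presence_background(predict(model, tr_p),
                                   predict(model, bg_p))
      train_auc - a
    }, numeric(1))
    max(mean(reps), 0)
  }, numeric(1))
  contrib <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(100 / length(drops), length(drops))
  contributions <- tibble::tibble(variable = fs$vars,
                                  contribution = unname(contrib))

  jk <- NULL
  if (jackknife) {
    gain <- function(mod) log(mod$n_background) - mod$entropy
    jk <- purrr::map_dfr(fs$vars, function(v) {
      fs_only <- feature_set(stats::setNames(
        list(c(fs$min[[v]], fs$max[[v]])), v),
        fs$linear, fs$quadratic, product = FALSE, fs$hinge,
        fs$n_hinge_knots)
      rest <- setdiff(fs$vars, v)
      fs_wo <- feature_set(
        stats::setNames(lapply(rest, function(u) c(fs$min[[u]],
                                                   fs$max[[u]])), rest),
        fs$linear, fs$quadratic, fs$product, fs$hinge, fs$n_hinge_knots)
      m_only <- fit_maxent(train[v], background_env[v], fs_only,
                           beta, tol, max_iter)
      m_wo <- fit_maxent(train[rest], background_env[rest], fs_wo,
                         beta, tol, max_iter)
      tibble::tibble(variable = v, gain_with_only = gain(m_only),
                     gain_without = gain(m_wo))
    })
  }
  structure(list(train_auc = train_auc, test_auc = test_auc,
                 contributions = contributions, jackknife = jk,
                 model = model, n_train = n - n_test, n_test = n_test),
            class = "maxent_eval")
}

#' @export
print.maxent_eval <- function(x, ...) {
  cat(sprintf("<maxent_eval> train AUC %.3f | test AUC %.3f (%d/%d split)\n",
              x$train_auc, x$test_auc, x$n_train, x$n_test))
  print(x$contributions)
  invisible(x)
}

#' Response curve of one variable
#'
#' Sweeps a variable across its training range with all other variables
#' held at their background means, and records the logistic prediction.
#'
#' @param model A `maxent_model`.
#' @param background_env Background environments defining the held means.
#' @param variable Variable name.
#' @param n_points Number of sweep points.
#' @return A tibble with columns `variable`, `value`, `response`.
#' @export
response_curve <- function(model, background_env, variable,
                           n_points = 100) {
  fs <- model$feature_set
  if (!variable %in% fs$vars) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  sweep_vals <- seq(fs$min[[variable]], fs$max[[variable]],
                    length.out = n_points)
  env <- tibble::as_tibble(lapply(
    stats::setNames(fs$vars, fs$vars),
    function(v) rep(mean(background_env[[v]]), n_points)
  ))
  env[[variable]] <- sweep_vals
  tibble::tibble(variable = variable, value = sweep_vals,
                 response = predict(model, env))
}

#' Serialise / restore a fitted niche model as JSON
#'
#' @param model A `maxent_model`.
#' @param path File path.
#' @return `write_model()` the path invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  fs <- model$feature_set
  jsonlite::write_json(list(
    vars = fs$vars, min = as.list(fs$min), max = as.list(fs$max),
    linear = fs$linear, quadratic = fs$quadratic, product = fs$product,
    hinge = fs$hinge, n_hinge_knots = fs$n_hinge_knots,
    weights = as.list(model$weights),
    s_f = as.list(stats::setNames(model$s_f, names(model$weights))),
    pres_mean = as.list(stats::setNames(model$pres_mean,
                                        names(model$weights))),
    log_z_mean = model$log_z_mean, n_background = model$n_background,
    n_presence = model$n_presence, entropy = model$entropy,
    beta = model$beta, box_residual = model$box_residual
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- feature_set(
    stats::setNames(lapply(j$vars, function(v) c(j$min[[v]], j$max[[v]])),
                    j$vars),
    j$linear, j$quadratic, j$product, j$hinge, j$n_hinge_knots
  )
  structure(list(
    feature_set = fs, weights = unlist(j$weights),
    s_f = unlist(j$s_f), pres_mean = unlist(j$pres_mean),
    log_z_mean = j$log_z_mean, n_background = j$n_background,
    n_presence = j$n_presence, entropy = j$entropy, beta = j$beta,
    box_residual = j$box_residual, convergence = 0
  ), class = "maxent_model")
}

#' Tidy a fitted niche model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return One row per feature: `feature`, `estimate`, `active`.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(feature = names(x$weights),
                 estimate = unname(x$weights),
                 active = x$weights != 0)
}

#' One-row model summary
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, entropy, penalty, sparsity.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$weights), n_active = sum(x$weights != 0),
    entropy = x$entropy, beta = x$beta,
    l1_norm = sum(abs(x$weights)), box_residual = x$box_residual
  )
}
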