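#' Resampling / elastic-net training specification
#'
#' Settings for the model-development engine: elastic-net penalized
#' logistic regression tuned by repeated stratified k-fold cross-validation.
#' Defaults follow the development design of the published classifier:
#' mixing factor \eqn{\alpha} screened from 0 to 1 in steps of 0.1, 3-fold
#' cross-validation repeated for 1000 resampling iterations.
#'
#' @param alpha_grid Elastic-net mixing values in `[0, 1]` (`0` = ridge,
#'   `1` = lasso).
#' @param n_resamples Number of resampling iterations (fresh stratified
#'   fold partitions).
#' @param k_folds Folds per iteration (>= 2).
#' @param n_lambda Length of the penalty path.
#' @param lambda_min_ratio Smallest path value as a fraction of the
#'   data-derived \eqn{\lambda_{max}}.
#' @param seed Integer seed; every random draw of the engine derives from
#'   it, making the whole workflow reproducible.
#' @return A list of class `enet_spec`.
#' @export
elastic_net_spec <- function(alpha_grid = seq(0, 1, by = 0.1),
                             n_resamples = 1000L,
                             k_folds = 3L,
                             n_lambda = 100L,
                             lambda_min_ratio = 0.01,
                             seed = 1L) {
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha values must lie in [0, 1]", call. = FALSE)
  if (k_folds < 2L) stop("k_folds must be at least 2", call. = FALSE)
  if (n_resamples < 1L) stop("n_resamples must be positive", call. = FALSE)
  if (n_lambda < 2L || lambda_min_ratio <= 0 || lambda_min_ratio >= 1) {
    stop("invalid lambda path settings", call. = FALSE)
  }
  structure(list(alpha_grid = sort(unique(alpha_grid)),
                 n_resamples = as.integer(n_resamples),
                 k_folds = as.integer(k_folds),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "enet_spec")
}

#' Assemble training data from normalized profiles and labels
#'
#' Restricts a normalized expression table to the labelled LUAD/LUSC
#' samples and encodes the response as `y = 1` for LUAD, `0` for LUSC.
#' NOS and UNKNOWN samples are excluded (they carry no trainable label).
#'
#' @param z Tibble from [normalize_expression()].
#' @param labels Tibble with columns `sample_id` and `label`.
#' @return A list of class `training_data`: `x` (samples-by-genes numeric
#'   matrix), `y` (0/1 vector), `sample_ids`, `genes`.
#' @export
training_data <- function(z, labels) {
  check_expression(z, "z")
  if (!all(c("sample_id", "label") %in% names(labels))) {
    stop("`labels` needs `sample_id` and `label` columns", call. = FALSE)
  }
  keep <- labels[labels$label %in% c("LUAD", "LUSC"), , drop = FALSE]
  samples <- intersect(setdiff(names(z), "gene"), keep$sample_id)
  if (!length(samples)) stop("no labelled LUAD/LUSC samples found in `z`", call. = FALSE)
  y <- as.integer(keep$label[match(samples, keep$sample_id)] == "LUAD")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both LUAD and LUSC samples", call. = FALSE)
  }
  x <- t(as.matrix(z[, samples, drop = FALSE]))
  colnames(x) <- z$gene
  rownames(x) <- samples
  structure(list(x = x, y = y, sample_ids = samples, genes = z$gene),
            class = "training_data")
}

#' Elastic-net penalized logistic objective
#'
#' The quantity the training engine minimizes:
#' \deqn{\frac{1}{n}\sum_i \left[-y_i \eta_i + \log(1 + e^{\eta_i})\right]
#'   + \lambda\left[(1-\alpha)\tfrac{1}{2}\lVert\beta\rVert_2^2
#'   + \alpha\lVert\beta\rVert_1\right],}
#' with \eqn{\eta_i = \beta_0 + g_i \beta^T}. The intercept is never
#' penalized.
#'
#' @param intercept Scalar \eqn{\beta_0}.
#' @param beta Coefficient vector; either unnamed of length
#'   `ncol(data$x)`, or named (genes absent from the names contribute 0).
#' @param data A [training_data()] object.
#' @param lambda Penalty strength, `>= 0`.
#' @param alpha Mixing factor in `[0, 1]`.
#' @return The objective value (a single number).
#' @export
penalized_objective <- function(intercept, beta, data, lambda, alpha) {
  stopifnot(inherits(data, "training_data"))
  if (!is.finite(intercept) || any(!is.finite(beta)) ||
      !is.finite(lambda) || !is.finite(alpha)) {
    stop("non-finite parameter", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  b <- expand_beta(beta, colnames(data$x))
  eta <- intercept + drop(data$x %*% b)
  nll <- mean(-data$y * eta + log1p(exp(eta)))
  nll + lambda * ((1 - alpha) * sum(b^2) / 2 + alpha * sum(abs(b)))
}

expand_beta <- function(beta, genes) {
  if (is.null(names(beta))) {
    if (length(beta) != length(genes)) {
      stop("unnamed `beta` must have one entry per gene", call. = FALSE)
    }
    return(as.numeric(beta))
  }
  b <- stats::setNames(numeric(length(genes)), genes)
  unknown <- setdiff(names(beta), genes)
  if (length(unknown)) {
    stop("beta names not in training data: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  b[names(beta)] <- beta
  as.numeric(b)
}

#' Data-derived penalty path
#'
#' Log-spaced decreasing sequence from \eqn{\lambda_{max}} (the smallest
#' penalty at which all coefficients are zero, computed from the gradient of
#' the null model) down to `lambda_min_ratio * lambda_max`. For `alpha = 0`
#' the usual convention of computing \eqn{\lambda_{max}} at a small
#' surrogate mixing value (0.001) is used, since ridge never fully shrinks.
#'
#' @inheritParams penalized_objective
#' @param n_lambda,lambda_min_ratio Path length and depth.
#' @return Strictly decreasing positive numeric vector.
#' @export
lambda_path <- function(data, alpha, n_lambda = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "training_data"))
  n <- length(data$y)
  a <- max(alpha, 0.001)
  lmax <- max(abs(crossprod(data$x, data$y - mean(data$y)))) / (n * a)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit elastic-net penalized logistic regression at one (lambda, alpha)
#'
#' Minimizes [penalized_objective()] by coordinate descent (via glmnet, on
#' unstandardized inputs with a tight convergence threshold). `lambda = 0`
#' is the unregularized maximum-likelihood fit; `lambda >=` the data-derived
#' \eqn{\lambda_{max}} fully shrinks every coefficient, leaving the
#' intercept at `logit(mean(y))`.
#'
#' @inheritParams penalized_objective
#' @return A list of class `enet_fit`: `intercept`, `beta` (full named
#'   coefficient vector, zeros included), `lambda`, `alpha`, `complexity`
#'   (number of nonzero coefficients).
#' @export
fit_elastic_net <- function(data, lambda, alpha) {
  stopifnot(inherits(data, "training_data"))
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  path <- lambda_path(data, alpha)
  lams <- sort(unique(c(path[path > lambda], lambda)), decreasing = TRUE)
  fit <- suppressWarnings(glmnet::glmnet(
    data$x, data$y, family = "binomial", alpha = alpha, lambda = lams,
    standardize = FALSE, thresh = 1e-12, maxit = 1e7
  ))
  if (length(fit$lambda) < length(lams)) {
    stop("elastic-net fit did not converge over the requested path", call. = FALSE)
  }
  i <- length(lams)
  beta <- stats::setNames(as.numeric(fit$beta[, i]), rownames(fit$beta))
  structure(list(intercept = as.numeric(fit$a0[i]), beta = beta,
                 lambda = lambda, alpha = alpha,
                 complexity = sum(beta != 0)),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("<enet_fit> lambda=", format(x$lambda), " alpha=", x$alpha,
      " | ", x$complexity, " nonzero of ", length(x$beta), " genes\n", sep = "")
  invisible(x)
}

#' Convert a penalized fit to a subtype model
#'
#' Keeps the nonzero coefficients (the model's signature genes).
#'
#' @param fit An `enet_fit` from [fit_elastic_net()].
#' @return A [subtype_model()].
#' @export
as_subtype_model <- function(fit) {
  stopifnot(inherits(fit, "enet_fit"))
  nz <- fit$beta[fit$beta != 0]
  if (!length(nz)) {
    stop("fit has no nonzero coefficients; cannot form a subtype model", call. = FALSE)
  }
  subtype_model(fit$intercept, nz)
}

# deterministic per-resample seed, kept below 2^31
resample_seed <- function(seed, resample_id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(resample_id) * 16807) %% 2147483647)
}

# evaluate expr under a given seed without disturbing the caller's RNG
with_seed_local <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# fresh stratified k-fold partition; every fold contains both classes
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation over the elastic-net grid
#'
#' The resampling engine behind model development: for each resampling
#' iteration a fresh stratified k-fold partition is drawn (seeded by the
#' spec seed and the iteration number); for each mixing value alpha the
#' penalty path is computed once from the full training data, each fold's
#' held-out accuracy is evaluated along the path (calls at the `p >= 0.5`
#' rule), and the path value maximizing the mean held-out accuracy is
#' selected (ties break to the largest, most parsimonious, penalty). The
#' recorded complexity is the nonzero-coefficient count of the full-data
#' refit at the selected penalty.
#'
#' @param data A [training_data()] object; each class needs at least
#'   `k_folds` members.
#' @param spec An [elastic_net_spec()].
#' @return A tibble with one row per (resample, alpha): `resample`,
#'   `alpha`, `best_lambda`, `cv_accuracy`, `complexity`. Identical seeds
#'   give identical tables.
#' @export
resample_cv <- function(data, spec = elastic_net_spec()) {
  stopifnot(inherits(data, "training_data"), inherits(spec, "enet_spec"))
  for (cls in 0:1) {
    if (sum(data$y == cls) < spec$k_folds) {
      stop("class ", c("LUSC", "LUAD")[cls + 1L], " has fewer members than folds",
           call. = FALSE)
    }
  }
  alphas <- spec$alpha_grid
  paths <- purrr::map(alphas, ~ lambda_path(data, .x, spec$n_lambda, spec$lambda_min_ratio))
  full_fits <- purrr::map2(alphas, paths, function(a, path) {
    suppressWarnings(glmnet::glmnet(
      data$x, data$y, family = "binomial", alpha = a, lambda = path,
      standardize = FALSE, thresh = 1e-9, maxit = 1e6))
  })
  n <- length(data$y)
  res <- vector("list", spec$n_resamples)
  for (r in seq_len(spec$n_resamples)) {
    fold <- with_seed_local(resample_seed(spec$seed, r),
                            stratified_folds(data$y, spec$k_folds))
    rows <- vector("list", length(alphas))
    for (ai in seq_along(alphas)) {
      path <- paths[[ai]]
      acc <- matrix(NA_real_, spec$k_folds, length(path))
      for (f in seq_len(spec$k_folds)) {
        tr <- fold != f
        fit <- suppressWarnings(glmnet::glmnet(
          data$x[tr, , drop = FALSE], data$y[tr], family = "binomial",
          alpha = alphas[ai], lambda = path,
          standardize = FALSE, thresh = 1e-9, maxit = 1e6))
        p <- stats::predict(fit, data$x[!tr, , drop = FALSE],
                            s = path, type = "response", exact = FALSE)
        acc[f, ] <- colMeans((p >= 0.5) == (data$y[!tr] == 1L))
      }
      macc <- colMeans(acc)
      best <- which.max(macc)  # path is decreasing: first max = largest lambda
      rows[[ai]] <- tibble::tibble(
        resample = r, alpha = alphas[ai], best_lambda = path[best],
        cv_accuracy = macc[best],
        complexity = sum(full_fits[[ai]]$beta[, best] != 0)
      )
    }
    res[[r]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(res)
}

#' Select the final model from resampling records
#'
#' Per-alpha mean and sd of the cross-validated accuracy are computed over
#' the resampling records; the alpha with the highest mean accuracy is
#' chosen (ties break to the smaller alpha), and the final model is refit
#' on all training samples at that alpha with the penalty fixed at the
#' median of the per-resample selected penalties.
#'
#' @param records Tibble from [resample_cv()].
#' @param data The [training_data()] the records were computed on.
#' @param spec The [elastic_net_spec()] used.
#' @return A list of class `subtype_fit`: `chosen_alpha`, `final_lambda`,
#'   `summary` (per-alpha tibble with `mean_accuracy`, `sd_accuracy`,
#'   `mean_complexity`), `records`, `fit` (the full-data `enet_fit`),
#'   `model` (a [subtype_model()] of the nonzero coefficients), and
#'   `accuracy` / `accuracy_sd` (the chosen alpha's resampling estimate,
#'   conventionally reported as "mean +/- sd").
#' @export
select_model <- function(records, data, spec = elastic_net_spec()) {
  if (!nrow(records)) stop("no resampling records", call. = FALSE)
  summary <- records |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(mean_accuracy = mean(.data$cv_accuracy),
                     sd_accuracy = stats::sd(.data$cv_accuracy),
                     mean_complexity = mean(.data$complexity),
                     median_lambda = stats::median(.data$best_lambda),
                     .groups = "drop") |>
    dplyr::arrange(.data$alpha)
  best <- summary |>
    dplyr::filter(.data$mean_accuracy == max(.data$mean_accuracy)) |>
    dplyr::slice_min(.data$alpha, n = 1)
  fit <- fit_elastic_net(data, lambda = best$median_lambda, alpha = best$alpha)
  model <- if (fit$complexity > 0) as_subtype_model(fit) else NULL
  structure(list(chosen_alpha = best$alpha,
                 final_lambda = best$median_lambda,
                 summary = summary,
                 records = records,
                 fit = fit,
                 model = model,
                 accuracy = best$mean_accuracy,
                 accuracy_sd = best$sd_accuracy),
            class = "subtype_fit")
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat(sprintf("<subtype_fit> alpha=%g, lambda=%.4g, accuracy %.3f +/- %.3f, complexity %d\n",
              x$chosen_alpha, x$final_lambda, x$accuracy,
              ifelse(is.na(x$accuracy_sd), 0, x$accuracy_sd), x$fit$complexity))
  invisible(x)
}

#' @describeIn select_model Coefficients of the final model as a tibble.
#' @param x A `subtype_fit`.
#' @param ... Unused.
#' @method tidy subtype_fit
#' @export
tidy.subtype_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(term = "(Intercept)", estimate = x$fit$intercept,
                          favours = NA_character_))
  }
  tidy(x$model)
}

#' @describeIn select_model One-row fit summary.
#' @method glance subtype_fit
#' @export
glance.subtype_fit <- function(x, ...) {
  tibble::tibble(chosen_alpha = x$chosen_alpha,
                 final_lambda = x$final_lambda,
                 cv_accuracy_mean = x$accuracy,
                 cv_accuracy_sd = x$accuracy_sd,
                 complexity = x$fit$complexity,
                 n_resamples = max(x$records$resample))
}

#' Convergence of the resampling estimates
#'
#' Tracks how the resampling-based estimates of model complexity, accuracy
#' and the mixing factor alpha stabilize as iterations accumulate. Records
#' are first reduced to one winner per resample (the alpha with the highest
#' cross-validated accuracy in that iteration; ties to the smaller alpha);
#' at each checkpoint k the running mean and the 95% confidence interval
#' `mean +/- 1.96 * sd / sqrt(k)` over the first k winners are reported.
#' With k = 1 the sd is undefined and the bounds are `NA`.
#'
#' @param records Tibble from [resample_cv()].
#' @param checkpoints Increasing positive integers, each at most the number
#'   of resamples present.
#' @return A tibble with columns `checkpoint`, `metric` (one of
#'   `complexity`, `cv_accuracy`, `alpha`), `mean`, `lower`, `upper`.
#' @export
convergence_summary <- function(records, checkpoints) {
  if (any(checkpoints < 1)) stop("checkpoints must be positive", call. = FALSE)
  n_res <- max(records$resample)
  if (any(checkpoints > n_res)) {
    stop("checkpoint exceeds the number of resamples (", n_res, ")", call. = FALSE)
  }
  winners <- records |>
    dplyr::group_by(.data$resample) |>
    dplyr::filter(.data$cv_accuracy == max(.data$cv_accuracy)) |>
    dplyr::slice_min(.data$alpha, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$resample)
  purrr::map_dfr(sort(unique(as.integer(checkpoints))), function(k) {
    w <- winners[seq_len(k), ]
    purrr::map_dfr(
      c(complexity = "complexity", cv_accuracy = "cv_accuracy", alpha = "alpha"),
      function(col) {
        m <- mean(w[[col]])
        s <- if (k > 1L) stats::sd(w[[col]]) else NA_real_
        hw <- 1.96 * s / sqrt(k)
        tibble::tibble(checkpoint = k, mean = m, lower = m - hw, upper = m + hw)
      },
      .id = "metric"
    )
  }) |>
    dplyr::select("checkpoint", "metric", "mean", "lower", "upper")
}
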