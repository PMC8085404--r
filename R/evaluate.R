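#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen LUAD sample receives a higher
#' predicted probability than a randomly chosen LUSC sample, with ties
#' counted half: `(#concordant + 0.5 #tied) / (#LUAD * #LUSC)` over all
#' cross-class pairs. Computed via midranks (equivalent to the pairwise
#' definition, but O(n log n)).
#'
#' @param p Numeric vector of scores/probabilities.
#' @param y Labels: 0/1, logical, or `"LUAD"`/`"LUSC"` (LUAD = positive).
#' @return The c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(p, y) {
  y <- encode_binary(y)
  if (length(p) != length(y)) stop("`p` and `y` lengths differ", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

encode_binary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("LUAD", "LUSC"))
    if (length(bad)) stop("labels must be LUAD/LUSC; got: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    return(as.integer(y == "LUAD"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
  as.integer(y)
}

#' ROC curve operating points
#'
#' Sensitivity (LUAD detection rate) and specificity (LUSC exclusion rate)
#' of the `p >= threshold` rule at every achievable threshold.
#'
#' @inheritParams c_statistic
#' @return A tibble with columns `threshold`, `sensitivity`, `specificity`,
#'   ordered by decreasing threshold, bracketed by the trivial (0,0) and
#'   (1,1) operating points.
#' @export
roc_points <- function(p, y) {
  y <- encode_binary(y)
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    pred <- p >= t
    tibble::tibble(
      threshold = t,
      sensitivity = mean(pred[y == 1L]),
      specificity = mean(!pred[y == 0L])
    )
  })
}

#' Accuracy of the thresholded call rule
#'
#' Fraction of samples whose call under `p >= theta` (LUAD) / `p < theta`
#' (LUSC) matches the true label.
#'
#' @inheritParams c_statistic
#' @param theta Threshold in `[0, 1]`.
#' @return A single number in `[0, 1]`.
#' @export
accuracy_at_threshold <- function(p, y, theta = 0.5) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  y <- encode_binary(y)
  mean((p >= theta) == (y == 1L))
}

#' Calibrate dual thresholds for confident subtyping
#'
#' Finds the subtype-specific thresholds \eqn{\theta_{LUAD}} and
#' \eqn{\theta_{LUSC}} at which confident calls reach a required
#' specificity, leaving the probabilities between them as an indeterminate
#' zone for pathologist review. Specificity of the LUAD call is measured
#' against the true-LUSC samples (fraction with `p <` \eqn{\theta_{LUAD}},
#' i.e. not mis-called LUAD), and symmetrically for the LUSC call.
#' \eqn{\theta_{LUAD}} is the smallest candidate meeting the target (the
#' most permissive confident-LUAD rule), \eqn{\theta_{LUSC}} the largest.
#' Candidates are the observed probabilities, their midpoints, and 0/1 —
#' every achievable operating point lies at one of these. When no candidate
#' meets the target the extreme threshold (1, or 0) is returned and the
#' corresponding feasibility flag is `FALSE`.
#'
#' @inheritParams c_statistic
#' @param target_specificity Required per-call specificity, in `(0.5, 1]`.
#' @return A one-row tibble: `theta_luad`, `theta_lusc`, `coverage`
#'   (fraction of all samples confidently called), `specificity_luad`,
#'   `specificity_lusc` (achieved specificities of each confident call;
#'   `NA` if no such call is made), `feasible_luad`, `feasible_lusc`.
#' @export
calibrate_thresholds <- function(p, y, target_specificity = 0.95) {
  if (target_specificity <= 0.5 || target_specificity > 1) {
    stop("target_specificity must lie in (0.5, 1]", call. = FALSE)
  }
  y <- encode_binary(y)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present", call. = FALSE)
  sp <- sort(unique(p))
  grid <- sort(unique(c(0, 1, sp, (sp[-1] + sp[-length(sp)]) / 2)))
  p_lusc <- p[y == 0L]; p_luad <- p[y == 1L]

  ok_luad <- vapply(grid, function(t) mean(p_lusc < t) >= target_specificity, logical(1))
  feasible_luad <- any(ok_luad)
  theta_luad <- if (feasible_luad) min(grid[ok_luad]) else 1

  ok_lusc <- vapply(grid, function(t) mean(p_luad > t) >= target_specificity, logical(1))
  feasible_lusc <- any(ok_lusc)
  theta_lusc <- if (feasible_lusc) max(grid[ok_lusc]) else 0

  if (theta_lusc > theta_luad) {
    # confident zones overlap: pull theta_lusc back so the pair stays ordered
    theta_lusc <- theta_luad
  }
  call_luad <- p >= theta_luad
  call_lusc <- p <= theta_lusc & !call_luad
  tibble::tibble(
    theta_luad = theta_luad,
    theta_lusc = theta_lusc,
    coverage = mean(call_luad | call_lusc),
    specificity_luad = if (any(call_luad)) mean(p_lusc < theta_luad) else NA_real_,
    specificity_lusc = if (any(call_lusc)) mean(p_luad > theta_lusc) else NA_real_,
    feasible_luad = feasible_luad,
    feasible_lusc = feasible_lusc
  )
}

#' Events-per-variable ratio
#'
#' Sample-size-per-predictor overfitting guardrail: the number of training
#' samples divided by the number of model genes. Ratios around 5 are
#' commonly cited as the minimum statistically acceptable for logistic
#' models.
#'
#' @param n_samples Number of training samples.
#' @param n_model_genes Number of predictors (model complexity), `>= 1`.
#' @return `n_samples / n_model_genes`.
#' @examples
#' events_per_variable(72, 15)  # 4.8
#' @export
events_per_variable <- function(n_samples, n_model_genes) {
  if (n_model_genes < 1) stop("n_model_genes must be at least 1", call. = FALSE)
  if (n_samples < 0) stop("n_samples must be non-negative", call. = FALSE)
  n_samples / n_model_genes
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' D is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs. The two-sided p-value uses
#' the asymptotic Kolmogorov distribution at the effective sample size
#' `n1 * n2 / (n1 + n2)`.
#'
#' @param x1,x2 Non-empty numeric vectors.
#' @return One-row tibble: `d_statistic`, `p_value`.
#' @export
ks_two_sample <- function(x1, x2) {
  if (!length(x1) || !length(x2)) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x1) || anyNA(x2)) stop("samples must not contain NA", call. = FALSE)
  pooled <- sort(unique(c(x1, x2)))
  f1 <- stats::ecdf(x1)(pooled)
  f2 <- stats::ecdf(x2)(pooled)
  d <- max(abs(f1 - f2))
  n_eff <- length(x1) * length(x2) / (length(x1) + length(x2))
  tibble::tibble(d_statistic = d, p_value = kolmogorov_sf(sqrt(n_eff) * d))
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 t^2), clamped to (0, 1]
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(101)
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(q, .Machine$double.xmin), 1)
}

#' Profile NOS cases against the typical subtypes
#'
#' Compares the predicted-probability distributions of the
#' not-otherwise-specified (NOS) cases with those of the confirmed LUAD and
#' LUSC cases: empirical CDFs (right-continuous step functions on `[0, 1]`),
#' Gaussian kernel density estimates (Silverman's bandwidth), and
#' Kolmogorov–Smirnov tests of NOS vs each typical subtype. A NOS group
#' concentrated between the two class modes — rather than mixing into them —
#' suggests the NOS cases are molecularly distinct.
#'
#' @param p_luad,p_lusc,p_nos Predicted LUAD probabilities per group
#'   (non-empty numeric vectors).
#' @return A list of class `nos_profile`: `ecdf` (tibble `group`, `x`, `F`
#'   evaluated at a common grid), `density` (tibble `group`, `x`, `y`),
#'   `ks` (tibble `comparison`, `d_statistic`, `p_value`), and
#'   `probabilities` (long tibble of the inputs).
#' @export
nos_profile <- function(p_luad, p_lusc, p_nos) {
  groups <- list(LUAD = p_luad, LUSC = p_lusc, NOS = p_nos)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop("group ", g, " is empty", call. = FALSE)
  }
  grid <- sort(unique(c(0, 1, unlist(groups))))
  ecdf_tbl <- purrr::imap_dfr(groups, function(v, g) {
    tibble::tibble(group = g, x = grid, F = stats::ecdf(v)(grid))
  })
  dens_tbl <- purrr::imap_dfr(groups, function(v, g) {
    if (length(v) >= 2L && stats::sd(v) > 0) {
      d <- stats::density(v, bw = "nrd0")
      tibble::tibble(group = g, x = d$x, y = d$y)
    } else {
      tibble::tibble(group = g, x = numeric(), y = numeric())
    }
  })
  ks_tbl <- dplyr::bind_rows(
    dplyr::mutate(ks_two_sample(p_nos, p_luad), comparison = "NOS vs LUAD"),
    dplyr::mutate(ks_two_sample(p_nos, p_lusc), comparison = "NOS vs LUSC")
  )[, c("comparison", "d_statistic", "p_value")]
  prob_tbl <- purrr::imap_dfr(groups, function(v, g) {
    tibble::tibble(group = g, probability = v)
  })
  structure(list(ecdf = ecdf_tbl, density = dens_tbl, ks = ks_tbl,
                 probabilities = prob_tbl),
            class = "nos_profile")
}

#' @export
print.nos_profile <- function(x, ...) {
  cat("<nos_profile>\n")
  print(x$ks, ...)
  invisible(x)
}
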