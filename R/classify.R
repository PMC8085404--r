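#' Predicted LUAD probability for normalized profiles
#'
#' Evaluates the logistic model
#' \eqn{\log \frac{p}{1-p} = \beta_0 + \sum_g \beta_g z_g}
#' for each sample, where \eqn{z} is the individually normalized profile.
#' The sigmoid is evaluated in a numerically stable form: no overflow or NaN
#' at any finite logit, and small tail probabilities stay strictly positive
#' (never clipped) down to the smallest representable double; probabilities
#' within half a ulp of 1 round to 1, so the complement of a near-certain
#' call should be read off the opposite-sign logit.
#'
#' @param z Tibble from [normalize_expression()] (a `gene` column plus one
#'   z column per sample). Must supply every model coefficient gene.
#' @param model A [subtype_model()]; default [published_model()].
#' @return A tibble with columns `sample_id` and `probability` (probability
#'   that the sample is LUAD).
#' @export
predict_proba <- function(z, model = published_model()) {
  stopifnot(inherits(model, "subtype_model"))
  check_expression(z)
  genes <- names(model$coefficients)
  missing <- setdiff(genes, z$gene)
  if (length(missing)) {
    stop("profile is missing model gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(genes, z$gene)
  samples <- setdiff(names(z), "gene")
  zm <- as.matrix(z[idx, samples, drop = FALSE])  # genes x samples
  logit <- model$intercept + drop(crossprod(zm, model$coefficients))
  tibble::tibble(sample_id = samples, probability = plogis_stable(logit))
}

plogis_stable <- function(eta) {
  # 1/(1+exp(-eta)) without overflow for large |eta|
  out <- numeric(length(eta))
  pos <- eta >= 0
  out[pos] <- 1 / (1 + exp(-eta[pos]))
  e <- exp(eta[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Construct a dual-threshold pair for confident calling
#'
#' Probabilities at or above `theta_luad` are confidently called LUAD,
#' at or below `theta_lusc` confidently LUSC; the open interval between
#' them is the indeterminate zone referred to pathologist review.
#'
#' @param theta_luad,theta_lusc Numbers in `[0, 1]` with
#'   `theta_lusc <= theta_luad`.
#' @return A list of class `threshold_pair`.
#' @export
threshold_pair <- function(theta_luad, theta_lusc) {
  if (!is.numeric(theta_luad) || !is.numeric(theta_lusc) ||
      length(theta_luad) != 1L || length(theta_lusc) != 1L ||
      theta_luad < 0 || theta_luad > 1 || theta_lusc < 0 || theta_lusc > 1) {
    stop("thresholds must be single numbers in [0, 1]", call. = FALSE)
  }
  if (theta_lusc > theta_luad) {
    stop("invalid thresholds: theta_lusc (", theta_lusc,
         ") must not exceed theta_luad (", theta_luad, ")", call. = FALSE)
  }
  structure(list(theta_luad = theta_luad, theta_lusc = theta_lusc),
            class = "threshold_pair")
}

#' Call subtypes from predicted probabilities
#'
#' Default single-threshold rule: `LUAD` iff `p >= 0.5`, else `LUSC` (the
#' tie at exactly 0.5 is a LUAD call). With a [threshold_pair()], the
#' dual-threshold rule applies: `LUAD` iff `p >= theta_luad`, `LUSC` iff
#' `p <= theta_lusc`, otherwise `INDETERMINATE`. A probability exactly equal
#' to a threshold yields the confident call.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param thresholds `NULL` for the single-threshold rule, or a
#'   [threshold_pair()].
#' @return Character vector in `{LUAD, LUSC, INDETERMINATE}`.
#' @export
call_subtype <- function(p, thresholds = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must be finite and in [0, 1]", call. = FALSE)
  }
  if (is.null(thresholds)) {
    return(ifelse(p >= 0.5, "LUAD", "LUSC"))
  }
  if (!inherits(thresholds, "threshold_pair")) {
    thresholds <- threshold_pair(thresholds$theta_luad, thresholds$theta_lusc)
  }
  dplyr::case_when(
    p >= thresholds$theta_luad ~ "LUAD",
    p <= thresholds$theta_lusc ~ "LUSC",
    .default = "INDETERMINATE"
  )
}

#' End-to-end subtyping of a raw expression table
#'
#' Convenience pipeline: individually normalize, predict LUAD probability,
#' and call subtypes. Deterministic — a pure function of the inputs.
#'
#' @param data Raw expression tibble (`gene` column plus sample columns).
#' @param panel A [gene_panel()] naming the housekeeping genes.
#' @param model A [subtype_model()]; default [published_model()].
#' @param thresholds `NULL` (single-threshold rule) or a [threshold_pair()].
#' @inheritParams normalize_sample
#' @return A tibble with columns `sample_id`, `probability`, `call`.
#' @examples
#' spec <- cohort_spec(n_luad = 5, n_lusc = 5, n_nos = 0, seed = 1)
#' cohort <- generate_cohort(spec)
#' panel <- generate_panel(spec)
#' model <- subtype_model(0, c(LUADg01 = 1, LUSCg01 = -1))
#' classify_samples(cohort$expression, panel, model)
#' @export
classify_samples <- function(data, panel, model = published_model(),
                             thresholds = NULL, pseudocount = 1) {
  z <- normalize_expression(data, panel, pseudocount = pseudocount)
  out <- predict_proba(z, model)
  out$call <- call_subtype(out$probability, thresholds)
  out
}
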