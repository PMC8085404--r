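#' Construct a subtype model
#'
#' A fitted logistic subtyping model on the individually normalized scale:
#' an intercept plus one coefficient per signature gene. Positive
#' coefficients favour LUAD, negative favour LUSC. Predictions require
#' input profiles to be normalized with [normalize_expression()] (per-sample
#' log2 / housekeeping-centred / z-scaled); the model carries that contract
#' in its `normalization` field.
#'
#' @param intercept Scalar intercept (log-odds of LUAD at an all-zero
#'   profile).
#' @param coefficients Named numeric vector, one finite coefficient per
#'   signature gene; names unique and non-empty.
#' @return An object of class `subtype_model`.
#' @export
subtype_model <- function(intercept, coefficients) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("`intercept` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(coefficients) || length(coefficients) == 0L) {
    stop("`coefficients` must be a non-empty named numeric vector", call. = FALSE)
  }
  nm <- names(coefficients)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("all coefficients must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicate coefficient gene names", call. = FALSE)
  if (any(!is.finite(coefficients))) stop("non-finite coefficient", call. = FALSE)
  structure(
    list(intercept = as.numeric(intercept),
         coefficients = stats::setNames(as.numeric(coefficients), nm),
         normalization = "individual-z"),
    class = "subtype_model"
  )
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("<subtype_model> ", length(x$coefficients), " signature genes, intercept ",
      format(x$intercept), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a subtype model into a coefficient table
#'
#' @param x A [subtype_model()].
#' @param ... Unused.
#' @return A tibble with columns `term` (gene name, `"(Intercept)"` first),
#'   `estimate`, and `favours` (`LUAD`/`LUSC` by coefficient sign).
#' @importFrom generics tidy
#' @method tidy subtype_model
#' @export
tidy.subtype_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    favours = c(NA_character_,
                ifelse(x$coefficients > 0, "LUAD",
                       ifelse(x$coefficients < 0, "LUSC", NA_character_)))
  )
}

#' Summarise a subtype model
#'
#' @param x A [subtype_model()].
#' @param ... Unused.
#' @return One-row tibble: number of signature genes (`n_genes`, the model
#'   complexity), counts of LUAD- and LUSC-favouring coefficients, and the
#'   intercept.
#' @importFrom generics glance
#' @method glance subtype_model
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$coefficients),
    n_positive = sum(x$coefficients > 0),
    n_negative = sum(x$coefficients < 0),
    intercept = x$intercept
  )
}

#' Read / write a subtype model as JSON
#'
#' Format: `{"intercept": <num>, "coefficients": {"GENE": <num>, ...}}`.
#' The round trip is bit-exact (coefficients serialized at full precision).
#'
#' @param path File path.
#' @return `read_model()` returns a [subtype_model()]; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("intercept", "coefficients", "normalization")
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("model file has unknown field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(obj$intercept)) stop("model file lacks an `intercept` field", call. = FALSE)
  if (is.null(obj$coefficients) || length(obj$coefficients) == 0L) {
    stop("model file lacks `coefficients`", call. = FALSE)
  }
  subtype_model(obj$intercept, unlist(obj$coefficients))
}

#' @rdname read_model
#' @param model A [subtype_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         normalization = model$normalization),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

#' The published 15-signature-gene NSCLC subtyping model
#'
#' The fixed coefficients of the published LUAD-vs-LUSC logistic classifier
#' developed on FNA NanoString panel data: 8 LUSC-favouring (negative) and
#' 7 LUAD-favouring (positive) genes plus an intercept, applied to
#' individually normalized expression profiles. Gene names are stored
#' verbatim as published (including the GPR116 symbol, an alias-prone gene
#' that is deliberately not remapped). Housekeeping-gene identities are not
#' part of the model; they come from the user's [gene_panel()].
#'
#' @return A [subtype_model()] with 15 coefficients.
#' @examples
#' m <- published_model()
#' tidy(m)
#' @export
published_model <- function() {
  subtype_model(
    intercept = 0.27297,
    coefficients = c(
      TP63      = -0.58872,
      KRT14     = -0.39198,
      ANXA8L2   = -0.27091,
      KRT5      = -0.25936,
      SERPINB13 = -0.10086,
      SNAI2     = -0.048,
      KRT6A     = -0.0221,
      PKP1      = -0.00488,
      SPINK1    =  0.00302,
      CD55      =  0.00562,
      `NKX2-1`  =  0.02709,
      MUC1      =  0.13468,
      GPR116    =  0.13792,
      PNMA2     =  0.15816,
      TMC5      =  0.31305
    )
  )
}
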