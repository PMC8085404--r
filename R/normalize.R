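#' Individually normalize one expression profile
#'
#' Per-sample ("individual") normalization: no statistic is shared across
#' samples, which keeps the transformation implementable one specimen at a
#' time in a clinical workflow. Steps, per sample:
#' \enumerate{
#'   \item \eqn{v_g = \log_2(x_g + 1)} for every panel gene;
#'   \item centre by the housekeeping reference: \eqn{c_g = v_g - \bar v_{HK}}
#'     for the diagnostic genes, where \eqn{\bar v_{HK}} is the mean of
#'     \eqn{v} over the housekeeping genes;
#'   \item z-scale across the diagnostic genes:
#'     \eqn{z_g = (c_g - \bar c)/\mathrm{sd}(c)} with the sample
#'     (n−1) standard deviation.
#' }
#' A profile whose diagnostic genes are all equal after step 2 has
#' \eqn{\mathrm{sd}(c) = 0}; it is returned as all-zero z with a degenerate
#' flag rather than NaN.
#'
#' @param raw Named non-negative numeric vector covering every panel gene.
#' @param panel A [gene_panel()].
#' @param pseudocount Added before the log2 transform (default 1), keeping
#'   zero counts finite.
#' @return A list: `z` (named numeric over the diagnostic genes, panel
#'   order) and `degenerate` (logical).
#' @export
normalize_sample <- function(raw, panel, pseudocount = 1) {
  validate_gene_panel(panel)
  missing <- setdiff(panel$gene, names(raw))
  if (length(missing)) {
    stop("sample is missing panel gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(raw[panel$gene])
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("raw expression must be finite and non-negative", call. = FALSE)
  }
  v <- log2(x + pseudocount)
  hk <- panel$role == "HOUSEKEEPING"
  diag_genes <- panel$gene[!hk]
  h <- mean(v[hk])
  c_g <- v[!hk] - h
  s <- stats::sd(c_g)
  if (length(c_g) < 2L || !is.finite(s) || s == 0) {
    return(list(z = stats::setNames(rep(0, length(c_g)), diag_genes),
                degenerate = TRUE))
  }
  z <- (c_g - mean(c_g)) / s
  list(z = stats::setNames(z, diag_genes), degenerate = FALSE)
}

#' Individually normalize an expression table
#'
#' Applies [normalize_sample()] to every sample column; each column's
#' normalized profile is a pure function of that column and the panel, so
#' results are invariant to the presence, order, or rescaling of other
#' samples.
#'
#' @param data Tibble with a `gene` column and one non-negative numeric
#'   column per sample (counts or FPKM-UQ; the same transformation applies
#'   to both platforms). Must cover every panel gene.
#' @param panel A [gene_panel()].
#' @inheritParams normalize_sample
#' @return A tibble with a `gene` column (diagnostic genes only, panel
#'   order) and one z-value column per sample, with attribute `degenerate`:
#'   a named logical vector flagging samples with zero diagnostic variance
#'   (their z columns are all zero). Retrieve it with [degenerate_samples()].
#' @examples
#' panel <- gene_panel(data.frame(
#'   gene = c("A", "B", "H1", "H2"),
#'   role = c("LUAD", "LUSC", "HOUSEKEEPING", "HOUSEKEEPING")
#' ))
#' counts <- tibble::tibble(gene = c("A", "B", "H1", "H2"), s1 = c(1, 7, 3, 3))
#' normalize_expression(counts, panel)
#' @export
normalize_expression <- function(data, panel, pseudocount = 1) {
  check_expression(data)
  validate_gene_panel(panel)
  samples <- setdiff(names(data), "gene")
  out <- tibble::tibble(gene = panel_genes(panel))
  degenerate <- stats::setNames(logical(length(samples)), samples)
  for (s in samples) {
    raw <- stats::setNames(data[[s]], data$gene)
    res <- tryCatch(
      normalize_sample(raw, panel, pseudocount = pseudocount),
      error = function(e) stop("sample '", s, "': ", conditionMessage(e), call. = FALSE)
    )
    out[[s]] <- unname(res$z)
    degenerate[s] <- res$degenerate
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Which samples of a normalized table were degenerate?
#'
#' @param z A tibble returned by [normalize_expression()].
#' @return Named logical vector (TRUE = zero diagnostic variance; the
#'   sample's z column is all zero).
#' @export
degenerate_samples <- function(z) {
  d <- attr(z, "degenerate")
  if (is.null(d)) {
    stop("`z` does not carry a degenerate attribute; was it produced by ",
         "normalize_expression()?", call. = FALSE)
  }
  d
}
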