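#' Synthetic-cohort specification
#'
#' Describes a simulated targeted-panel study: cohort composition, panel
#' layout, differential-expression strength, technical variation, and
#' platform. Defaults emulate the development cohort structure of the
#' published classifier — 47 LUAD, 25 LUSC and 11 NOS specimens measured on
#' a 67-gene panel (23 LUAD-associated, 40 LUSC-associated, 4
#' housekeeping) — with overdispersed counts and per-sample library-size
#' variation of the kind digital counting platforms show.
#'
#' @param n_luad,n_lusc,n_nos Samples per histology group.
#' @param n_luad_genes,n_lusc_genes,n_hk_genes Panel composition.
#' @param n_signal_luad,n_signal_lusc How many genes of each diagnostic
#'   role truly carry a subtype effect (the first genes of the role);
#'   `NULL` (default) means all of them. Non-signal diagnostic genes behave
#'   like housekeeping genes (zero effect) and serve as decoys in
#'   feature-selection recovery studies.
#' @param effect_log2fc Mean per-gene subtype effect on the log2 scale; a
#'   concordant role/label combination shifts the latent mean by
#'   `+effect`, a discordant one by `-effect`.
#' @param effect_sd Between-gene sd of the effect (draws are truncated at
#'   zero so a role never flips sign).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance
#'   distribution (log2 scale).
#' @param libsize_sigma sd of the per-sample log2 library factor.
#' @param dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); used on the COUNTS platform.
#' @param platform `"COUNTS"` (negative-binomial) or `"FPKM_UQ"`
#'   (log-normal noise, sd 0.25 log2 units).
#' @param nos_mode How NOS cases are generated: `"MIXTURE"` draws each NOS
#'   sample from one of the two class distributions at full strength
#'   (label hidden), `"INTERMEDIATE"` at half strength, placing NOS
#'   profiles between the class modes.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_luad = 47L, n_lusc = 25L, n_nos = 11L,
                        n_luad_genes = 23L, n_lusc_genes = 40L, n_hk_genes = 4L,
                        n_signal_luad = NULL, n_signal_lusc = NULL,
                        effect_log2fc = 2, effect_sd = 0.5,
                        baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                        libsize_sigma = 0.3, dispersion = 0.1,
                        platform = c("COUNTS", "FPKM_UQ"),
                        nos_mode = c("INTERMEDIATE", "MIXTURE"),
                        seed = 1L) {
  platform <- match.arg(platform)
  nos_mode <- match.arg(nos_mode)
  if (n_luad < 0 || n_lusc < 0 || n_nos < 0) stop("group sizes must be non-negative", call. = FALSE)
  if (n_luad_genes + n_lusc_genes < 1L) stop("panel needs at least one diagnostic gene", call. = FALSE)
  if (n_hk_genes < 1L) stop("panel needs at least one housekeeping gene", call. = FALSE)
  if (n_luad > 0 && n_luad_genes < 1L) stop("LUAD samples need at least one LUAD-role gene", call. = FALSE)
  if (n_lusc > 0 && n_lusc_genes < 1L) stop("LUSC samples need at least one LUSC-role gene", call. = FALSE)
  if (effect_log2fc < 0 || effect_sd < 0) stop("effect parameters must be non-negative", call. = FALSE)
  if (libsize_sigma < 0) stop("libsize_sigma must be non-negative", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (is.null(n_signal_luad)) n_signal_luad <- n_luad_genes
  if (is.null(n_signal_lusc)) n_signal_lusc <- n_lusc_genes
  if (n_signal_luad > n_luad_genes || n_signal_lusc > n_lusc_genes) {
    stop("signal gene counts cannot exceed role gene counts", call. = FALSE)
  }
  structure(list(n_luad = as.integer(n_luad), n_lusc = as.integer(n_lusc),
                 n_nos = as.integer(n_nos),
                 n_luad_genes = as.integer(n_luad_genes),
                 n_lusc_genes = as.integer(n_lusc_genes),
                 n_hk_genes = as.integer(n_hk_genes),
                 n_signal_luad = as.integer(n_signal_luad),
                 n_signal_lusc = as.integer(n_signal_lusc),
                 effect_log2fc = effect_log2fc, effect_sd = effect_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 libsize_sigma = libsize_sigma, dispersion = dispersion,
                 platform = platform, nos_mode = nos_mode,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Deterministic gene panel for a synthetic cohort
#'
#' Gene names are fixed by role and index (`LUADg01...`, `LUSCg01...`,
#' `HK1...`), so panels from equal specs are identical.
#'
#' @param spec A [cohort_spec()].
#' @return A [gene_panel()].
#' @examples
#' nrow(generate_panel(cohort_spec()))  # 67
#' @export
generate_panel <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  gene_panel(data.frame(
    gene = c(sprintf("LUADg%02d", seq_len(spec$n_luad_genes)),
             sprintf("LUSCg%02d", seq_len(spec$n_lusc_genes)),
             sprintf("HK%d", seq_len(spec$n_hk_genes))),
    role = c(rep("LUAD", spec$n_luad_genes),
             rep("LUSC", spec$n_lusc_genes),
             rep("HOUSEKEEPING", spec$n_hk_genes))
  ))
}

#' Generate a synthetic expression cohort with ground truth
#'
#' Simulates a gene-by-sample expression table under a latent log2 model:
#' for gene g and sample i,
#' `latent = baseline_g + s_i + e(g, i)`, where `s_i` is a per-sample
#' library factor `~ N(0, libsize_sigma)` and `e` is `+effect_g` when the
#' gene's role matches the sample's class, `-effect_g` when it opposes it,
#' and 0 for housekeeping and non-signal genes. Per-gene effects are drawn
#' once from `N(effect_log2fc, effect_sd)` truncated at zero. On the
#' COUNTS platform the observed value is a negative-binomial draw around
#' `2^latent`; on FPKM_UQ it is `2^(latent + N(0, 0.25))`. NOS samples get
#' a hidden class (fair coin) and either full-strength (`MIXTURE`) or
#' half-strength (`INTERMEDIATE`) effects in that direction.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `expression` (tibble, `gene` column plus one column per
#'   sample, non-negative; integer counts on the COUNTS platform),
#'   `labels` (tibble `sample_id`, `label`), and `truth` (list with
#'   `genes` — tibble `gene`, `role`, `effect`, `signal` — and `samples` —
#'   tibble `sample_id`, `label`, `hidden_class`, `lib_factor`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- generate_panel(spec)
  with_seed_local(spec$seed, {
    genes <- panel$gene
    roles <- panel$role
    n_genes <- length(genes)
    signal <- rep(FALSE, n_genes)
    signal[roles == "LUAD"][seq_len(spec$n_signal_luad)] <- TRUE
    signal[roles == "LUSC"][seq_len(spec$n_signal_lusc)] <- TRUE
    effect <- numeric(n_genes)
    n_sig <- sum(signal)
    if (n_sig > 0) {
      effect[signal] <- pmax(stats::rnorm(n_sig, spec$effect_log2fc, spec$effect_sd), 0)
    }
    baseline <- stats::rnorm(n_genes, spec$baseline_log2_mean, spec$baseline_log2_sd)

    labels <- c(rep("LUAD", spec$n_luad), rep("LUSC", spec$n_lusc),
                rep("NOS", spec$n_nos))
    n <- length(labels)
    if (n == 0L) stop("cohort has no samples", call. = FALSE)
    sample_ids <- sprintf("S%03d", seq_len(n))
    hidden <- labels
    nos <- labels == "NOS"
    hidden[nos] <- sample(c("LUAD", "LUSC"), sum(nos), replace = TRUE)
    strength <- ifelse(nos & spec$nos_mode == "INTERMEDIATE", 0.5, 1)
    lib <- stats::rnorm(n, 0, spec$libsize_sigma)

    vals <- matrix(0, n_genes, n, dimnames = list(genes, sample_ids))
    for (i in seq_len(n)) {
      dir <- ifelse(roles == "HOUSEKEEPING", 0,
                    ifelse(roles == hidden[i], 1, -1))
      latent <- baseline + lib[i] + strength[i] * dir * effect
      mu <- 2^latent
      vals[, i] <- if (spec$platform == "COUNTS") {
        stats::rnbinom(n_genes, mu = mu, size = 1 / spec$dispersion)
      } else {
        2^(latent + stats::rnorm(n_genes, 0, 0.25))
      }
    }
    expr <- tibble::tibble(gene = genes)
    for (j in seq_len(n)) expr[[sample_ids[j]]] <- vals[, j]
    attr(expr, "platform") <- spec$platform
    list(
      expression = expr,
      labels = tibble::tibble(sample_id = sample_ids, label = labels),
      truth = list(
        genes = tibble::tibble(gene = genes, role = roles,
                               effect = effect, signal = signal),
        samples = tibble::tibble(sample_id = sample_ids, label = labels,
                                 hidden_class = hidden, lib_factor = lib)
      )
    )
  })
}

#' End-to-end parameter-recovery study
#'
#' Runs the whole workflow on a synthetic cohort — generate, individually
#' normalize, repeated-CV elastic-net training, model selection — and
#' scores the selected model against the generator's ground truth:
#' which truly differential (signal) genes were selected, whether their
#' coefficient signs match their roles (positive for LUAD-role, negative
#' for LUSC-role), and the cross-validated accuracy estimate.
#'
#' @param spec A [cohort_spec()].
#' @param train_spec An [elastic_net_spec()].
#' @return A list of class `recovery_report`: `summary` (one-row tibble:
#'   `n_true_signal`, `n_selected`, `n_signal_selected`, `signal_recall`,
#'   `sign_agreement` — sign correctness over all selected genes,
#'   `signal_sign_agreement` — over the recovered signal genes only,
#'   `mean_cv_accuracy`, `sd_cv_accuracy`, `chosen_alpha`, `complexity`),
#'   `fit` (the [select_model()] result), `records`, and `truth`.
#' @export
end_to_end_recovery <- function(spec = cohort_spec(),
                                train_spec = elastic_net_spec()) {
  cohort <- generate_cohort(spec)
  panel <- generate_panel(spec)
  z <- normalize_expression(cohort$expression, panel)
  td <- training_data(z, cohort$labels)
  records <- resample_cv(td, train_spec)
  fit <- select_model(records, td, train_spec)
  truth <- cohort$truth$genes
  beta <- fit$fit$beta
  selected <- names(beta)[beta != 0]
  signal_genes <- truth$gene[truth$signal]
  expected_sign <- ifelse(truth$role == "LUAD", 1, -1)
  names(expected_sign) <- truth$gene
  agree <- if (length(selected)) {
    mean(sign(beta[selected]) == expected_sign[selected])
  } else NA_real_
  sel_signal <- intersect(selected, signal_genes)
  agree_signal <- if (length(sel_signal)) {
    mean(sign(beta[sel_signal]) == expected_sign[sel_signal])
  } else NA_real_
  summary <- tibble::tibble(
    n_true_signal = length(signal_genes),
    n_selected = length(selected),
    n_signal_selected = length(sel_signal),
    signal_recall = if (length(signal_genes)) {
      length(sel_signal) / length(signal_genes)
    } else NA_real_,
    sign_agreement = agree,
    signal_sign_agreement = agree_signal,
    mean_cv_accuracy = fit$accuracy,
    sd_cv_accuracy = fit$accuracy_sd,
    chosen_alpha = fit$chosen_alpha,
    complexity = fit$fit$complexity
  )
  structure(list(summary = summary, fit = fit, records = records,
                 truth = cohort$truth),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary, ...)
  invisible(x)
}
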