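test_that("penalized_objective matches hand arithmetic", {
  # one sample, y = 1, all parameters zero, no penalty: log 2
  d1 <- structure(list(x = matrix(0, 1, 2, dimnames = list("s1", c("g1", "g2"))),
                       y = 1L, sample_ids = "s1", genes = c("g1", "g2")),
                  class = "training_data")
  expect_equal(penalized_objective(0, c(0, 0), d1, 0, 0.5), log(2),
               tolerance = 1e-12)

  # data term held fixed (x = 0), penalties are pure arithmetic:
  # L1 at lambda=1, alpha=1, beta=(0.5,-0.5): +1.0
  expect_equal(penalized_objective(0, c(0.5, -0.5), d1, 1, 1) -
                 penalized_objective(0, c(0, 0), d1, 1, 1),
               1.0, tolerance = 1e-12)
  # L2 at lambda=1, alpha=0, beta=(2,0): +||beta||^2/2 = 2.0
  expect_equal(penalized_objective(0, c(2, 0), d1, 1, 0) -
                 penalized_objective(0, c(0, 0), d1, 1, 0),
               2.0, tolerance = 1e-12)

  expect_error(penalized_objective(NaN, c(0, 0), d1, 0, 0.5), "non-finite")
  expect_error(penalized_objective(0, c(0, 0), d1, -1, 0.5), "non-negative")
})

test_that("fit_elastic_net matches an independent brute-force minimizer", {
  data <- fixed_training_instance()
  for (alpha in c(0, 0.5, 1)) {
    for (lambda in c(0.002, 0.05, 0.3)) {
      fit <- fit_elastic_net(data, lambda, alpha)
      obj_fit <- penalized_objective(fit$intercept, fit$beta, data, lambda, alpha)
      obj_brute <- brute_force_enet(data, lambda, alpha)
      expect_lt(obj_fit, obj_brute + 1e-6,
                label = sprintf("objective at (lambda=%g, alpha=%g)", lambda, alpha))
    }
  }
})

test_that("lambda = 0 reproduces the unregularized maximum-likelihood fit", {
  data <- fixed_training_instance()
  fit <- fit_elastic_net(data, 0, 0.5)
  ml <- stats::glm(data$y ~ data$x, family = stats::binomial())
  expect_equal(unname(fit$intercept), unname(stats::coef(ml)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(stats::coef(ml)[-1]), tolerance = 1e-4)

  # duplicating every sample leaves the per-sample-averaged solution unchanged
  dup <- structure(list(x = rbind(data$x, data$x), y = c(data$y, data$y),
                        sample_ids = c(data$sample_ids, paste0(data$sample_ids, "b")),
                        genes = data$genes),
                   class = "training_data")
  fit_dup <- fit_elastic_net(dup, 0, 0.5)
  expect_equal(fit_dup$beta, fit$beta, tolerance = 1e-5)
})

test_that("full shrinkage at lambda >= lambda_max leaves only the intercept", {
  data <- fixed_training_instance()
  lmax <- max(lambda_path(data, 1))
  fit <- fit_elastic_net(data, lmax * 1.01, 1)
  expect_equal(unname(fit$beta), rep(0, 3))
  expect_equal(fit$complexity, 0L)
  expect_equal(fit$intercept, stats::qlogis(mean(data$y)), tolerance = 1e-6)
  expect_error(as_subtype_model(fit), "no nonzero")
})

test_that("L1 norm of the solution shrinks along the penalty path", {
  data <- fixed_training_instance(n = 30, p = 4, seed = 21)
  path <- lambda_path(data, 0.5, n_lambda = 12)
  l1 <- vapply(path, function(l) sum(abs(fit_elastic_net(data, l, 0.5)$beta)),
               numeric(1))
  # path is decreasing, so L1 norms must be non-decreasing along it
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("resample_cv is reproducible, stratified, and well-formed", {
  spec <- cohort_spec(n_luad = 12, n_lusc = 9, n_nos = 0,
                      n_luad_genes = 4, n_lusc_genes = 4, n_hk_genes = 2,
                      seed = 17)
  cohort <- generate_cohort(spec)
  z <- normalize_expression(cohort$expression, generate_panel(spec))
  td <- training_data(z, cohort$labels)
  espec <- elastic_net_spec(alpha_grid = c(0.2, 0.8), n_resamples = 4,
                            n_lambda = 25, seed = 42)
  rec1 <- resample_cv(td, espec)
  rec2 <- resample_cv(td, espec)
  expect_identical(rec1, rec2)
  expect_equal(nrow(rec1), 4 * 2)
  expect_true(all(rec1$cv_accuracy >= 0 & rec1$cv_accuracy <= 1))
  expect_true(all(rec1$complexity <= length(td$genes)))
  expect_true(all(rec1$best_lambda > 0))

  # a different seed draws different fold partitions
  f42 <- panelsubtype:::with_seed_local(panelsubtype:::resample_seed(42, 1),
                                        panelsubtype:::stratified_folds(td$y, 3))
  f43 <- panelsubtype:::with_seed_local(panelsubtype:::resample_seed(43, 1),
                                        panelsubtype:::stratified_folds(td$y, 3))
  expect_false(identical(f42, f43))

  # every stratified fold contains both classes
  for (r in 1:50) {
    fold <- panelsubtype:::with_seed_local(
      panelsubtype:::resample_seed(42, r),
      panelsubtype:::stratified_folds(td$y, 3))
    tab <- table(fold, td$y)
    expect_true(all(tab > 0))
  }
  expect_error(panelsubtype:::stratified_folds(c(1, 1, 1, 0), 3), "fewer members")
})

test_that("select_model picks the argmax alpha with ties to the smaller", {
  rec <- tibble::tibble(
    resample = rep(1:10, each = 3),
    alpha = rep(c(0.2, 0.5, 0.8), 10),
    best_lambda = 0.05,
    cv_accuracy = rep(c(0.8, 0.9, 0.8), 10),
    complexity = 5L
  )
  data <- fixed_training_instance(n = 20, p = 3, seed = 33)
  fit <- select_model(rec, data)
  expect_equal(fit$chosen_alpha, 0.5)
  expect_equal(fit$accuracy, 0.9)
  expect_equal(fit$final_lambda, 0.05)

  # exact tie between 0.2 and 0.8: the smaller alpha wins
  rec_tie <- dplyr::mutate(rec, cv_accuracy = rep(c(0.9, 0.8, 0.9), 10))
  expect_equal(select_model(rec_tie, data)$chosen_alpha, 0.2)

  g <- glance(fit)
  expect_equal(g$complexity, fit$fit$complexity)
  expect_error(select_model(rec[0, ], data), "no resampling records")
})

test_that("convergence_summary tracks running means and closed-form CI widths", {
  # constant winners: CI width 0 at every checkpoint
  const <- tibble::tibble(resample = 1:20, alpha = 0.5, best_lambda = 0.1,
                          cv_accuracy = 0.9, complexity = 7L)
  cs <- convergence_summary(const, c(5, 10, 20))
  expect_true(all(cs$upper - cs$lower == 0))
  expect_true(all(cs$mean[cs$metric == "complexity"] == 7))

  # checkpoint 1: sd undefined, bounds NA
  cs1 <- convergence_summary(const, 1)
  expect_true(all(is.na(cs1$lower)) && all(is.na(cs1$upper)))

  # i.i.d. accuracies with known sd: half-width ~ 1.96 * sd / sqrt(k)
  withr::with_seed(77, {
    acc <- stats::rnorm(1000, 0.9, 0.05)
  })
  sim <- tibble::tibble(resample = 1:1000, alpha = 0.5, best_lambda = 0.1,
                        cv_accuracy = acc, complexity = 7L)
  cs2 <- convergence_summary(sim, 1000)
  hw <- with(cs2[cs2$metric == "cv_accuracy", ], (upper - lower) / 2)
  expect_equal(hw, 1.96 * stats::sd(acc) / sqrt(1000), tolerance = 1e-12)
  expect_equal(hw, 0.0031, tolerance = 0.1)

  expect_error(convergence_summary(const, 0), "positive")
  expect_error(convergence_summary(const, 21), "exceeds")
})
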