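# explicit all-pairs concordance, the oracle for the rank-based implementation
brute_force_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

test_that("c_statistic equals all-pairs concordance", {
  # toy values
  expect_equal(c_statistic(c(0.9, 0.3, 0.6), c(1, 1, 0)), 0.5)
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      p <- round(stats::runif(n), sample(1:3, 1))  # rounding induces ties
      expect_equal(c_statistic(p, y), brute_force_auc(p, y), tolerance = 1e-12)
    }
  })
  expect_error(c_statistic(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("c_statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    y <- stats::rbinom(80, 1, 0.5)
    y[1:2] <- c(0, 1)
    p <- stats::runif(80)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
  expect_equal(c_statistic(p, y), ref, tolerance = 1e-12)
})

test_that("accuracy_at_threshold counts threshold-rule agreement", {
  expect_equal(accuracy_at_threshold(c(1, 0, 1), c(1, 0, 1), 0.5), 1.0)
  expect_equal(accuracy_at_threshold(c(0.6, 0.4), c(0, 1), 0.5), 0.0)
  expect_equal(accuracy_at_threshold(c(0.7, 0.6, 0.2), c(1, 0, 0), 0.65), 1.0)
  # at theta = 0.5 accuracy complements the Hamming distance of the calls
  withr::with_seed(47, {
    p <- stats::runif(30)
    y <- stats::rbinom(30, 1, 0.5)
  })
  calls <- as.integer(call_subtype(p) == "LUAD")
  expect_equal(accuracy_at_threshold(p, y, 0.5), 1 - sum(calls != y) / 30)
})

test_that("calibrate_thresholds reaches the target specificity", {
  # separable toy: full coverage at target 1.0
  res <- calibrate_thresholds(c(0.9, 0.8, 0.2, 0.3), c(1, 1, 0, 0), 1.0)
  expect_equal(res$coverage, 1.0)
  expect_true(res$feasible_luad && res$feasible_lusc)
  expect_lte(res$theta_lusc, res$theta_luad)
  expect_gt(res$theta_luad, 0.3)
  expect_lte(res$theta_luad, 0.8)

  # an extreme LUSC sample at p = 0.99 forces theta_luad above it
  p <- c(0.9, 0.95, 0.8, 0.99, 0.2, 0.3)
  y <- c(1, 1, 1, 0, 0, 0)
  res2 <- calibrate_thresholds(p, y, 1.0)
  expect_gt(res2$theta_luad, 0.99)
  expect_lt(res2$coverage, 1.0)

  expect_error(calibrate_thresholds(p, y, 0.4), "0.5")
})

test_that("coverage is non-increasing in the specificity target", {
  withr::with_seed(53, {
    for (i in 1:20) {
      n <- sample(20:60, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.6))
      p <- stats::plogis(stats::rnorm(n, mean = 2 * y - 1))
      targets <- c(0.6, 0.75, 0.9, 0.95, 1.0)
      cov <- vapply(targets,
                    function(t) calibrate_thresholds(p, y, t)$coverage,
                    numeric(1))
      expect_true(all(diff(cov) <= 1e-12))
      res <- calibrate_thresholds(p, y, 0.95)
      expect_lte(res$theta_lusc, res$theta_luad)
    }
  })
})

test_that("events_per_variable is the guardrail ratio", {
  expect_equal(events_per_variable(72, 15), 4.8)
  expect_equal(round(events_per_variable(72, 15)), 5)
  expect_equal(events_per_variable(15, 15), 1.0)
  expect_equal(events_per_variable(0, 15), 0.0)
  expect_error(events_per_variable(10, 0), "at least 1")
})

test_that("KS D equals the brute-force ECDF supremum", {
  brute_d <- function(x1, x2) {
    pts <- c(x1, x2)
    max(vapply(pts, function(t) abs(mean(x1 <= t) - mean(x2 <= t)), numeric(1)))
  }
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d_statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$d_statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$d_statistic, 0.5)

  withr::with_seed(59, {
    for (i in 1:50) {
      x1 <- stats::rnorm(sample(3:30, 1))
      x2 <- stats::rnorm(sample(3:30, 1), mean = stats::runif(1, -1, 1))
      res <- ks_two_sample(x1, x2)
      expect_equal(res$d_statistic, brute_d(x1, x2), tolerance = 1e-12)
      # D is invariant under a strictly monotone transform of both samples
      expect_equal(ks_two_sample(exp(x1), exp(x2))$d_statistic,
                   res$d_statistic, tolerance = 1e-12)
    }
  })
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS asymptotic p-value matches the reference implementation", {
  withr::with_seed(61, {
    for (i in 1:20) {
      x1 <- stats::rnorm(sample(10:40, 1))
      x2 <- stats::rnorm(sample(10:40, 1), mean = 0.5)
      ours <- ks_two_sample(x1, x2)
      ref <- suppressWarnings(stats::ks.test(x1, x2, exact = FALSE))
      expect_equal(ours$d_statistic, unname(ref$statistic), tolerance = 1e-12)
      # the reference evaluates its asymptotic series only to ~1e-6 absolute
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-4)
    }
  })
})

test_that("nos_profile builds ECDF/density curves and pairwise KS tests", {
  prof <- nos_profile(p_luad = c(0.9, 0.8, 0.95), p_lusc = c(0.1, 0.2),
                      p_nos = c(0.2, 0.8))
  # ECDF of {0.2, 0.8} at 0.5 is 0.5
  nos_ecdf <- prof$ecdf[prof$ecdf$group == "NOS", ]
  expect_equal(stats::approx(nos_ecdf$x, nos_ecdf$F, xout = 0.5,
                             method = "constant")$y, 0.5)
  expect_setequal(prof$ks$comparison, c("NOS vs LUAD", "NOS vs LUSC"))
  expect_true(all(prof$ks$d_statistic >= 0 & prof$ks$d_statistic <= 1))
  expect_error(nos_profile(numeric(0), 0.5, 0.5), "empty")
})

test_that("NOS drawn from the LUAD distribution rarely rejects; an intermediate mode does", {
  withr::with_seed(67, {
    null_p <- vapply(1:100, function(i) {
      luad <- stats::rbeta(40, 8, 2)
      nos <- stats::rbeta(30, 8, 2)   # same distribution as LUAD
      nos_profile(luad, stats::rbeta(40, 2, 8), nos)$ks$p_value[1]
    }, numeric(1))
  })
  expect_gte(mean(null_p > 0.05), 0.9)

  withr::with_seed(71, {
    alt_reject <- vapply(1:20, function(i) {
      luad <- stats::rbeta(40, 10, 2)          # mode near 1
      lusc <- stats::rbeta(40, 2, 10)          # mode near 0
      nos <- stats::runif(30, 0.35, 0.65)      # concentrated between the modes
      ks <- nos_profile(luad, lusc, nos)$ks
      all(ks$p_value < 0.05)
    }, logical(1))
  })
  expect_gte(mean(alt_reject), 0.9)
})
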