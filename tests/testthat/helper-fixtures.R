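# small fixtures built in code; nothing is stored on disk

toy_panel <- function() {
  gene_panel(data.frame(
    gene = c("A", "B", "H1", "H2"),
    role = c("LUAD", "LUSC", "HOUSEKEEPING", "HOUSEKEEPING")
  ))
}

# write a minimal single-sample RCC file; rows = list of character vectors
# (CodeClass, Name, Accession, Count)
write_rcc_fixture <- function(path, rows) {
  lines <- c(
    "<Header>", "FileVersion,1.7", "</Header>",
    "<Sample_Attributes>", "ID,FIX1", "</Sample_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    vapply(rows, paste, "", collapse = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  path
}

# random valid gene panel + expression table for property-style loops
random_expression <- function(n_diag = 8, n_hk = 3, n_samples = 1,
                              prefix = "s") {
  panel <- gene_panel(data.frame(
    gene = c(sprintf("D%02d", seq_len(n_diag)), sprintf("K%02d", seq_len(n_hk))),
    role = c(sample(c("LUAD", "LUSC"), n_diag, replace = TRUE),
             rep("HOUSEKEEPING", n_hk))
  ))
  data <- tibble::tibble(gene = panel$gene)
  for (j in seq_len(n_samples)) {
    data[[paste0(prefix, j)]] <- stats::rpois(n_diag + n_hk, lambda = 200)
  }
  list(panel = panel, data = data)
}

# tiny fixed training instance used by the optimizer-oracle tests
fixed_training_instance <- function(n = 10, p = 3, seed = 8) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("g%d", 1:p)))
    y <- rbinom(n, 1, plogis(x[, 1] - 0.5 * x[, 2]))
    if (length(unique(y)) == 1L) y[1] <- 1L - y[1]
  })
  structure(list(x = x, y = y, sample_ids = rownames(x), genes = colnames(x)),
            class = "training_data")
}

# independent brute-force minimizer of the penalized objective:
# split beta into positive/negative parts so the L1 term is smooth,
# then box-constrained quasi-Newton from several starts
brute_force_enet <- function(data, lambda, alpha, n_starts = 8, seed = 99) {
  p <- ncol(data$x)
  f <- function(par) {
    b0 <- par[1]
    bp <- par[2:(p + 1)]
    bm <- par[(p + 2):(2 * p + 1)]
    b <- bp - bm
    eta <- b0 + drop(data$x %*% b)
    mean(-data$y * eta + log1p(exp(eta))) +
      lambda * ((1 - alpha) * sum(b^2) / 2 + alpha * sum(bp + bm))
  }
  best <- Inf
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- c(0, abs(rnorm(2 * p, 0, 0.5)))
      o <- stats::optim(start, f, method = "L-BFGS-B",
                        lower = c(-Inf, rep(0, 2 * p)),
                        control = list(maxit = 5000, factr = 1e4))
      best <- min(best, o$value)
    }
  })
  best
}
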