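make_curve_samples <- function(a, b, n = 400, p_max = min(0.89, b * 0.94),
                               noise_sd = 0) {
  p <- p_max * seq_len(n) / n
  d <- gamma_distance(p, a, b)
  if (noise_sd > 0) d <- d * exp(stats::rnorm(n, 0, noise_sd))
  data.frame(p = p, d = d)
}

test_that("uniform-p subsampling enforces its contract", {
  set.seed(4)
  df <- data.frame(p = runif(5000, 0, 1), d = runif(5000, 0.1, 2))
  expect_error(subsample_uniform_p(df[df$p > 0.95, ], 100), "p <= 0.9")
  out <- subsample_uniform_p(df, target_n = 100, n_bins = 10, seed = 1)
  expect_equal(nrow(out), 100L)
  bins <- floor(out$p / 0.09)
  expect_true(all(table(bins) == 10))
  expect_true(all(out$p <= 0.9))
  # no-harm: output at least as uniform as the input on [0, 0.9]
  ks <- function(p) {
    p <- sort(p) / 0.9
    max(abs(p - (seq_along(p) - 0.5) / length(p)))
  }
  skewed <- data.frame(p = c(runif(4000, 0, 0.2), runif(1000, 0, 0.9)),
                       d = 1)
  sub <- subsample_uniform_p(skewed, 500, seed = 2)
  expect_lte(ks(sub$p), ks(skewed$p[skewed$p <= 0.9]))
  # determinism
  s1 <- subsample_uniform_p(df, 200, seed = 7)
  s2 <- subsample_uniform_p(df, 200, seed = 7)
  expect_identical(s1, s2)
})

test_that("noise-free data on the curve are recovered exactly", {
  # PC and EI shapes, randomized generating constants
  set.seed(10)
  for (k in 1:20) {
    a_true <- runif(1, 0.5, 8)
    b_true <- if (k %% 2 == 0) 1 else runif(1, 0.9, 0.95)
    df <- make_curve_samples(a_true, b_true)
    fit <- fit_gamma_a(df, b = b_true)
    expect_true(fit$converged)
    expect_equal(fit$a_hat, a_true, tolerance = 1e-6)
    expect_lt(fit$mse, 1e-16)
  }
})

test_that("the Gauss-Newton optimum matches brute-force minimization and nls", {
  set.seed(20)
  for (k in 1:10) {
    a_true <- runif(1, 0.8, 6)
    b <- if (k %% 2 == 0) 1 else 0.94
    df <- make_curve_samples(a_true, b, noise_sd = 0.05)
    fit <- fit_gamma_a(df, b = b)
    w <- df$d^-2
    sse <- function(a) sum(w * (df$d - gamma_distance(df$p, a, b))^2)
    a_grid <- stats::optimize(sse, c(0.2, 20), tol = 1e-12)$minimum
    expect_equal(fit$a_hat, a_grid, tolerance = 1e-6)
    # nls stops at its own (looser) relative-offset criterion
    nf <- stats::nls(d ~ a * b * ((1 - p / b)^(-1 / a) - 1), data = df,
                     start = list(a = 2), weights = df$d^-2)
    expect_equal(fit$a_hat, unname(stats::coef(nf)), tolerance = 1e-4)
  }
})

test_that("noisy data recover the generating constant within tolerance", {
  set.seed(30)
  df <- make_curve_samples(4, 0.95, n = 2000, noise_sd = 0.002)
  fit <- fit_gamma_a(df, b = 0.95)
  expect_equal(fit$a_hat, 4, tolerance = 0.01)
})

test_that("relative weighting changes the estimate on heteroscedastic data", {
  set.seed(40)
  p <- 0.88 * (1:500) / 500
  d <- gamma_distance(p, 2, 1) + stats::rnorm(500, 0, 0.25 * p)
  keep <- d > 0
  df <- data.frame(p = p[keep], d = d[keep])
  fw <- fit_gamma_a(df, b = 1, weighted = TRUE)
  fu <- fit_gamma_a(df, b = 1, weighted = FALSE)
  expect_gt(abs(fw$a_hat - fu$a_hat), 1e-3)
})

test_that("the 95% confidence interval covers the generating value", {
  set.seed(50)
  hits <- 0L
  for (r in 1:100) {
    df <- make_curve_samples(2.5, 1, n = 150, noise_sd = 0.02)
    fit <- fit_gamma_a(df, b = 1)
    if (fit$ci_low <= 2.5 && 2.5 <= fit$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("degenerate fitting inputs are rejected", {
  df <- data.frame(p = c(0.1, 0.2), d = c(0.1, 0.25))
  expect_error(fit_gamma_a(df, b = 1), "at least 10")
  dfz <- data.frame(p = rep(c(0.1, 0.3), 10), d = 0)
  expect_error(fit_gamma_a(dfz, b = 1), "at least 10")  # d = 0 excluded
  dfbad <- data.frame(p = seq(0.5, 0.99, length.out = 20),
                      d = seq(0.5, 3, length.out = 20))
  expect_error(fit_gamma_a(dfbad, b = 0.94), "p < b")
})

test_that("analytic calibration reproduces bundled constants for a reference model", {
  fit <- calibrate_analytic("Dayhoff", "PC")
  expect_true(fit$converged)
  expect_equal(fit$a_hat, 1.99924, tolerance = 0.05)
  expect_equal(fit$model_name, "Dayhoff")
  expect_equal(fit$b, 1)
  fei <- calibrate_analytic("Dayhoff", "EI")
  expect_equal(fei$b, equal_input_b(load_model("Dayhoff")), tolerance = 1e-12)
  expect_equal(fei$a_hat, 3.14582, tolerance = 0.05)
})

test_that("the uniform model's equal-input curve drives a toward infinity", {
  # its exact curve is the a -> infinity limit -b log(1 - p/b)
  fit <- suppressWarnings(calibrate_analytic(uniform_model(), "EI",
                                             n_grid = 500))
  expect_true(!fit$converged || fit$a_hat > 100)
})

test_that("simulated calibration is deterministic and exact in the long-sequence limit", {
  f1 <- calibrate_simulated("Dayhoff", "PC", n_trees = 6, n_sites = 400,
                            seed = 99, taxa_range = c(5, 8),
                            max_pairs_per_tree = 15, target_n = 500,
                            n_bins = 10)
  f2 <- calibrate_simulated("Dayhoff", "PC", n_trees = 6, n_sites = 400,
                            seed = 99, taxa_range = c(5, 8),
                            max_pairs_per_tree = 15, target_n = 500,
                            n_bins = 10)
  expect_identical(unclass(f1)[names(unclass(f1))],
                   unclass(f2)[names(unclass(f2))])
  expect_s3_class(f1, "gamma_fit")
  expect_true(f1$n_obs >= 10)
})

test_that("fit results serialize to JSON and a constants-table row", {
  fit <- calibrate_analytic("LG", "EI", n_grid = 200)
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$a_hat, fit$a_hat, tolerance = 1e-12)
  expect_equal(j$variant, "EI")
  row <- as_constants_row(fit)
  expect_equal(row$model, "LG")
  expect_equal(row$a, fit$a_hat)
})
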