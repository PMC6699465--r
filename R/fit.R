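#' Subsample (p, d) observations toward a uniform p distribution
#'
#' Discards observations with p above `p_max`, stratifies the rest into
#' equal-width p bins over `[0, p_max]`, and draws the same number from
#' each bin without replacement (capped by bin occupancy), so the retained
#' p values approximately follow a uniform distribution over `[0, p_max]`.
#'
#' @param samples Data frame with columns `p_count`, `d_count`, `n_sites`
#'   (see [simulate_pd_samples()]), or columns `p` and `d` on the
#'   proportion scale.
#' @param target_n Desired total number of retained observations (the
#'   output may be smaller when bins run dry).
#' @param p_max Upper p limit (default 0.9).
#' @param n_bins Number of equal-width strata (default 45).
#' @param seed Optional integer seed for the within-bin draws.
#' @return The subsampled data frame (rows of `samples`).
#' @export
subsample_uniform_p <- function(samples, target_n, p_max = 0.9,
                                n_bins = 45, seed = NULL) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0, target_n >= 1,
            n_bins >= 1, p_max > 0)
  p <- .samples_p(samples)
  keep <- which(p <= p_max)
  if (length(keep) == 0)
    stop("No observations with p <= ", p_max, " to subsample from.")
  .with_seed(seed, {
    bin <- pmin(floor(p[keep] / (p_max / n_bins)), n_bins - 1L)
    quota <- floor(target_n / n_bins)
    if (quota < 1) quota <- 1L
    chosen <- unlist(lapply(split(keep, bin), function(idx) {
      if (length(idx) <= quota) idx
      else idx[sample.int(length(idx), quota)]
    }), use.names = FALSE)
    samples[sort(chosen), , drop = FALSE]
  })
}

.samples_p <- function(samples) {
  if (all(c("p_count", "n_sites") %in% names(samples)))
    samples$p_count / samples$n_sites
  else if ("p" %in% names(samples)) samples$p
  else stop("samples must have columns (p_count, d_count, n_sites) or (p, d).")
}

.samples_d <- function(samples) {
  if (all(c("d_count", "n_sites") %in% names(samples)))
    samples$d_count / samples$n_sites
  else if ("d" %in% names(samples)) samples$d
  else stop("samples must have columns (p_count, d_count, n_sites) or (p, d).")
}

#' Estimate the gamma-distance shape constant a by weighted Gauss-Newton
#' regression
#'
#' Fits d = a*b*((1 - p/b)^(-1/a) - 1) to paired (p, d) observations with
#' `b` held fixed, minimizing the relative-weighted sum of squares
#' `sum(w * (d - f(p; a))^2)` with `w = d^-2`, by Gauss-Newton iteration
#' with analytic gradient, step halving on divergent steps, starting value
#' `a = 2`, relative-offset convergence at 1e-8 and at most 50 iterations.
#' Pairs with `d == 0` are excluded (their weight is undefined, and they
#' carry no information about a).
#'
#' The asymptotic standard error comes from the weighted Jacobian; the 95%
#' confidence interval uses the t quantile with n - 1 degrees of freedom.
#' The reported mean squared error is the unweighted mean of squared
#' residuals at the estimate.
#'
#' @param samples Data frame as in [subsample_uniform_p()], or a numeric
#'   vector of p values (then `d` must be given).
#' @param b Fixed saturation constant in (0, 1].
#' @param d Numeric vector of evolutionary distances when `samples` is a
#'   plain p vector.
#' @param start_a Starting value (default 2).
#' @param max_iter,tol Iteration cap (50) and relative-offset tolerance
#'   (1e-8).
#' @param weighted Use relative weighting d^-2 (default `TRUE`; `FALSE`
#'   gives ordinary least squares, mainly for diagnostics).
#' @return A `gamma_fit` object: `a_hat`, `se`, `ci_low`, `ci_high`, `mse`,
#'   `n_obs`, `converged`, `n_iter`, `b`, `variant`, `model_name`.
#' @examples
#' p <- seq(0.01, 0.85, length.out = 200)
#' d <- gamma_distance(p, a = 2.5, b = 1)
#' fit_gamma_a(data.frame(p = p, d = d), b = 1)
#' @export
fit_gamma_a <- function(samples, b, d = NULL, start_a = 2,
                        max_iter = 50, tol = 1e-8, weighted = TRUE) {
  if (is.data.frame(samples)) {
    p <- .samples_p(samples)
    dd <- .samples_d(samples)
  } else {
    stopifnot(is.numeric(samples), !is.null(d))
    p <- samples; dd <- d
  }
  .check_ab(1, b)
  keep <- dd > 0
  p <- p[keep]; dd <- dd[keep]
  if (length(p) < 10)
    stop("Need at least 10 (p, d) pairs with d > 0; have ", length(p), ".")
  if (any(p < 0) || any(p >= b))
    stop("All p must satisfy 0 <= p < b = ", b, ".")
  w <- if (weighted) dd^-2 else rep(1, length(dd))

  f <- function(a) a * b * ((1 - p / b)^(-1 / a) - 1)
  grad <- function(a) {
    u <- 1 - p / b
    ua <- u^(-1 / a)
    b * (ua - 1) + (b / a) * ua * log(u)
  }
  sse <- function(a) sum(w * (dd - f(a))^2)

  a <- start_a
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- dd - f(a)
    J <- grad(a)
    denom <- sum(w * J * J)
    if (!is.finite(denom) || denom <= 0)
      stop("Singular Jacobian in Gauss-Newton iteration (a = ",
           format(a), ").")
    delta <- sum(w * J * r) / denom
    s0 <- sum(w * r^2)
    step <- delta
    for (h in 0:20) {            # step halving on divergent steps
      a_new <- a + step
      if (a_new > 0 && is.finite(sse(a_new)) && sse(a_new) <= s0) break
      step <- step / 2
    }
    a_new <- a + step
    if (a_new <= 0) a_new <- a / 2
    done <- abs(a_new - a) <= tol * (abs(a) + tol)
    a <- a_new
    if (done) { converged <- TRUE; break }
  }

  r <- dd - f(a)
  J <- grad(a)
  n <- length(p)
  sigma2 <- sum(w * r^2) / (n - 1)
  se <- sqrt(sigma2 / sum(w * J * J))
  tq <- stats::qt(0.975, df = n - 1)
  structure(
    list(model_name = NA_character_, variant = NA_character_,
         a_hat = a, se = se, ci_low = a - tq * se, ci_high = a + tq * se,
         mse = mean(r^2), n_obs = n, converged = converged, n_iter = iter,
         b = b),
    class = "gamma_fit"
  )
}

#' Analytic calibration of the shape constant a for a model
#'
#' A deterministic shortcut to the full simulation pipeline: place `n_grid`
#' p values evenly over `(0, p_max]`, map each to the exact evolutionary
#' distance on the model's divergence curve via [invert_expected_p()]
#' (the infinite-sites limit of simulated data), and fit the gamma distance
#' by [fit_gamma_a()] with `b = 1` (PC) or `b = 1 - sum(pi^2)` (EI).
#'
#' @param model Model name, `aa_model` or `aa_rate_matrix`.
#' @param variant `"PC"` or `"EI"`.
#' @param n_grid Number of grid points (default 2000).
#' @param p_max Upper end of the p grid (default 0.9); clipped with a
#'   warning if at/above the model's saturation plateau.
#' @return A `gamma_fit` (see [fit_gamma_a()]) with model/variant filled
#'   in.
#' @examples
#' \donttest{calibrate_analytic("Dayhoff", "PC")}
#' @export
calibrate_analytic <- function(model, variant = c("PC", "EI"),
                               n_grid = 2000, p_max = 0.9) {
  rm <- .as_rate_matrix(model)
  variant <- match.arg(toupper(variant[1]), c("PC", "EI"))
  b <- if (variant == "PC") 1 else 1 - sum(rm$pi^2)
  lim <- rm$plateau * (1 - 1e-6)
  if (p_max >= lim) {
    warning("p_max = ", p_max, " is at/above the saturation plateau ",
            format(rm$plateau), " of ", rm$model_name, "; clipping.")
    p_max <- lim
  }
  p <- p_max * seq_len(n_grid) / n_grid
  d <- invert_expected_p(rm, p)
  fit <- fit_gamma_a(data.frame(p = p, d = d), b = b)
  fit$model_name <- rm$model_name
  fit$variant <- variant
  fit
}

#' Calibrate the shape constant a from simulated sequence data
#'
#' The full desk-scale pipeline: [simulate_pd_samples()] (synthetic tree
#' collection, CTMC sequence simulation, pairwise p-distances and
#' maximum-likelihood distances, integer scaling), then
#' [subsample_uniform_p()] to a roughly uniform p distribution over
#' `[0, p_max]`, then [fit_gamma_a()].  Fully deterministic given `seed`.
#'
#' @inheritParams calibrate_analytic
#' @inheritParams simulate_pd_samples
#' @param target_n Subsample size passed to [subsample_uniform_p()].
#' @param p_max Upper p limit of the uniformized sample (default 0.9).
#' @param n_bins Strata for the uniformization (default 45).
#' @return A `gamma_fit` with model/variant filled in; the `samples`
#'   attribute carries the fitted subsample for plotting.
#' @export
calibrate_simulated <- function(model, variant = c("PC", "EI"),
                                n_trees = 200, n_sites = 5000, seed = 1,
                                taxa_range = c(25, 30),
                                diameter_range = c(0.05, 20),
                                max_pairs_per_tree = 150,
                                target_n = 20000, p_max = 0.9,
                                n_bins = 45) {
  rm <- .as_rate_matrix(model)
  variant <- match.arg(toupper(variant[1]), c("PC", "EI"))
  b <- if (variant == "PC") 1 else 1 - sum(rm$pi^2)
  samples <- simulate_pd_samples(rm, n_trees = n_trees, n_sites = n_sites,
                                 seed = seed, taxa_range = taxa_range,
                                 diameter_range = diameter_range,
                                 max_pairs_per_tree = max_pairs_per_tree)
  sub <- subsample_uniform_p(samples, target_n = target_n,
                             p_max = min(p_max, b * (1 - 1e-6)),
                             n_bins = n_bins, seed = seed)
  fit <- fit_gamma_a(sub, b = b)
  fit$model_name <- rm$model_name
  fit$variant <- variant
  attr(fit, "samples") <- sub
  fit
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma-distance calibration%s%s\n  a = %.5f  (95%% CI %.5f..%.5f, SE %.2g)\n  b = %.5f (fixed), MSE = %.5g, n = %d, %s in %d iteration(s)\n",
    if (is.na(x$model_name)) "" else paste0(": ", x$model_name),
    if (is.na(x$variant)) "" else paste0(" [", x$variant, "]"),
    x$a_hat, x$ci_low, x$ci_high, x$se, x$b, x$mse, x$n_obs,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Scatter plot of calibration data with the fitted gamma-distance curve
#'
#' @param samples (p, d) data frame (counts or proportions).
#' @param fit A `gamma_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `fit`.
#' @export
plot_calibration <- function(samples, fit, ...) {
  p <- .samples_p(samples); d <- .samples_d(samples)
  graphics::plot(p, d, pch = 16, cex = 0.3, col = "grey60",
                 xlab = "uncorrected distance p",
                 ylab = "evolutionary distance d", ...)
  pp <- seq(0, max(p), length.out = 400)
  graphics::lines(pp, gamma_distance(pp, fit$a_hat, fit$b), col = "red2",
                  lwd = 2)
  invisible(fit)
}

#' Serialize a calibration result as JSON
#'
#' @param fit A `gamma_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gamma_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' One table row (published-constants shape) for a calibration result
#'
#' @param fit A `gamma_fit`.
#' @return Data frame with columns `model`, `variant`, `b`, `a`, `ci_low`,
#'   `ci_high`, `mse`.
#' @export
as_constants_row <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  data.frame(model = fit$model_name, variant = fit$variant, b = fit$b,
             a = fit$a_hat, ci_low = fit$ci_low, ci_high = fit$ci_high,
             mse = fit$mse, stringsAsFactors = FALSE)
}
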