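#' Build the normalized reversible rate matrix Q of a model
#'
#' Constructs the general time-reversible generator Q[i,j] = S[i,j] * pi[j]
#' (i != j), sets the diagonal so rows sum to zero, and rescales Q globally
#' so the expected substitution rate at stationarity, -sum(pi * diag(Q)),
#' equals 1: branch lengths are then expected substitutions per site.
#'
#' Because Q is reversible, diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric;
#' its eigendecomposition is computed once and cached so that transition
#' matrices for many branch lengths are cheap.
#'
#' @param model An `aa_model`, or a model name passed to [load_model()].
#' @return An `aa_rate_matrix`: list with `model_name`, `Q`, `pi`,
#'   `plateau` (1 - sum(pi^2), the large-distance limit of the expected
#'   p-distance), and cached spectral factors.
#' @examples
#' rm <- rate_matrix("Dayhoff")
#' range(rowSums(rm$Q))
#' @export
rate_matrix <- function(model) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "aa_model"))
  pi <- model$frequencies / sum(model$frequencies)
  S <- model$exchangeabilities
  Q <- S * rep(pi, each = 20)          # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  ## symmetrize: B = D^{1/2} Q D^{-1/2} with D = diag(pi)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2                  # kill rounding asymmetry
  eig <- eigen(B, symmetric = TRUE)
  ## a generator has an exact null eigenvalue; zero out its numerical dust
  ## so P(t) is stable for arbitrarily large t
  eig$values[abs(eig$values) < 1e-13] <- 0
  U <- eig$vectors
  ## P(t) = A exp(Lambda t) Bt  with A = D^{-1/2} U, Bt = U' D^{1/2}
  A <- U / sq
  Bt <- t(U * sq)
  ## expected_p needs only sum_i pi_i P_ii(t) = sum_k c_k exp(lambda_k t)
  cvec <- colSums(pi * (U * U))
  structure(
    list(model_name = model$name, Q = Q, pi = pi,
         plateau = 1 - sum(pi^2),
         values = eig$values, A = A, B = Bt, c = cvec),
    class = "aa_rate_matrix"
  )
}

.as_rate_matrix <- function(x) {
  if (inherits(x, "aa_rate_matrix")) x else rate_matrix(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q An `aa_rate_matrix` (or model/model name, converted on the fly).
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @return 20x20 row-stochastic matrix; tiny negative entries from floating
#'   point are clamped to 0.
#' @examples
#' P <- transition_matrix(rate_matrix("Dayhoff"), 0.5)
#' rowSums(P)
#' @export
transition_matrix <- function(Q, t) {
  rm <- .as_rate_matrix(Q)
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("Branch length t must be >= 0, got ", t)
  P <- rm$A %*% (exp(rm$values * t) * rm$B)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' Expected p-distance at evolutionary distance d
#'
#' The exact probability that two sequences separated by evolutionary
#' distance `d` differ at a site, under the model at stationarity:
#' 1 - sum_i pi_i P(d)[i,i].  Strictly increasing in `d`, from 0 at `d = 0`
#' to the saturation plateau 1 - sum(pi^2) as `d` grows.
#'
#' @param Q An `aa_rate_matrix` (or model/model name).
#' @param d Evolutionary distance(s), `>= 0`; vectorized.
#' @return Expected proportion(s) of observed differences.
#' @examples
#' expected_p(rate_matrix("Dayhoff"), c(0.1, 1, 10))
#' @export
expected_p <- function(Q, d) {
  rm <- .as_rate_matrix(Q)
  stopifnot(is.numeric(d), all(is.finite(d)))
  if (any(d < 0)) stop("Evolutionary distance d must be >= 0.")
  vapply(d, function(di) 1 - sum(rm$c * exp(rm$values * di)), numeric(1))
}

#' Invert the expected p-distance curve
#'
#' Finds the evolutionary distance `d` such that `expected_p(Q, d) == p`,
#' by bracketed root finding on the strictly monotone curve.
#'
#' @param Q An `aa_rate_matrix` (or model/model name).
#' @param p Observed proportion(s) of differences; must lie strictly below
#'   the model's saturation plateau `1 - sum(pi^2)`.
#' @param tol Absolute tolerance on `expected_p(Q, d) - p` (default 1e-12).
#' @return Evolutionary distance(s) `d >= 0`.
#' @examples
#' rm <- rate_matrix("Dayhoff")
#' invert_expected_p(rm, expected_p(rm, 0.8))
#' @export
invert_expected_p <- function(Q, p, tol = 1e-12) {
  rm <- .as_rate_matrix(Q)
  stopifnot(is.numeric(p), all(is.finite(p)))
  if (any(p < 0)) stop("p must be >= 0.")
  bad <- p >= rm$plateau * (1 - 1e-9)
  if (any(bad))
    stop("p = ", format(max(p[bad])), " is at or above the saturation ",
         "plateau 1 - sum(pi^2) = ", format(rm$plateau),
         " of model ", rm$model_name, "; the curve cannot be inverted there.")
  vapply(p, function(pi1) {
    if (pi1 == 0) return(0)
    upper <- 1
    while (expected_p(rm, upper) < pi1) upper <- upper * 2
    stats::uniroot(function(d) expected_p(rm, d) - pi1,
                   lower = 0, upper = upper,
                   tol = min(tol, 1e-12), maxiter = 200)$root
  }, numeric(1))
}

#' Pairwise maximum-likelihood evolutionary distance
#'
#' Estimates the evolutionary distance separating two aligned sequences by
#' maximizing the standard pairwise likelihood
#' `sum_ij n_ij log(pi_i P(t)[i,j])` over `t >= 0`, where `n_ij` counts
#' alignment sites with residue i in one sequence and j in the other.
#' One-dimensional Brent optimization on `t` in `[1e-9, 1000]`.
#'
#' @param model An `aa_model`, model name, or `aa_rate_matrix`.
#' @param pair_counts 20x20 matrix of nonnegative site-pattern counts
#'   (ARNDCQEGHILKMFPSTWYV order).
#' @param tol Optimization tolerance (default 1e-8).
#' @return Nonnegative scalar distance estimate; exactly 0 for identical
#'   sequences (all counts on the diagonal).
#' @export
ml_pairwise_distance <- function(model, pair_counts, tol = 1e-8) {
  rm <- .as_rate_matrix(model)
  stopifnot(is.matrix(pair_counts), all(dim(pair_counts) == c(20L, 20L)))
  if (any(pair_counts < 0)) stop("pair_counts must be nonnegative.")
  n_tot <- sum(pair_counts)
  if (n_tot == 0) stop("pair_counts are all zero: no sites to compare.")
  off <- pair_counts
  diag(off) <- 0
  if (sum(off) == 0) return(0)
  nz <- which(pair_counts > 0)
  n <- pair_counts[nz]
  pii <- rm$pi[((nz - 1L) %% 20L) + 1L]   # row index i of each nonzero cell
  negll <- function(t) {
    P <- rm$A %*% (exp(rm$values * t) * rm$B)
    v <- pii * P[nz]
    v[v < 1e-300] <- 1e-300
    -sum(n * log(v))
  }
  ## Brent on log(t): the likelihood is unimodal in t but flat across the
  ## saturation plateau, which spans most of [1e-9, 1000] on a linear
  ## scale; geometric probing avoids collapsing into the flat region.
  coarse <- stats::optimize(function(lt) negll(exp(lt)),
                            interval = log(c(1e-9, 1000)), tol = 1e-6)
  t0 <- exp(coarse$minimum)
  opt <- stats::optimize(negll, interval = c(max(1e-9, t0 / 3),
                                             min(1000, t0 * 3)), tol = tol)
  ## likelihood can be monotone decreasing for (near-)identical sequences
  if (negll(1e-9) <= opt$objective) return(0)
  opt$minimum
}
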