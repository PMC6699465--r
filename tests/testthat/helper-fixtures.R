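# Shared fixtures, all built in code.

# 20-state Jukes-Cantor-like model: equal exchangeabilities, uniform
# frequencies.  Its divergence curve has the closed form
# p(d) = 0.95 * (1 - exp(-d / 0.95)).
uniform_model <- function() {
  S <- matrix(1, 20, 20, dimnames = list(protgamma:::AA_ORDER,
                                         protgamma:::AA_ORDER))
  diag(S) <- 0
  structure(
    list(name = "uniform20", exchangeabilities = S,
         frequencies = stats::setNames(rep(1 / 20, 20),
                                       protgamma:::AA_ORDER),
         file = NA_character_),
    class = "aa_model"
  )
}

jc20_p <- function(d) 0.95 * (1 - exp(-d / 0.95))
jc20_d <- function(p) -0.95 * log(1 - p / 0.95)

# Write a tiny synthetic PAML-format model file; returns its path.
write_toy_dat <- function(path = tempfile(fileext = ".dat")) {
  S <- matrix(0, 20, 20)
  S[upper.tri(S)] <- seq_len(190)          # distinct values, row-major file
  S <- S + t(S)
  freq <- (1:20) / sum(1:20)
  lines <- vapply(2:20, function(i)
    paste(sprintf("%.17g", S[i, seq_len(i - 1)]), collapse = " "),
    character(1))
  writeLines(c(lines, "", paste(sprintf("%.17g", freq), collapse = " ")),
             path)
  path
}

# Deterministic exact site-pattern counts n_ij = round(N * pi_i * P(t)_ij).
exact_pair_counts <- function(rm, t, N = 1e6) {
  P <- transition_matrix(rm, t)
  round(N * outer(rm$pi, rep(1, 20)) * P)
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
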