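#' Gamma distance: correct an observed p-distance into an evolutionary
#' distance
#'
#' Implements d = a * b * ((1 - p/b)^(-1/a) - 1).  With `b = 1` this is the
#' Poisson-correction (PC) gamma distance; with `b = 1 - sum(pi^2)` the
#' equal-input (EI) gamma distance.  `a` captures the heterogeneity of
#' replacement rates among residue pairs and sites; `b` is the saturation
#' plateau of the expected p-distance.
#'
#' @param p Observed proportion(s) of differences, `0 <= p`; vectorized.
#' @param a Positive shape constant.
#' @param b Saturation constant in (0, 1].
#' @return Evolutionary distance(s).  Values of `p` at or beyond the
#'   saturation plateau (`p >= b * (1 - 1e-9)`) yield `Inf`, the in-memory
#'   saturated sentinel; writers serialize it as a finite placeholder (see
#'   [write_phylip_dm()]).
#' @examples
#' gamma_distance(0.5, a = 1, b = 1)       # p/(1-p) = 1
#' gamma_distance(0.5, a = 2, b = 1)       # 2*(sqrt(2)-1)
#' @export
gamma_distance <- function(p, a, b) {
  .check_ab(a, b)
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0)) stop("p must be finite and >= 0.")
  out <- ifelse(p >= b * (1 - 1e-9),
                Inf,
                a * b * ((1 - p / b)^(-1 / a) - 1))
  ## exact zero at p = 0 regardless of rounding
  out[p == 0] <- 0
  out
}

#' Inverse gamma distance: expected p at evolutionary distance d
#'
#' The inverse of [gamma_distance()]: p = b * (1 - (1 + d/(a*b))^(-a)).
#' Approaches `b` as `d` grows.
#'
#' @param d Evolutionary distance(s), `>= 0`; vectorized.
#' @inheritParams gamma_distance
#' @return Uncorrected distance(s) in `[0, b)`.
#' @export
inverse_gamma_distance <- function(d, a, b) {
  .check_ab(a, b)
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("d must be >= 0.")
  b * (1 - (1 + d / (a * b))^(-a))
}

.check_ab <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) stop("Shape constant a must be > 0.")
  if (!is.finite(b) || b <= 0 || b > 1) stop("Constant b must be in (0, 1].")
  invisible(TRUE)
}

#' Uncorrected distance (p-distance) between two aligned sequences
#'
#' Proportion of differing sites among compared sites.  Pairwise deletion:
#' a site is compared only if both residues are one of the 20 canonical
#' amino acids; gaps (`-`, `.`), ambiguity codes (B, Z, X, J, U, O) and `?`
#' are excluded.  Case-insensitive.
#'
#' @param seq1,seq2 Character scalars (sequence strings) or character
#'   vectors of single residues; must be the same length.
#' @return List with `p` (proportion of differences) and `n_compared`
#'   (number of sites compared).
#' @examples
#' p_distance("ACDE", "ACDF")
#' p_distance("AC-E", "ACDE")   # gap site dropped
#' @export
p_distance <- function(seq1, seq2) {
  s1 <- .as_residues(seq1)
  s2 <- .as_residues(seq2)
  if (length(s1) != length(s2))
    stop("Sequences have different lengths (", length(s1), " vs ",
         length(s2), "); they must be aligned.")
  if (length(s1) == 0) stop("Empty sequences.")
  ok <- s1 %in% AA_ORDER & s2 %in% AA_ORDER
  n <- sum(ok)
  if (n == 0) stop("No comparable sites (all positions carry a gap or ",
                   "non-canonical residue in at least one sequence).")
  list(p = sum(s1[ok] != s2[ok]) / n, n_compared = n)
}

.as_residues <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1]]
  toupper(as.character(s))
}

#' Construct an alignment object from named sequences
#'
#' @param seqs Named character vector of equal-length sequence strings, or
#'   a character matrix (taxa in rows, one residue per column).
#' @return An `aa_alignment`: character matrix of uppercase residues with
#'   taxon labels as row names.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("Sequences have unequal lengths: ",
           paste(unique(lens), collapse = ", "))
    if (lens[1] == 0) stop("Zero-length alignment.")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m))) stop("Duplicated sequence identifiers.")
  structure(m, class = "aa_alignment")
}

#' Read a protein alignment from FASTA (or relaxed sequential PHYLIP)
#'
#' @param path Input file.
#' @param format `"fasta"` (default) or `"phylip"` (relaxed sequential:
#'   header line `ntaxa nsites`, then `name sequence` records, whitespace
#'   separated, sequences possibly wrapped).
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- ape::read.FASTA(path, type = "AA")
    chs <- as.character(x)
    if (!is.matrix(chs)) {
      if (length(unique(lengths(chs))) != 1L)
        stop("Sequences in '", path, "' have unequal lengths; this reader ",
             "expects an alignment.")
      chs <- do.call(rbind, chs)
      rownames(chs) <- names(x)
    }
    return(as_alignment(toupper(chs)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("Bad PHYLIP header in '", path, "'.")
  toks <- strsplit(paste(lines[-1], collapse = " "), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  ids <- character(hdr[1]); seqs <- character(hdr[1])
  i <- 1L
  for (k in seq_len(hdr[1])) {
    ids[k] <- toks[i]; i <- i + 1L
    acc <- ""
    while (nchar(acc) < hdr[2]) {
      acc <- paste0(acc, toks[i]); i <- i + 1L
    }
    if (nchar(acc) != hdr[2]) stop("Sequence '", ids[k], "' has wrong length.")
    seqs[k] <- acc
  }
  names(seqs) <- ids
  as_alignment(seqs)
}

#' Pairwise gamma-distance matrix for an alignment
#'
#' Computes the p-distance for every sequence pair (pairwise deletion) and
#' corrects it with the gamma distance using either the bundled published
#' constants of the selected model/variant or custom constants.
#'
#' @param aln An `aa_alignment` (see [as_alignment()], [read_alignment()]).
#' @param model Model identifier (ignored when `constants` given).
#' @param variant `"PC"` or `"EI"`.
#' @param constants Optional list/object with elements `a` and `b`,
#'   overriding the published constants.
#' @return A `gamma_dm` object: list with `labels`, `distances` (symmetric
#'   matrix, `Inf` marks saturated pairs), `saturated` (logical matrix),
#'   `p` (p-distance matrix), `n_compared`, `model_name`, `variant`, `a`,
#'   `b`.
#' @examples
#' aln <- as_alignment(c(s1 = "ARNDCQ", s2 = "ARNDCE", s3 = "ARNECE"))
#' distance_matrix(aln, "Dayhoff", "PC")
#' @export
distance_matrix <- function(aln, model = NULL, variant = c("PC", "EI"),
                            constants = NULL) {
  if (!inherits(aln, "aa_alignment")) aln <- as_alignment(aln)
  variant <- match.arg(toupper(variant[1]), c("PC", "EI"))
  if (is.null(constants)) {
    if (is.null(model)) stop("Give a model name or explicit constants.")
    constants <- published_constants(model, variant)
  }
  a <- constants$a; b <- constants$b
  .check_ab(a, b)
  n <- nrow(aln)
  if (n < 2) stop("Need at least 2 sequences.")
  labels <- rownames(aln)
  code <- matrix(match(aln, AA_ORDER), n, ncol(aln))
  P <- matrix(0, n, n, dimnames = list(labels, labels))
  NC <- matrix(ncol(aln), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      nc <- sum(ok)
      if (nc == 0) {
        P[i, j] <- P[j, i] <- NA_real_
        NC[i, j] <- NC[j, i] <- 0
      } else {
        P[i, j] <- P[j, i] <- sum(code[i, ok] != code[j, ok]) / nc
        NC[i, j] <- NC[j, i] <- nc
      }
    }
  }
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  off <- upper.tri(P)
  D[off] <- ifelse(is.na(P[off]), Inf, gamma_distance_vec(P[off], a, b))
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  sat <- is.infinite(D) | is.na(P)
  diag(sat) <- FALSE
  if (any(sat))
    warning(sum(sat[upper.tri(sat)]), " sequence pair(s) saturated ",
            "(p at/above b = ", format(b), ") or without comparable sites.")
  structure(
    list(labels = labels, distances = D, saturated = sat, p = P,
         n_compared = NC,
         model_name = if (is.null(constants$model_name)) NA_character_
                      else constants$model_name,
         variant = variant, a = a, b = b),
    class = "gamma_dm"
  )
}

## vectorized core without per-call argument checks
gamma_distance_vec <- function(p, a, b) {
  out <- ifelse(p >= b * (1 - 1e-9), Inf,
                a * b * ((1 - p / b)^(-1 / a) - 1))
  out[p == 0] <- 0
  out
}

#' @export
print.gamma_dm <- function(x, digits = 6, ...) {
  cat(sprintf("Gamma distance matrix (%s, %s: a = %.5f, b = %.5f), %d taxa\n",
              ifelse(is.na(x$model_name), "custom constants", x$model_name),
              x$variant, x$a, x$b, length(x$labels)))
  print(round(x$distances, digits))
  if (any(x$saturated)) cat("Inf marks saturated pairs.\n")
  invisible(x)
}

#' Write a square PHYLIP distance matrix
#'
#' @param dm A `gamma_dm` (or plain numeric matrix with dimnames).
#' @param path Output file.
#' @param saturated_value Finite placeholder written for saturated pairs
#'   (default 30), since downstream tree builders need finite input.
#' @return `path`, invisibly.
#' @export
write_phylip_dm <- function(dm, path, saturated_value = 30) {
  D <- if (inherits(dm, "gamma_dm")) dm$distances else dm
  D[!is.finite(D)] <- saturated_value
  labels <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste0(formatC(labels[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Write a distance matrix in long TSV format
#'
#' One row per unordered pair: `taxon1 taxon2 p d saturated`.
#'
#' @inheritParams write_phylip_dm
#' @return `path`, invisibly.
#' @export
write_tsv_dm <- function(dm, path) {
  stopifnot(inherits(dm, "gamma_dm"))
  idx <- which(upper.tri(dm$distances), arr.ind = TRUE)
  df <- data.frame(
    taxon1 = dm$labels[idx[, 1]],
    taxon2 = dm$labels[idx[, 2]],
    p = dm$p[idx],
    d = dm$distances[idx],
    saturated = dm$saturated[idx]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
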