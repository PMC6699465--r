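#' @keywords internal
"_PACKAGE"

## Canonical residue order used throughout (PAML convention).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Registry of the 27 empirical substitution models.  `file` is the PAML-style
## .dat definition shipped with phangorn ("" where no definition file is
## redistributed in any installed source; published constants still cover
## those models, but load_model() cannot).
.pg_registry <- data.frame(
  name = c("Dayhoff", "BLOSUM62", "JTT", "mtREV", "mtMam", "cpREV", "VT",
           "WAG", "WAG*", "rtREV", "PMB", "DCMut-Dayhoff", "DCMut-JTT",
           "HIVb", "HIVw", "MtArt", "LG", "MtZoa", "cpREV64", "FLU",
           "gcpREV", "stmtREV", "AB", "mtInv", "mtMet", "mtVer", "DEN"),
  file = c("Dayhoff.dat", "Blosum62.dat", "JTT.dat", "mtREV24.dat",
           "mtmam.dat", "cpREV.dat", "VT.dat", "wag.dat", "", "RtREV.dat",
           "", "dayhoff-dcmut.dat", "jtt-dcmut.dat", "HIVb.dat", "HIVw.dat",
           "mtArt.dat", "lg.dat", "MtZoa.dat", "", "FLU.dat",
           "", "", "", "", "", "", ""),
  stringsAsFactors = FALSE
)

## Extra lookup keys on top of the case-folded canonical names.
.pg_aliases <- c(
  "wagstar"        = "WAG*",
  "wag star"       = "WAG*",
  "mtrev24"        = "mtREV",
  "blosum"         = "BLOSUM62",
  "dcmut"          = "DCMut-Dayhoff",
  "dayhoff-dcmut"  = "DCMut-Dayhoff",
  "dayhoff_dcmut"  = "DCMut-Dayhoff",
  "jtt-dcmut"      = "DCMut-JTT",
  "jtt_dcmut"      = "DCMut-JTT"
)

.pg_fold <- function(x) tolower(trimws(x))

#' Resolve a model name to its canonical Table-style spelling
#'
#' Matching is case-insensitive and understands common aliases
#' (e.g. `"wagstar"` for `"WAG*"`, `"mtREV24"` for `"mtREV"`).
#'
#' @param name Character scalar, a model identifier.
#' @return Canonical model name (character scalar).
#' @export
resolve_model_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- .pg_fold(name)
  hit <- match(key, .pg_fold(.pg_registry$name))
  if (!is.na(hit)) return(.pg_registry$name[hit])
  if (key %in% names(.pg_aliases)) return(unname(.pg_aliases[key]))
  stop("Unknown amino acid substitution model '", name, "'. Valid names: ",
       paste(.pg_registry$name, collapse = ", "), call. = FALSE)
}

#' List the bundled empirical amino acid substitution models
#'
#' @return A data frame with one row per model: `name` (canonical spelling),
#'   `has_definition` (whether the full replacement matrix and frequency
#'   vector are available so the model can be loaded, simulated from and
#'   calibrated), and `has_constants` (whether published gamma-distance
#'   constants are bundled; always `TRUE`).
#' @examples
#' list_models()
#' @export
list_models <- function() {
  data.frame(
    name = .pg_registry$name,
    has_definition = nzchar(.pg_registry$file),
    has_constants = TRUE,
    stringsAsFactors = FALSE
  )
}

.pg_model_file <- function(canonical) {
  f <- .pg_registry$file[match(canonical, .pg_registry$name)]
  if (!nzchar(f)) {
    stop("No replacement matrix definition is available for model '",
         canonical, "': its PAML-format file is not redistributed in this ",
         "installation. Models with definitions: ",
         paste(.pg_registry$name[nzchar(.pg_registry$file)], collapse = ", "),
         ". Published gamma constants for '", canonical,
         "' remain available via published_constants().", call. = FALSE)
  }
  path <- system.file("extdata", f, package = "phangorn")
  if (!nzchar(path)) stop("Model definition file '", f, "' not found.")
  path
}

#' Read a PAML-format amino acid replacement matrix file
#'
#' Parses the standard PAML `.dat` dialect: 190 lower-triangular
#' exchangeabilities (19 rows) followed by 20 equilibrium frequencies, in
#' ARNDCQEGHILKMFPSTWYV order.  Non-numeric tokens (residue labels, comment
#' text) are ignored; numeric tokens beyond the first 210 (ancillary counts
#' present in some distributions) are ignored too.
#'
#' @param path Path to the `.dat` file.
#' @param name Model name to attach to the result.
#' @return An `aa_model` object: list with `name`, `exchangeabilities`
#'   (symmetric 20x20 matrix, zero diagonal), `frequencies` (length-20
#'   vector renormalized to sum to 1), and `file`.
#' @export
read_paml_dat <- function(path, name = basename(path)) {
  raw <- scan(path, what = "character", quiet = TRUE)
  num <- suppressWarnings(as.numeric(raw))
  num <- num[!is.na(num)]
  if (length(num) < 210)
    stop("'", path, "' does not look like a PAML amino acid model file: ",
         "found ", length(num), " numeric tokens, need at least 210.")
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  ## the file lists the lower triangle row by row; filling the upper
  ## triangle (column-major) visits cells in exactly that order
  S[upper.tri(S)] <- num[1:190]
  S <- S + t(S)
  if (any(S < 0)) stop("Negative exchangeability in '", path, "'.")
  freq <- num[191:210]
  if (any(freq < 0) || abs(sum(freq) - 1) > 0.02)
    stop("Frequency block of '", path, "' does not sum to ~1 (sum = ",
         format(sum(freq)), ").")
  freq <- freq / sum(freq)
  names(freq) <- AA_ORDER
  structure(
    list(name = name, exchangeabilities = S, frequencies = freq, file = path),
    class = "aa_model"
  )
}

#' Load an empirical amino acid substitution model
#'
#' Returns the model's symmetric exchangeability matrix and equilibrium
#' frequency vector, parsed from the PAML-format definition file.
#'
#' @param name Model identifier (case-insensitive; aliases accepted, see
#'   [resolve_model_name()]).
#' @return An `aa_model` object (see [read_paml_dat()]).
#' @examples
#' m <- load_model("Dayhoff")
#' sum(m$frequencies)
#' @export
load_model <- function(name) {
  canonical <- resolve_model_name(name)
  mod <- read_paml_dat(.pg_model_file(canonical), name = canonical)
  mod
}

#' Equal-input saturation constant b = 1 - sum(pi^2)
#'
#' The expected p-distance between two sequences saturates, as divergence
#' grows, at one minus the sum of squared equilibrium frequencies.  This is
#' the `b` used by the equal-input (EI) gamma distance.
#'
#' @param model An `aa_model`, or a model name passed to [load_model()].
#' @return Numeric scalar in (0, 1).
#' @examples
#' equal_input_b(load_model("WAG"))
#' @export
equal_input_b <- function(model) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "aa_model"))
  pi <- model$frequencies / sum(model$frequencies)
  1 - sum(pi^2)
}

.pg_constants_env <- new.env(parent = emptyenv())

.pg_constants_table <- function() {
  if (is.null(.pg_constants_env$tab)) {
    path <- system.file("extdata", "gamma_constants.tsv", package = "protgamma")
    .pg_constants_env$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .pg_constants_env$tab
}

#' Published gamma-distance constants for a model
#'
#' Returns the bundled shape constant `a` (with 95% confidence interval and
#' mean squared error of the original fit) and saturation constant `b` for
#' one of the 27 empirical models, for either the Poisson-correction (PC,
#' b = 1) or equal-input (EI, b = 1 - sum(pi^2)) gamma distance.
#'
#' @param name Model identifier.
#' @param variant `"PC"` or `"EI"` (case-insensitive).
#' @return A `gamma_constants` object: list with `model_name`, `variant`,
#'   `a`, `b`, `ci_low`, `ci_high`, `mse`.
#' @examples
#' published_constants("Dayhoff", "PC")
#' published_constants("BLOSUM62", "EI")
#' @export
published_constants <- function(name, variant = c("PC", "EI")) {
  canonical <- resolve_model_name(name)
  variant <- toupper(variant)
  variant <- match.arg(variant, c("PC", "EI"))
  tab <- .pg_constants_table()
  row <- tab[tab$model == canonical & tab$variant == variant, ]
  if (nrow(row) != 1L)
    stop("No published constants for (", canonical, ", ", variant, ").")
  structure(
    list(model_name = canonical, variant = variant, a = row$a, b = row$b,
         ci_low = row$ci_low, ci_high = row$ci_high, mse = row$mse),
    class = "gamma_constants"
  )
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Empirical amino acid substitution model:", x$name, "\n")
  cat("  exchangeabilities: 20 x 20 symmetric, ",
      sum(x$exchangeabilities[lower.tri(x$exchangeabilities)] > 0),
      " nonzero pairs\n", sep = "")
  cat("  equilibrium frequencies: sum =", format(sum(x$frequencies)),
      " (b =", format(round(1 - sum(x$frequencies^2), 5)), ")\n")
  invisible(x)
}

#' @export
print.gamma_constants <- function(x, ...) {
  cat(sprintf("%s gamma constants for %s: a = %.5f [%.5f, %.5f], b = %.5f (MSE %.5f)\n",
              x$variant, x$model_name, x$a, x$ci_low, x$ci_high, x$b, x$mse))
  invisible(x)
}
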