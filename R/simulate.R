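## Seed helper: set the RNG deterministically for a call without clobbering
## the caller's stream state when no seed is requested.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

.check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("Tree has no branch lengths.")
  if (any(tree$edge.length < 0)) stop("Negative branch length in tree.")
  if (anyDuplicated(tree$tip.label)) stop("Duplicated tip labels.")
  if (length(tree$tip.label) < 2) stop("Tree must have >= 2 taxa.")
  invisible(tree)
}

#' Simulate sequence evolution along a phylogenetic tree
#'
#' Draws a root sequence i.i.d. from the model's equilibrium frequencies
#' and evolves it along every branch by sampling each site's end state from
#' the row of P(t) = exp(Qt) given its start state (only endpoint states
#' matter for observed differences, so no event-by-event simulation is
#' needed).  Homogeneous rates across sites, no indels.
#'
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per site.
#' @param model Model name, `aa_model` or `aa_rate_matrix`.
#' @param n_sites Number of simulated residues per sequence.
#' @param seed Optional integer seed; the same seed reproduces the
#'   alignment exactly.
#' @return An `aa_alignment` holding the leaf sequences.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
#' simulate_alignment(tr, "Dayhoff", 100, seed = 1)
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  .check_tree(tree)
  stopifnot(is.numeric(n_sites), length(n_sites) == 1L, n_sites >= 1)
  n_sites <- as.integer(n_sites)
  rm <- .as_rate_matrix(model)
  .with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tr$tip.label)
    root <- n_tip + 1L
    n_node <- n_tip + tr$Nnode
    states <- vector("list", n_node)
    states[[root]] <- sample.int(20L, n_sites, replace = TRUE, prob = rm$pi)
    ## preorder: parents before children
    edges <- rev(seq_len(nrow(tr$edge)))
    for (e in edges) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      P <- transition_matrix(rm, tr$edge.length[e])
      src <- states[[par]]
      out <- integer(n_sites)
      for (s in unique(src)) {
        idx <- which(src == s)
        out[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[[child]] <- out
    }
    m <- do.call(rbind, lapply(seq_len(n_tip), function(i)
      AA_ORDER[states[[i]]]))
    rownames(m) <- tr$tip.label
    as_alignment(m)
  })
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, labelled by tips.
#' @export
patristic_matrix <- function(tree) {
  .check_tree(tree)
  stats::cophenetic(tree)
}

#' Tree diameter: the maximum patristic distance
#'
#' @inheritParams patristic_matrix
#' @return Numeric scalar.
#' @export
tree_diameter <- function(tree) {
  max(patristic_matrix(tree))
}

#' Select trees whose diameters track a regular grid
#'
#' For each grid value m (default: 0.0001 to 20 in steps of 0.001, i.e.
#' 20,000 values), picks the eligible tree (at least `min_taxa` taxa) whose
#' diameter is closest to m; ties go to the earlier tree in the input.  The
#' same tree may be picked for several grid values unless `dedup = TRUE`.
#'
#' @param trees A `multiPhylo` or list of `phylo` trees.
#' @param start,stop,step Diameter grid (inclusive of `start`, stepping by
#'   `step` while `<= stop`).
#' @param min_taxa Minimum number of leaves for a tree to be eligible.
#' @param dedup If `TRUE`, drop repeated picks, keeping first occurrence.
#' @return A data frame with columns `m` (grid value), `index` (position of
#'   the picked tree in `trees`) and `diameter`.
#' @export
select_trees_by_diameter <- function(trees, start = 0.0001, stop = 20,
                                     step = 0.001, min_taxa = 25,
                                     dedup = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) > 0)
  ntaxa <- vapply(trees, function(t) length(t$tip.label), integer(1))
  eligible <- which(ntaxa >= min_taxa)
  if (length(eligible) == 0)
    stop("No tree with at least ", min_taxa, " taxa.")
  diam <- vapply(trees[eligible], tree_diameter, numeric(1))
  m <- seq(start, stop, by = step)
  ## nearest eligible diameter per m; which.min is first-wins, and
  ## `eligible` preserves input order, so ties go to the earlier tree
  pick <- vapply(m, function(mk) which.min(abs(diam - mk)), integer(1))
  out <- data.frame(m = m, index = eligible[pick], diameter = diam[pick])
  if (dedup) out <- out[!duplicated(out$index), ]
  out
}

#' Scale a (p, d) pair to integer counts
#'
#' Multiplies the proportion of observed differences and the evolutionary
#' distance by the number of sites and rounds half away from zero, giving
#' the integer representation used by the calibration data blocks.
#'
#' @param p Proportion(s) of observed differences in \\[0, 1\\].
#' @param d Evolutionary distance(s), `>= 0`.
#' @param n_sites Alignment length.
#' @return Data frame with integer columns `p_count`, `d_count` and
#'   `n_sites`.
#' @examples
#' to_integer_counts(0.123456, 0.2, 50000)
#' @export
to_integer_counts <- function(p, d, n_sites) {
  stopifnot(is.numeric(p), is.numeric(d), length(p) == length(d))
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1].")
  if (any(d < 0)) stop("d must be >= 0.")
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)   # half away from zero
  data.frame(p_count = as.integer(rnd(p * n_sites)),
             d_count = as.integer(rnd(d * n_sites)),
             n_sites = as.integer(n_sites))
}

#' Generate a synthetic collection of random phylogenetic trees
#'
#' Random topologies built by uniform coalescent-style joins of lineages,
#' with i.i.d. exponential branch lengths, each tree rescaled so that the
#' collection's diameters are evenly spread across `diameter_range`.  A
#' synthetic stand-in for a large database of real gene trees: what matters
#' downstream is the spread of patristic distances and taxon counts.
#'
#' @param n_trees Number of trees.
#' @param taxa_range Integer range `c(min, max)` of leaf counts (sampled
#'   uniformly).
#' @param diameter_range Range of target diameters.
#' @param seed Optional integer seed.
#' @return A `multiPhylo` object.
#' @export
generate_tree_collection <- function(n_trees, taxa_range = c(25, 50),
                                     diameter_range = c(0.0001, 20),
                                     seed = NULL) {
  stopifnot(n_trees >= 1, length(taxa_range) == 2, taxa_range[1] >= 2,
            length(diameter_range) == 2, all(diameter_range > 0))
  .with_seed(seed, {
    targets <- seq(diameter_range[1], diameter_range[2],
                   length.out = max(n_trees, 2))[seq_len(n_trees)]
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      n <- sample(seq(taxa_range[1], taxa_range[2]), 1L)
      frag <- sprintf("t%d_%d", i, seq_len(n))
      len <- rep(NA_real_, n)
      repeat {
        k <- length(frag)
        if (k == 1L) break
        pair <- sample.int(k, 2L)
        bl <- stats::rexp(2, rate = 2)
        merged <- sprintf("(%s:%.10f,%s:%.10f)",
                          frag[pair[1]], bl[1], frag[pair[2]], bl[2])
        frag <- c(frag[-pair], merged)
      }
      tr <- ape::read.tree(text = paste0(frag, ";"))
      dia <- tree_diameter(tr)
      tr$edge.length <- tr$edge.length * (targets[i] / dia)
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
    trees
  })
}

#' Simulate calibration data: paired (p, d) observations
#'
#' The native desk-scale data-generating pipeline: generate a synthetic
#' tree collection spanning a range of diameters, simulate an alignment on
#' each tree, compute pairwise p-distances (a random subset of pairs per
#' tree to bound cost), re-estimate each pair's evolutionary distance by
#' pairwise maximum likelihood under the same model, and convert each
#' (p, d) pair to integer counts.
#'
#' @param model Model name, `aa_model` or `aa_rate_matrix`.
#' @param n_trees Number of trees.
#' @param n_sites Sites per simulated sequence.
#' @param seed Integer seed (required: the data are the point).
#' @param taxa_range Leaf-count range per tree.
#' @param diameter_range Tree diameter range.
#' @param max_pairs_per_tree Cap on sequence pairs sampled per tree.
#' @return A `DistanceSample` data frame: `p_count`, `d_count`, `n_sites`,
#'   plus `tree_id`; attribute `"seed"` records the seed.
#' @export
simulate_pd_samples <- function(model, n_trees = 200, n_sites = 5000,
                                seed = 1, taxa_range = c(25, 30),
                                diameter_range = c(0.05, 20),
                                max_pairs_per_tree = 150) {
  rm <- .as_rate_matrix(model)
  .with_seed(seed, {
    trees <- generate_tree_collection(n_trees, taxa_range, diameter_range,
                                      seed = NULL)
    res <- vector("list", n_trees)
    for (ti in seq_len(n_trees)) {
      tr <- trees[[ti]]
      aln <- simulate_alignment(tr, rm, n_sites, seed = NULL)
      code <- matrix(match(aln, AA_ORDER), nrow(aln), ncol(aln))
      n <- nrow(code)
      pairs <- utils::combn(n, 2)
      if (ncol(pairs) > max_pairs_per_tree)
        pairs <- pairs[, sample.int(ncol(pairs), max_pairs_per_tree),
                       drop = FALSE]
      p <- numeric(ncol(pairs)); d <- numeric(ncol(pairs))
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        counts <- matrix(tabulate((code[i, ] - 1L) * 20L + code[j, ],
                                  nbins = 400L), 20, 20, byrow = TRUE)
        p[k] <- 1 - sum(diag(counts)) / n_sites
        d[k] <- ml_pairwise_distance(rm, counts)
      }
      ic <- to_integer_counts(p, pmin(d, 1e6), n_sites)
      ic$tree_id <- ti
      res[[ti]] <- ic
    }
    out <- do.call(rbind, res)
    attr(out, "seed") <- seed
    attr(out, "model_name") <- rm$model_name
    out
  })
}

#' Write (p, d) calibration samples as a TSV block file
#'
#' Header comment lines carry the model name and seed so a block file is
#' self-describing and reproducible.
#'
#' @param samples Data frame from [simulate_pd_samples()] (columns
#'   `p_count`, `d_count`, `n_sites`, optionally `tree_id`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pd_blocks <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# model=", attr(samples, "model_name") %||% "NA"),
    paste0("# seed=", attr(samples, "seed") %||% "NA")
  ), con)
  utils::write.table(samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a (p, d) TSV block file written by [write_pd_blocks()]
#'
#' @param path Input file.
#' @return Data frame with the block's columns; `seed` and `model_name`
#'   attributes restored from the header when present.
#' @export
read_pd_blocks <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                       collapse = "\n"))
  seed <- sub("^# seed=", "", grep("^# seed=", hdr, value = TRUE))
  model <- sub("^# model=", "", grep("^# model=", hdr, value = TRUE))
  if (length(seed)) attr(df, "seed") <- suppressWarnings(as.numeric(seed))
  if (length(model)) attr(df, "model_name") <- model
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
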