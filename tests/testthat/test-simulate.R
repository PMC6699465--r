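test_that("zero-length branches copy the root sequence to every leaf", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln <- simulate_alignment(tr, uniform_model(), 200, seed = 3)
  expect_identical(aln["A", ], aln["B", ])
  expect_identical(aln["A", ], aln["C", ])
})

test_that("simulation is deterministic given a seed", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  a1 <- simulate_alignment(tr, "Dayhoff", 500, seed = 42)
  a2 <- simulate_alignment(tr, "Dayhoff", 500, seed = 42)
  expect_identical(unclass(a1), unclass(a2))
  a3 <- simulate_alignment(tr, "Dayhoff", 500, seed = 43)
  expect_false(identical(unclass(a1), unclass(a3)))
  expect_error(simulate_alignment(ape::read.tree(text = "(A:-1,B:1);"),
                                  "Dayhoff", 10), "Negative")
})

test_that("observed divergence matches the analytic curve (two-taxon check)", {
  rm <- rate_matrix("Dayhoff")
  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")   # total path d = 0.5
  n <- 50000
  aln <- simulate_alignment(tr, rm, n, seed = 7)
  p_obs <- mean(aln[1, ] != aln[2, ])
  p_exp <- expected_p(rm, 0.5)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("deep-branch leaf composition converges to the equilibrium frequencies", {
  rm <- rate_matrix("LG")
  tr <- ape::read.tree(text = "(A:50,B:50);")
  n <- 50000
  aln <- simulate_alignment(tr, rm, n, seed = 11)
  freq <- table(factor(aln[1, ], levels = protgamma:::AA_ORDER)) / n
  tol <- 4 * sqrt(rm$pi * (1 - rm$pi) / n)
  expect_true(all(abs(as.numeric(freq) - rm$pi) < tol))
})

test_that("patristic distances sum branch lengths along paths", {
  pm <- patristic_matrix(toy_tree())
  expect_equal(pm["A", "B"], 3)
  expect_equal(pm["A", "C"], 4.5)
  expect_equal(pm["B", "C"], 5.5)
  expect_equal(unname(diag(pm)), rep(0, 3))
  # cherry with zero branch lengths
  expect_equal(max(patristic_matrix(ape::read.tree(text = "(A:0,B:0);"))), 0)
})

test_that("patristic matrices satisfy the four-point condition", {
  trees <- generate_tree_collection(5, taxa_range = c(6, 10),
                                    diameter_range = c(0.5, 5), seed = 5)
  for (tr in trees) {
    pm <- patristic_matrix(tr)
    lab <- sample(rownames(pm), 4)
    s1 <- pm[lab[1], lab[2]] + pm[lab[3], lab[4]]
    s2 <- pm[lab[1], lab[3]] + pm[lab[2], lab[4]]
    s3 <- pm[lab[1], lab[4]] + pm[lab[2], lab[3]]
    ss <- sort(c(s1, s2, s3))
    expect_lt(ss[3] - ss[2], 1e-9)    # two largest sums equal
  }
})

test_that("tree_diameter is the maximum patristic distance and scales linearly", {
  tr <- toy_tree()
  expect_equal(tree_diameter(tr), 5.5)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 3
  expect_equal(tree_diameter(tr2), 3 * tree_diameter(tr))
})

test_that("diameter-grid tree selection picks nearest trees with first-wins ties", {
  mk <- function(d, n = 25) {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length * (d / tree_diameter(tr))
    tr
  }
  set.seed(2)
  trees <- list(mk(1), mk(5), mk(10))
  sel <- select_trees_by_diameter(trees, start = 1, stop = 5, step = 4,
                                  min_taxa = 25)
  expect_equal(sel$index, c(1L, 2L))
  # tie: diameters 2 and 4 exactly equidistant from m = 3 -> earlier wins
  trees2 <- list(ape::read.tree(text = "(A:1,B:1);"),
                 ape::read.tree(text = "(A:2,B:2);"))
  sel2 <- select_trees_by_diameter(trees2, start = 3, stop = 3, step = 1,
                                   min_taxa = 2)
  expect_equal(sel2$index, 1L)
  # min_taxa filter can empty the collection
  small <- list(mk(1, n = 5))
  expect_error(select_trees_by_diameter(small), "at least 25")
  # dedup keeps first occurrences only
  sel3 <- select_trees_by_diameter(trees, start = 1, stop = 1.2, step = 0.1,
                                   dedup = TRUE)
  expect_equal(nrow(sel3), 1L)
})

test_that("the default selection grid makes exactly 20,000 picks", {
  set.seed(8)
  trees <- lapply(exp(seq(log(0.001), log(25), length.out = 40)), function(d) {
    tr <- ape::rtree(25)
    tr$edge.length <- tr$edge.length * (d / tree_diameter(tr))
    tr
  })
  sel <- select_trees_by_diameter(trees)
  expect_equal(nrow(sel), 20000L)
  expect_equal(sel$m[1], 0.0001)
  expect_equal(sel$m[20000], 19.9991, tolerance = 1e-9)
})

test_that("integer scaling rounds half away from zero and bounds the error", {
  ic <- to_integer_counts(0.123456, 0.2, 50000)
  expect_equal(ic$p_count, 6173L)
  expect_equal(ic$d_count, 10000L)
  expect_equal(to_integer_counts(0, 0, 1000)[1, 1:2],
               data.frame(p_count = 0L, d_count = 0L)[1, ])
  # rounding bound |p_count/n - p| <= 1/(2n) on random draws
  set.seed(1)
  p <- runif(200)
  ic2 <- to_integer_counts(p, p, 5000)
  expect_true(all(abs(ic2$p_count / 5000 - p) <= 1 / (2 * 5000) + 1e-12))
  # half-integer cases round away from zero
  expect_equal(to_integer_counts(0.5, 1.5, 1)$p_count, 1L)
  expect_equal(to_integer_counts(0.5, 1.5, 1)$d_count, 2L)
})

test_that("synthetic tree collections honor their contract deterministically", {
  trees <- generate_tree_collection(20, taxa_range = c(25, 30),
                                    diameter_range = c(0.1, 20), seed = 9)
  expect_length(trees, 20)
  ntax <- vapply(trees, function(t) length(t$tip.label), integer(1))
  expect_true(all(ntax >= 25 & ntax <= 30))
  dia <- vapply(trees, tree_diameter, numeric(1))
  expect_true(all(dia >= 0.1 - 1e-9 & dia <= 20 + 1e-9))
  trees2 <- generate_tree_collection(20, taxa_range = c(25, 30),
                                     diameter_range = c(0.1, 20), seed = 9)
  expect_identical(ape::write.tree(trees), ape::write.tree(trees2))
})

test_that("patristic distances round-trip through Newick text", {
  trees <- generate_tree_collection(3, taxa_range = c(5, 8),
                                    diameter_range = c(1, 4), seed = 13)
  for (tr in trees) {
    txt <- ape::write.tree(tr)
    tr2 <- ape::read.tree(text = txt)
    pm1 <- patristic_matrix(tr)
    pm2 <- patristic_matrix(tr2)
    expect_lt(max(abs(pm1 - pm2[rownames(pm1), colnames(pm1)])), 1e-9)
  }
})

test_that("(p, d) block files round-trip with their seed header", {
  s <- simulate_pd_samples("Dayhoff", n_trees = 2, n_sites = 300, seed = 21,
                           taxa_range = c(5, 6), max_pairs_per_tree = 10)
  expect_true(all(s$p_count >= 0 & s$p_count <= 300))
  expect_true(all(s$d_count >= 0))
  f <- tempfile(fileext = ".tsv")
  write_pd_blocks(s, f)
  s2 <- read_pd_blocks(f)
  expect_equal(s2$p_count, s$p_count)
  expect_equal(s2$d_count, s$d_count)
  expect_equal(attr(s2, "seed"), 21)
  expect_equal(attr(s2, "model_name"), "Dayhoff")
})
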