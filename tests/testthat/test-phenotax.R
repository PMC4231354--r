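# Jaccard similarity over binary phenotype panels and UPGMA dendrograms.

panel <- function(id, ...) phenotype_panel(id, c(...))

test_that("Jaccard ignores joint negatives and untested entries", {
  a <- panel("a", t1 = TRUE, t2 = TRUE, t3 = FALSE)
  b <- panel("b", t1 = TRUE, t2 = FALSE, t3 = FALSE)
  expect_equal(jaccard_similarity(a, b), 0.5)

  # identical all-positive panels
  p <- panel("p", t1 = TRUE, t2 = TRUE)
  q <- panel("q", t1 = TRUE, t2 = TRUE)
  expect_equal(jaccard_similarity(p, q), 1)

  # disjoint positive sets
  x <- panel("x", t1 = TRUE, t2 = FALSE)
  y <- panel("y", t1 = FALSE, t2 = TRUE)
  expect_equal(jaccard_similarity(x, y), 0)

  # joint negatives change nothing
  a2 <- panel("a2", t1 = TRUE, t2 = TRUE, t3 = FALSE, t4 = FALSE, t5 = FALSE)
  b2 <- panel("b2", t1 = TRUE, t2 = FALSE, t3 = FALSE, t4 = FALSE, t5 = FALSE)
  expect_equal(jaccard_similarity(a2, b2), 0.5)

  # untested entries are excluded pairwise
  a3 <- panel("a3", t1 = TRUE, t2 = NA, t3 = TRUE)
  b3 <- panel("b3", t1 = TRUE, t2 = TRUE, t3 = FALSE)
  expect_equal(jaccard_similarity(a3, b3), 0.5)

  # similarity 1 iff the positive sets are equal and non-empty
  expect_equal(jaccard_similarity(panel("m", t1 = TRUE, t2 = FALSE),
                                  panel("n", t1 = TRUE, t2 = FALSE)), 1)
  expect_lt(jaccard_similarity(panel("m", t1 = TRUE, t2 = TRUE),
                               panel("n", t1 = TRUE, t2 = FALSE)), 1)

  # no comparable informative tests -> undefined
  expect_error(jaccard_similarity(panel("u", t1 = NA, t2 = FALSE),
                                  panel("v", t1 = TRUE, t2 = FALSE)),
               class = "undefined_similarity")
  # symmetry
  expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
})

test_that("Jaccard matches vegan on complete binary panels", {
  skip_if_not_installed("vegan")
  set.seed(23)
  mat <- matrix(stats::runif(5 * 12) < 0.5, 5, 12,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:12)))
  panels <- lapply(rownames(mat), function(id) phenotype_panel(id, mat[id, ]))
  mine <- jaccard_matrix(panels)
  ref <- 1 - as.matrix(vegan::vegdist(mat, method = "jaccard", binary = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("UPGMA reproduces the three-strain hand computation", {
  d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d, is_distance = TRUE)
  merges <- attr(tr, "merges")
  expect_equal(merges$height, c(0.05, 0.25))
  expect_identical(sort(c(merges$left[1], merges$right[1])), c("A", "B"))
  # ((A,B),C): A and B coalesce below C's junction
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 0.1)
  expect_equal(cp["A", "C"], 0.5)
})

test_that("UPGMA output is ultrametric with non-decreasing merge heights", {
  set.seed(24)
  for (i in 1:5) {
    d <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
    d[upper.tri(d)] <- stats::runif(15, 0.05, 1)
    d <- d + t(d)
    tr <- upgma_tree(d, is_distance = TRUE)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_false(is.unsorted(attr(tr, "merges")$height))
    # agreement with the naive average-linkage oracle
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)],
                 naive_upgma_cophenetic(d), tolerance = 1e-10)
    # and with hclust's UPGMA
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(as.matrix(stats::cophenetic(hc))[rownames(d), colnames(d)],
                 ape::cophenetic.phylo(tr)[rownames(d), colnames(d)],
                 tolerance = 1e-10)
  }
})

test_that("identical strains collapse into a zero-height clade", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d, is_distance = TRUE)
  expect_true(all(attr(tr, "merges")$height == 0))
  expect_true(all(tr$edge.length == 0))
})

test_that("phenotype CSV parsing accepts +/-/NT and rejects junk", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("strain_id,t1,t2,t3", "s1,+,-,NT", "s2,+,+,-"), path)
  panels <- read_phenotype_csv(path)
  expect_identical(panels[[1]]$tests, c(t1 = TRUE, t2 = FALSE, t3 = NA))
  writeLines(c("strain_id,t1", "s1,maybe"), path)
  expect_error(read_phenotype_csv(path), class = "invalid_input")
  unlink(path)
})

test_that("planted phenotype clusters come out as clades", {
  panels <- simulate_phenotype_panels(c(crud = 4, mong = 4), flip_prob = 0.03,
                                      seed = 25)
  tr <- upgma_tree(jaccard_matrix(panels))
  truth <- attr(panels, "truth")
  for (cl in unique(truth))
    expect_true(ape::is.monophyletic(tr, names(truth)[truth == cl]))
})
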