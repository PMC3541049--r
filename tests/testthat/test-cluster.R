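mk_comm <- function(m, ids = paste0("S", seq_len(nrow(m)))) {
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}

test_that("Bray-Curtis reproduces hand-computed values and edge cases", {
  m <- mk_comm(rbind(c(1, 3), c(3, 1)))
  expect_equal(as.numeric(bray_curtis(m)), 0.5)

  same <- mk_comm(rbind(c(2, 5), c(2, 5)))
  expect_equal(as.numeric(bray_curtis(same)), 0)

  disjoint <- mk_comm(rbind(c(1, 0), c(0, 4)))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  zero_pair <- mk_comm(rbind(c(0, 0), c(0, 0), c(1, 1)))
  d <- as.matrix(bray_curtis(zero_pair))
  expect_equal(d["S1", "S2"], 0)

  expect_error(bray_curtis(mk_comm(rbind(c(-1, 2), c(1, 1)))), "non-negative")
})

test_that("Bray-Curtis output is bounded, symmetric and zero on the diagonal", {
  withr::with_seed(5, {
    for (i in 1:10) {
      m <- matrix(rexp(8 * 5), nrow = 8)
      d <- as.matrix(bray_curtis(mk_comm(m)))
      expect_true(all(d >= 0 & d <= 1))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
    }
  })
})

test_that("UPGMA reproduces hand-traceable merges", {
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.4)

  d3 <- stats::as.dist(matrix(c(0, 0.2, 0.6,
                                0.2, 0, 0.6,
                                0.6, 0.6, 0), 3,
                              dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C"))))
  t3 <- upgma(d3)
  expect_equal(sort(t3$height), c(0.2, 0.6))

  expect_error(upgma(stats::as.dist(matrix(0, 1, 1))), "at least two")
})

test_that("UPGMA and its cophenetic matrix agree with the brute-force oracle", {
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(3:8, 1)
      D <- matrix(0, n, n)
      D[upper.tri(D)] <- runif(n * (n - 1) / 2)
      D <- D + t(D)
      labs <- paste0("L", seq_len(n))
      dimnames(D) <- list(labs, labs)
      tree <- upgma(stats::as.dist(D))
      got <- as.matrix(stats::cophenetic(tree))[labs, labs]
      want <- oracle_upgma_cophenetic(D)
      dimnames(want) <- dimnames(got)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("merge heights are monotone along every path to the root", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 7
      D <- matrix(0, n, n)
      D[upper.tri(D)] <- runif(n * (n - 1) / 2)
      D <- D + t(D)
      dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
      tree <- upgma(stats::as.dist(D))
      expect_true(all(diff(tree$height) >= -1e-12))
    }
  })
})

test_that("cophenetic correlation is exactly one for ultrametric input", {
  d3 <- stats::as.dist(matrix(c(0, 0.2, 0.6,
                                0.2, 0, 0.6,
                                0.6, 0.6, 0), 3,
                              dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C"))))
  tree <- upgma(d3)
  expect_equal(cophenetic_correlation(d3, tree), 1)

  # a tree's own cophenetic matrix correlates perfectly with itself
  dc <- stats::cophenetic(tree)
  expect_equal(cophenetic_correlation(dc, upgma(dc)), 1)

  expect_error(
    cophenetic_correlation(stats::as.dist(matrix(c(0, 1, 1, 0), 2)), tree),
    "three")
})

test_that("cophenetic correlation degrades as ultrametricity is perturbed", {
  base <- matrix(c(0, 0.2, 0.6, 0.7,
                   0.2, 0, 0.6, 0.7,
                   0.6, 0.6, 0, 0.7,
                   0.7, 0.7, 0.7, 0), 4,
                 dimnames = list(paste0("L", 1:4), paste0("L", 1:4)))
  perturb <- function(eps) {
    m <- base
    m[1, 3] <- m[1, 3] + eps
    m[3, 1] <- m[1, 3]
    d <- stats::as.dist(m)
    cophenetic_correlation(d, upgma(d))
  }
  c0 <- perturb(0); c1 <- perturb(0.05); c2 <- perturb(0.15)
  expect_equal(c0, 1)
  expect_true(c1 < 1)
  expect_true(c2 < c1)
})

test_that("cutting the dendrogram partitions by height", {
  d3 <- stats::as.dist(matrix(c(0, 0.2, 0.6,
                                0.2, 0, 0.6,
                                0.6, 0.6, 0), 3,
                              dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C"))))
  tree <- upgma(d3)
  below <- cut_dendrogram(tree, 0.1)
  expect_equal(dplyr::n_distinct(below$cluster), 3)
  mid <- cut_dendrogram(tree, 0.3)
  expect_equal(dplyr::n_distinct(mid$cluster), 2)
  expect_equal(mid$cluster[mid$sample_id == "A"],
               mid$cluster[mid$sample_id == "B"])
  top <- cut_dendrogram(tree, 0.6)
  expect_equal(dplyr::n_distinct(top$cluster), 1)
})

test_that("Kruskal-Wallis matches the rank-formula oracle, ties included", {
  sym <- tibble::tibble(y = c(1, 2, 1, 2), g = c("a", "a", "b", "b"))
  expect_equal(kruskal_wallis(sym, y, g)$statistic, 0)

  hand <- tibble::tibble(y = 1:6, g = rep(c("a", "b"), each = 3))
  res <- kruskal_wallis(hand, y, g)
  expect_equal(res$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0495, tolerance = 1e-3)
  expect_equal(res$statistic, oracle_kruskal_h(hand$y, hand$g))

  tied <- tibble::tibble(y = c(1, 2, 2, 2, 3, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(tied, y, g)$statistic,
               oracle_kruskal_h(tied$y, tied$g), tolerance = 1e-9)

  flat <- tibble::tibble(y = rep(c(5, 6), 3), g = rep(c("a", "b", "c"), each = 2))
  expect_equal(kruskal_wallis(flat, y, g)$statistic, 0)

  expect_error(kruskal_wallis(tibble::tibble(y = 1:3, g = "a"), y, g),
               "two groups")
})

test_that("tidy, glance and Newick export describe the tree consistently", {
  withr::with_seed(2, {
    m <- matrix(rexp(6 * 4), nrow = 6,
                dimnames = list(paste0("S", 1:6), NULL))
  })
  d <- bray_curtis(mk_comm(m, rownames(m)))
  tree <- upgma(d)
  td <- tidy(tree)
  expect_equal(nrow(td), 5)
  expect_true(all(diff(td$height) >= -1e-12))
  gl <- glance(tree)
  expect_equal(gl$n_samples, 6)
  expect_equal(gl$max_height, max(tree$height))
  expect_true(gl$cophenetic_correlation <= 1)

  nwk <- tempfile(fileext = ".nwk")
  export_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, paste0("S", 1:6))
})
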