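test_that("Pearson chi-squared test matches hand computations", {
  flat <- matrix(10, 2, 2)
  res <- pearson_chi_squared(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, 1)

  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- pearson_chi_squared(diag2)  # E = 5 everywhere: 4 * 25/5 = 20
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)

  set.seed(2)
  t54 <- matrix(rpois(20, 30) + 1, 5, 4)
  expect_equal(pearson_chi_squared(t54)$df, 12L)

  degenerate <- matrix(c(1, 0, 2, 0), 2, 2)
  expect_error(pearson_chi_squared(degenerate), "degenerate")
})

test_that("chi-squared type-I error is calibrated under a simulated null", {
  set.seed(17)
  pr <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  pc <- c(0.3, 0.3, 0.2, 0.2)
  pv <- replicate(500, {
    tab <- matrix(rmultinom(1, 2000, outer(pr, pc)), 5, 4)
    pearson_chi_squared(tab)$p_value
  })
  expect_lt(abs(mean(pv <= 0.05) - 0.05), 0.03)
})

test_that("Bray-Curtis similarity follows its closed form", {
  expect_equal(bray_curtis_similarity(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(bray_curtis_similarity(c(5, 0), c(0, 3)), 0)
  expect_equal(bray_curtis_similarity(c(1, 2), c(2, 2)), 1 - 1 / 7)
  # symmetry and invariance to joint coordinate permutation
  u <- c(4, 1, 7, 0); v <- c(2, 2, 3, 5)
  expect_equal(bray_curtis_similarity(u, v), bray_curtis_similarity(v, u))
  o <- c(3, 1, 4, 2)
  expect_equal(bray_curtis_similarity(u[o], v[o]),
               bray_curtis_similarity(u, v))
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis_similarity(1:3, 1:4), "equal length")
})

test_that("Mantel test is exact on small designs and matches enumeration", {
  set.seed(12)
  xy <- matrix(rnorm(8), 4, 2)
  D1 <- as.matrix(dist(xy))
  dimnames(D1) <- list(paste0("s", 1:4), paste0("s", 1:4))

  # identical matrices: r = 1, p at the enumeration minimum
  res <- mantel_test(D1, D1, n_perm = 999)
  expect_equal(res$statistic, 1)
  expect_true(res$exact)
  expect_equal(res$p_value, oracle_mantel_exact_p(D1, D1))

  D2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(D2) <- dimnames(D1)
  res <- mantel_test(D1, D2, n_perm = 999)
  expect_equal(res$p_value, oracle_mantel_exact_p(D1, D2))

  # statistic agrees with the vegan implementation
  expect_equal(res$statistic,
               unname(vegan::mantel(D1, D2, permutations = 9)$statistic))

  D3 <- D2
  rownames(D3) <- colnames(D3) <- paste0("t", 1:4)
  expect_error(mantel_test(D1, D3), "mismatching site labels")
  expect_error(mantel_test(matrix(0, 4, 4), D1), "constant")
})

test_that("Monte-Carlo Mantel p is reproducible and roughly uniform under the null", {
  set.seed(13)
  mk <- function() {
    d <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
    d
  }
  a <- mantel_test(mk(), mk(), n_perm = 199, seed = 99)
  expect_false(a$exact)
  expect_gte(a$p_value, 1 / 200)
  expect_lte(a$p_value, 1)
  Dx <- mk(); Dy <- mk()
  expect_identical(mantel_test(Dx, Dy, n_perm = 199, seed = 5)$p_value,
                   mantel_test(Dx, Dy, n_perm = 199, seed = 5)$p_value)

  set.seed(14)
  pv <- replicate(500, {
    r <- mantel_test(mk(), mk(), n_perm = 99)
    r$p_value
  })
  expect_equal(mean(pv), 0.5, tolerance = 0.06)
  expect_gt(mean(pv <= 0.25), 0.15)
  expect_gt(mean(pv >= 0.75), 0.15)
})

test_that("context comparison handles constant, separated and degenerate data", {
  vals <- rep(2.5, 12)
  ctx <- rep(landscape_contexts(), each = 3)
  res <- permutation_context_compare(vals, ctx, n_perm = 199, seed = 1)
  expect_true(all(res$p_value == 1))
  expect_equal(nrow(res), choose(4, 2))

  # non-overlapping 3+3: exact enumeration over C(6,3)=20 relabellings,
  # two-sided minimum p = 2/20
  vals <- c(10, 11, 12, 100, 101, 102)
  ctx <- rep(c("urban", "semi-natural"), each = 3)
  res <- permutation_context_compare(vals, ctx, n_perm = 999, seed = 1)
  expect_equal(res$n_perm, 20)
  expect_equal(res$p_value, 2 / 20)
  expect_match(res$method, "exact")

  expect_error(permutation_context_compare(c(1, 2, 3), c("a", "a", "b")),
               "insufficient replication")
  expect_error(permutation_context_compare(c(1, 2, 3, 4),
                                           rep("urban", 4)),
               "at least two")
})

test_that("context comparison detects a built-in synthetic effect", {
  # semi-natural vs urban per-web totals differ strongly under the default
  # presets; the exact relabelling p should be small for a single study
  study <- generate_study(default_presets(seed = 2024))
  webs <- build_all_networks(study$records, study$sites)
  ns <- do.call(rbind, lapply(webs, network_summary))
  sel <- ns$landscape_context %in% c("semi-natural", "urban")
  res <- permutation_context_compare(ns$total_interactions[sel],
                                     ns$landscape_context[sel],
                                     n_perm = 999, seed = 3)
  expect_lt(res$p_value, 0.05)
})
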