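test_that("contingency tables tally aligned ratings exhaustively", {
  a <- rand_ratings(52, seed = 1, source = "A", prob = c(13, 13, 26) / 52)
  tab <- contingency(a, a)
  expect_equal(sum(diag(tab)), 52)
  expect_equal(sum(tab) - sum(diag(tab)), 0)
  # random vectors vs a brute-force pairwise tally
  b <- rand_ratings(52, seed = 2, source = "B")
  tab <- contingency(a, b)
  cats <- change_categories()
  for (i in 1:3) for (j in 1:3) {
    expect_equal(tab[i, j],
                 sum(a$category == cats[i] & b$category == cats[j]))
  }
  # disjoint ids are an error
  b2 <- b; b2$lesion_id <- paste0("x", b2$lesion_id)
  expect_error(contingency(a, b2), "unmatched ids")
})

test_that("kappa from a table follows the p0/pe formula and matches an independent implementation", {
  # perfect agreement
  perfect <- diag(c(13, 13, 26))
  expect_equal(kappa_from_table(perfect)$kappa, 1.0)
  # unanimity in one category is degenerate
  degen <- matrix(0, 2, 2); degen[1, 1] <- 10
  expect_error(kappa_from_table(degen), "degenerate")
  # random tables vs e1071's implementation
  skip_if_not_installed("e1071")
  set.seed(5)
  for (rep in 1:25) {
    tab <- matrix(rpois(9, 6), 3, 3)
    if (sum(tab) == 0) next
    k <- kappa_from_table(tab)
    expect_equal(k$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    expect_equal(k$kappa, (k$p0 - k$pe) / (1 - k$pe), tolerance = 1e-12)
  }
})

test_that("kappa from marginals reproduces the aggregated published values", {
  # visual planar vs quantitative, both readers pooled (n = 104)
  k1 <- kappa_from_marginals(c(35, 33, 36), c(25, 28, 51),
                             n_agree = 104 - (18 + 22), n = 104)
  expect_equal(round(k1$kappa, 2), 0.42)
  expect_equal(k1$label, "moderate")
  # visual SPECT/CT vs quantitative (n = 104)
  k2 <- kappa_from_marginals(c(29, 28, 47), c(25, 28, 51),
                             n_agree = 104 - (11 + 14), n = 104)
  expect_equal(round(k2$kappa, 2), 0.62)
  expect_equal(k2$label, "substantial")
  # full agreement with equal marginals
  k3 <- kappa_from_marginals(c(10, 5, 5), c(10, 5, 5), n_agree = 20)
  expect_equal(k3$kappa, 1.0)
  # inconsistent sums
  expect_error(kappa_from_marginals(c(1, 2, 3), c(2, 2, 3), n_agree = 4),
               "sum to n")
})

test_that("marginal and table paths give identical kappa for any table", {
  set.seed(77)
  for (rep in 1:200) {
    tab <- matrix(rpois(9, 4), 3, 3)
    if (sum(tab) == 0 || sum(rowSums(tab) / sum(tab) * colSums(tab) / sum(tab)) >= 1 - 1e-12)
      next
    kt <- kappa_from_table(tab)
    km <- kappa_from_marginals(rowSums(tab), colSums(tab),
                               n_agree = sum(diag(tab)), n = sum(tab))
    expect_identical(kt$kappa, km$kappa)
    expect_identical(kt$pe, km$pe)
  }
})

test_that("kappa is symmetric, capped by p0, and 1 only at perfect agreement", {
  set.seed(31)
  for (rep in 1:30) {
    a <- rand_ratings(40, seed = 300 + rep, source = "A")
    b <- rand_ratings(40, seed = 600 + rep, source = "B", prob = c(2, 1, 1) / 4)
    kab <- kappa_from_table(contingency(a, b))
    kba <- kappa_from_table(contingency(b, a))
    expect_equal(kab$kappa, kba$kappa, tolerance = 1e-12)
    expect_lte(kab$kappa, kab$p0 + 1e-12)
    if (kab$p0 < 1) expect_lt(kab$kappa, 1)
  }
})

test_that("Landis-Koch labels follow the published strata with inclusive upper bounds", {
  expect_equal(interpret_kappa(0.94), "almost perfect")
  expect_equal(interpret_kappa(0.42), "moderate")
  expect_equal(interpret_kappa(0.20), "slight")
  expect_equal(interpret_kappa(c(-0.1, 0, 0.2, 0.21, 0.4, 0.41, 0.6, 0.61, 0.8, 0.81, 1)),
               c("poor", "slight", "slight", "fair", "fair", "moderate",
                 "moderate", "substantial", "substantial", "almost perfect",
                 "almost perfect"))
  expect_error(interpret_kappa(1.2), "exceed 1")
})

test_that("discrepancy counts and fractions match direct comparison", {
  a <- rand_ratings(52, seed = 9, source = "A")
  expect_equal(discrepancy_count(a, a), list(n_discrepant = 0L, fraction = 0, n = 52L))
  # 11 of 52 discrepant -> 21.1% at one decimal
  b <- a
  flip <- function(x) c(progressive = "stable", stable = "regressive",
                        regressive = "progressive")[as.character(x)]
  b$category[1:11] <- factor(flip(b$category[1:11]), change_categories())
  d <- discrepancy_count(a, b)
  expect_equal(d$n_discrepant, 11L)
  expect_equal(format_percent(d$fraction), 21.1)
  # brute-force check on random pairs
  x <- rand_ratings(37, seed = 10); y <- rand_ratings(37, seed = 11)
  expect_equal(discrepancy_count(x, y)$n_discrepant,
               sum(as.character(x$category) != as.character(y$category)))
})

test_that("Mann-Whitney U matches symmetry, separation, and reference implementations", {
  x <- c(1, 2, 5, 9); y <- c(9, 5, 2, 1)
  expect_equal(mann_whitney_u(x, y)$U, length(x) * length(y) / 2)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  # tie-free small samples against stats::wilcox.test exact p and W
  set.seed(14)
  for (rep in 1:10) {
    x <- round(rnorm(6), 4); y <- round(rnorm(7, 0.5), 4)
    res <- mann_whitney_u(x, y)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$U, unname(wt$statistic))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  }
  # large samples: normal approximation with tie correction
  set.seed(15)
  x <- sample(1:8, 40, replace = TRUE); y <- sample(2:9, 45, replace = TRUE)
  res <- mann_whitney_u(x, y)
  expect_equal(res$method, "normal approximation with tie correction")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res$U, unname(wt$statistic))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
})

test_that("Spearman correlation handles monotone, reversed, and random data", {
  x <- c(3, 8, 1, 5, 9, 2)
  expect_equal(spearman_rho(x, x)$rho, 1.0)
  expect_equal(spearman_rho(x, -x)$rho, -1.0)
  set.seed(16)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    res <- spearman_rho(x, y)
    expect_equal(res$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("independent raters give kappa near zero on large samples", {
  uniform <- reader_model(matrix(1 / 3, 3, 3), seed = 101L)
  uniform2 <- reader_model(matrix(1 / 3, 3, 3), seed = 202L)
  truth <- rep(change_categories(), length.out = 10000)
  r1 <- simulate_reader(truth, uniform)
  r2 <- simulate_reader(truth, uniform2)
  k <- kappa_from_table(contingency(r1, r2))
  expect_lt(abs(k$kappa), 0.03)
})
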