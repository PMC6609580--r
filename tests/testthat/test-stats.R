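test_that("kruskal_wallis matches hand arithmetic and handles degeneracy", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p, 0.04953461, tolerance = 1e-6)

  same <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_lt(same$H, 0.5)
  expect_gt(same$p, 0.4)

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("kruskal_wallis agrees with stats::kruskal.test on random fixtures", {
  set.seed(401)
  for (i in 1:60) {
    g <- lapply(seq_len(sample(2:4, 1)),
                function(j) sample(1:8, sample(3:10, 1), replace = TRUE))
    ref <- suppressWarnings(stats::kruskal.test(g))
    kw <- kruskal_wallis(g)
    if (is.nan(ref$statistic)) next
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bh_fdr performs the step-up adjustment and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(402)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("sign_test is the exact two-sided binomial tail doubling", {
  expect_equal(sign_test(rep(1, 8)), 0.0078125)
  expect_equal(sign_test(c(rep(1, 7), -1)), 0.0703125)
  expect_equal(sign_test(c(rep(1, 4), rep(-1, 4))), 1)
  expect_equal(sign_test(rep(0, 5)), 1)      # zeros dropped, nothing left
  expect_equal(sign_test(c(0, 0, 1, 1)), 0.5)
  expect_error(sign_test(numeric(0)), "nonempty")
})

test_that("mutual_information is the plug-in estimate in bits", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
  set.seed(403)
  for (i in 1:40) {
    x <- sample(-1:1, 20, replace = TRUE)
    y <- sample(0:1, 20, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mi_oracle(x, y),
                 tolerance = 1e-10)
    expect_gte(mutual_information(x, y), 0)
  }
})

test_that("ternary_discretize cuts at mean +/- sd/2 with strict inequalities", {
  expect_equal(ternary_discretize(c(0, 0, 10, 10)), c(-1L, -1L, 1L, 1L))
  expect_equal(ternary_discretize(c(3, 3, 3)), c(0L, 0L, 0L))
  # a value exactly at mean + sd/2 stays in the middle bin
  v <- c(0, 2)  # mean 1, sd sqrt(2); boundary = 1 + sqrt(2)/2
  boundary <- 1 + sqrt(2) / 2
  expect_equal(ternary_discretize(c(v, boundary))[3], 0L)
  expect_error(ternary_discretize(1), ">= 2")
})

test_that("hypergeom_upper is the exact upper tail", {
  expect_equal(hypergeom_upper(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper(10, 5, 5, 0), 1)
  expect_error(hypergeom_upper(10, 11, 5, 2), "inconsistent")
  expect_error(hypergeom_upper(10, 5, 5, 6), "inconsistent")
  set.seed(404)
  for (i in 1:40) {
    N <- sample(10:80, 1); M <- sample(1:N, 1); n <- sample(1:N, 1)
    ks <- 0:min(M, n)
    # normalization: point masses sum to one
    pmf <- vapply(ks, function(k) {
      upper <- hypergeom_upper(N, M, n, k)
      nxt <- if (k < min(M, n)) hypergeom_upper(N, M, n, k + 1) else 0
      upper - nxt
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    # monotone decreasing in k
    tails <- vapply(ks, function(k) hypergeom_upper(N, M, n, k), numeric(1))
    expect_true(all(diff(tails) <= 1e-12))
    # reference implementation
    k <- sample(ks, 1)
    expect_equal(hypergeom_upper(N, M, n, k),
                 stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("ks_statistic is the ECDF sup-difference", {
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  expect_equal(ks_statistic(1:3, 4:6), 1)
  expect_equal(ks_statistic(c(2, 5, 9), c(2, 5, 9)), 0)
  expect_error(ks_statistic(numeric(0), 1:3), "nonempty")
  set.seed(405)
  for (i in 1:60) {
    a <- sample(1:10, sample(2:12, 1), replace = TRUE)  # ties included
    b <- runif(sample(2:12, 1), 0, 10)
    expect_equal(ks_statistic(a, b), ks_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("balanced_error averages the two error rates", {
  expect_equal(balanced_error(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0)
  # FNR 0.5 (1 of 2 positives missed), FPR 0.1 (1 of 10 negatives hit)
  truth <- c(rep(1, 2), rep(0, 10))
  pred <- c(1, 0, 1, rep(0, 9))
  expect_equal(balanced_error(pred, truth), 0.3)
  expect_equal(balanced_error(rep(1, 4), c(0, 0, 1, 1)), 0.5)
  expect_error(balanced_error(c(1, 0), c(1, 1)), "both classes")
})
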