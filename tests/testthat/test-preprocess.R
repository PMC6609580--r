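test_that("zscore_by_normal standardizes by normal statistics", {
  nm <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f1"))
  tm <- matrix(2, 1, 1, dimnames = list(NULL, "f1"))
  z <- zscore_by_normal(tm, nm)
  expect_equal(unname(z$tumor[1, 1]), 0)

  nm2 <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "f1"))
  tm2 <- matrix(4, 1, 1, dimnames = list(NULL, "f1"))
  expect_equal(unname(zscore_by_normal(tm2, nm2)$tumor[1, 1]), 2.1213,
               tolerance = 1e-4)

  # constant feature dropped with a warning
  nm3 <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  tm3 <- cbind(f1 = c(0, 1), f2 = c(4, 6))
  expect_warning(z3 <- zscore_by_normal(tm3, nm3), "zero-variance")
  expect_identical(colnames(z3$normal), "f1")

  # output normal matrix is exactly standardized
  set.seed(601)
  nm4 <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  z4 <- zscore_by_normal(nm4, nm4)
  expect_lt(max(abs(colMeans(z4$normal))), 1e-10)
  expect_lt(max(abs(apply(z4$normal, 2, sd) - 1)), 1e-10)
})

test_that("svd_detrend removes exactly the top normal components", {
  set.seed(602)
  # rank-3 normal matrix is annihilated by 3-component removal
  a <- matrix(rnorm(18), 6, 3); b <- matrix(rnorm(24), 3, 8)
  nm <- a %*% b
  colnames(nm) <- paste0("f", 1:8)
  tm <- matrix(rnorm(16), 2, 8, dimnames = list(NULL, paste0("f", 1:8)))
  r <- svd_detrend(tm, nm, 3)
  expect_lt(norm(r$normal, "F"), 1e-8)
  # components orthonormal
  expect_equal(crossprod(r$components), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residual uncorrelated with removed directions
  expect_lt(max(abs(r$normal %*% r$components)), 1e-8)

  # identity at zero components
  r0 <- svd_detrend(tm, nm, 0)
  expect_identical(r0$tumor, tm)
  expect_error(svd_detrend(tm, nm, 6), "min\\(dim")
})

test_that("svd_detrend matches an eigendecomposition oracle", {
  set.seed(603)
  nm <- scale(matrix(rnorm(20), 5, 4))[, ]  # 5 x 4 z-scored
  colnames(nm) <- paste0("f", 1:4)
  tm <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("f", 1:4)))
  r <- svd_detrend(tm, nm, 3)
  ev <- eigen(crossprod(nm), symmetric = TRUE)
  v <- ev$vectors[, 1:3]
  expect_equal(r$normal, nm - (nm %*% v) %*% t(v), tolerance = 1e-8)
  expect_equal(r$tumor, tm - (tm %*% v) %*% t(v), tolerance = 1e-8)
})

test_that("svd_detrend is invariant under feature permutation round trips", {
  set.seed(604)
  nm <- matrix(rnorm(80), 10, 8, dimnames = list(NULL, paste0("f", 1:8)))
  tm <- matrix(rnorm(24), 3, 8, dimnames = list(NULL, paste0("f", 1:8)))
  r <- svd_detrend(tm, nm, 2)
  perm <- sample(8)
  rp <- svd_detrend(tm[, perm], nm[, perm], 2)
  expect_equal(rp$normal[, colnames(nm)], r$normal, tolerance = 1e-8)
})

test_that("normalize_dnam composes its three steps and records state", {
  set.seed(605)
  nm <- matrix(runif(120), 12, 10, dimnames = list(NULL, paste0("f", 1:10)))
  tm <- matrix(runif(60), 6, 10, dimnames = list(NULL, paste0("f", 1:10)))
  r <- normalize_dnam(tm, nm)
  expect_identical(r$state$applied_steps, c("zscore", "svd3", "zscore"))
  expect_lt(max(abs(colMeans(r$normal))), 1e-10)
  expect_lt(max(abs(apply(r$normal, 2, sd) - 1)), 1e-10)
  # equals manual composition of the public steps
  z1 <- zscore_by_normal(tm, nm)
  sv <- svd_detrend(z1$tumor, z1$normal, 3)
  z2 <- zscore_by_normal(sv$tumor, sv$normal)
  expect_equal(r$tumor, z2$tumor, tolerance = 1e-12)
  expect_equal(r$normal, z2$normal, tolerance = 1e-12)
})

test_that("median_normalize equalizes sample medians", {
  one <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(median_normalize(one), one)

  two <- rbind(c(1, 2, 3), c(7, 8, 9))  # medians 2 and 8, grand median 5
  r <- median_normalize(two)
  expect_equal(r[1, ], two[1, ] * 2.5)
  expect_equal(r[2, ], two[2, ] * 0.625)
  expect_lt(diff(range(apply(r, 1, median))), 1e-10)

  allsame <- matrix(4, 3, 5)
  expect_equal(median_normalize(allsame), allsame)
  zero <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), NULL))
  expect_error(median_normalize(zero), "s1")
})

test_that("binarize_mutations thresholds at one mutation", {
  expect_equal(binarize_mutations(matrix(c(0, 1, 3), 1, 3)),
               matrix(c(0L, 1L, 1L), 1, 3))
  z <- matrix(0, 2, 3)
  expect_equal(binarize_mutations(z), matrix(0L, 2, 3))
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(binarize_mutations(binarize_mutations(b)),
               binarize_mutations(b))
  expect_error(binarize_mutations(matrix(-1)), "nonnegative")
})

test_that("preprocess_cohort preserves samples and only drops features", {
  g <- generate_cohort(small_cohort_config(seed = 11))
  n <- preprocess_cohort(g$cohort)
  expect_identical(rownames(n$dnam), g$cohort$annotations$sample_id)
  expect_true(all(colnames(n$dnam) %in% colnames(g$cohort$dnam)))
  expect_length(n$normalization_states, 4)
  expect_false(anyNA(n$dnam))
})
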