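test_that("expression_delta subtracts pairwise and names unpaired ids", {
  tm <- matrix(c(3, 5), 1, 2, dimnames = list("p1", c("g1", "g2")))
  nm <- matrix(c(1, 2), 1, 2, dimnames = list("p1", c("g1", "g2")))
  expect_equal(expression_delta(tm, nm),
               matrix(c(2, 3), 1, 2, dimnames = list("p1", c("g1", "g2"))))
  expect_equal(expression_delta(tm, tm)[1, ], c(g1 = 0, g2 = 0))
  nm2 <- nm; rownames(nm2) <- "p2"
  expect_error(expression_delta(tm, nm2), "p1")
  # row count equals number of complete pairs
  tm3 <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("g1", "g2")))
  nm3 <- tm3[c(2, 1, 3), ]
  expect_identical(nrow(expression_delta(tm3, nm3)), 3L)
})

test_that("lasso_select honours the LassoFit contract", {
  set.seed(701)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_warning(empty <- lasso_select(x, rep(0, 40)), "zero-variance")
  expect_length(empty$selected_ids, 0)

  y <- x[, 2] + rnorm(40, sd = 0.1)
  fit <- lasso_select(x, y, seed = 5)
  # largest lambda kills every coefficient
  expect_true(all(fit$B[, 1] == 0))
  # chosen lambda attains the CV minimum; selected ids are the nonzeros
  expect_equal(fit$mse_per_lambda[match(fit$chosen_lambda, fit$lambda)],
               min(fit$mse_per_lambda))
  expect_setequal(fit$selected_ids,
                  rownames(fit$B)[fit$B[, match(fit$chosen_lambda,
                                                fit$lambda)] != 0])
  expect_true("f2" %in% fit$selected_ids)
})

test_that("the lasso path approaches least squares as lambda vanishes", {
  set.seed(702)
  x <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- drop(x %*% c(1, -2, 0.5, 0, 3)) + rnorm(20, sd = 0.2)
  lam <- exp(seq(log(5), log(1e-7), length.out = 60))
  fit <- lasso_select(x, y, seed = 1, lambda = lam)
  ols <- coef(lm(y ~ x))[-1]
  expect_equal(unname(fit$B[, ncol(fit$B)]), unname(ols), tolerance = 1e-4)
})

test_that("lasso recovers a planted single predictor", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1000), 50, 20, dimnames = list(NULL, sprintf("f%02d", 1:20)))
    y <- 2 * x[, 7] + rnorm(50, sd = 0.05)
    identical(lasso_select(x, y, seed = s)$selected_ids, "f07")
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("bipartite_network retains planted pairs and stays null-calibrated", {
  set.seed(703)
  n <- 40
  mut <- cbind(m1 = rbinom(n, 1, 0.4), m2 = rbinom(n, 1, 0.4))
  rownames(mut) <- paste0("p", 1:n)
  del <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(paste0("p", 1:n), paste0("g", 1:10)))
  # plant: g1..g3 shift strongly with m1
  del[, 1:3] <- del[, 1:3] + 3 * mut[, "m1"]
  edges <- bipartite_network(mut, del)
  planted <- edges[edges$mutation_id == "m1" &
                     edges$expression_id %in% c("g1", "g2", "g3"), ]
  expect_gte(nrow(planted), 3 * 0.8)
  expect_true(all(edges$fdr >= edges$p_value))
  expect_true(all(diff(edges$p_value) >= 0))
  # invariance to gene-column permutation
  edges2 <- bipartite_network(mut, del[, sample(10)])
  expect_equal(edges2[order(edges2$mutation_id, edges2$expression_id), ],
               edges[order(edges$mutation_id, edges$expression_id), ],
               ignore_attr = TRUE)
  # constant mutation skipped with warning
  mut3 <- cbind(mut, m3 = rep(1, n))
  expect_warning(e3 <- bipartite_network(mut3, del), "m3")
  expect_false("m3" %in% e3$mutation_id)

  # null: independent deltas yield (almost) no edges
  null_edges <- vapply(1:10, function(s) {
    set.seed(100 + s)
    m <- cbind(m1 = rbinom(n, 1, 0.4))
    rownames(m) <- paste0("p", 1:n)
    d <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(paste0("p", 1:n), paste0("g", 1:20)))
    nrow(bipartite_network(m, d))
  }, numeric(1))
  expect_lt(mean(null_edges), 1)
})

test_that("accel_modules links the two LASSO selections", {
  g <- generate_cohort(eqtl_cohort_config(seed = 31))
  co <- g$cohort
  anno <- co$annotations
  mut <- paired_view(co$mutation, anno)
  expr <- paired_view(median_normalize(co$expression), anno)
  deltas <- expression_delta(expr$tumor, expr$normal)
  acc <- g$truth$per_sample_acceleration
  res <- suppressMessages(
    accel_modules(mut$tumor, deltas, acc, seed = 31))
  expect_s3_class(res$mutation_fit, "lasso_fit")
  expect_true(g$truth$driver_mutation_ids %in% res$mutation_fit$selected_ids)
  expect_true(is.data.frame(res$edges))
})
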