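test_that("deg_candidates applies the sign-test / FDR / fold-change filter", {
  set.seed(801)
  n <- 30
  nm <- matrix(2^rnorm(n * 20, mean = 5), n, 20,
               dimnames = list(paste0("p", 1:n), paste0("g", 1:20)))
  # identical matrices: nothing retained
  r0 <- deg_candidates(nm, nm)
  expect_false(any(r0$retained))

  # plant a 4-fold upregulation on g1..g4
  tm <- nm
  tm[, 1:4] <- tm[, 1:4] * 4 * 2^rnorm(n * 4, sd = 0.3)
  r <- deg_candidates(tm, nm)
  expect_gte(sum(r$retained & r$gene_id %in% paste0("g", 1:4)), 3)
  expect_true(all(r$fdr >= r$p_value))

  # strong consistency but fold change only 1.5: excluded
  tm2 <- nm
  tm2[, 5] <- nm[, 5] * 1.5
  r2 <- deg_candidates(tm2, nm)
  g5 <- r2[r2$gene_id == "g5", ]
  expect_lt(g5$p_value, 1e-6)
  expect_false(g5$retained)
})

test_that("mrmr_rank maximizes relevance and penalizes redundancy", {
  lab <- rep(c(0, 1), each = 10)
  set.seed(802)
  g1 <- lab; g1[3] <- 1 - g1[3]            # near-perfect proxy of the label
  dup <- g1                                 # exact duplicate of g1
  g2 <- lab; g2[c(5, 15)] <- 1 - g2[c(5, 15)]  # informative, not identical
  noise <- sample(0:1, 20, replace = TRUE)
  x <- cbind(a_top = g1, b_dup = dup, c_alt = g2, d_noise = noise)
  ord <- mrmr_rank(x, lab, 4)
  expect_identical(ord[1], "a_top")          # maximal relevance first
  expect_false(ord[2] == "b_dup")            # duplicate penalized
  # permutation-prefix property
  expect_identical(sort(ord), sort(colnames(x)))
  expect_identical(mrmr_rank(x, lab, 0), character(0))
  expect_error(mrmr_rank(x, lab, 9), "<=")
  # greedy first element equals the exhaustive relevance maximizer
  set.seed(803)
  for (i in 1:5) {
    xr <- matrix(sample(-1:1, 8 * 6, replace = TRUE), 8, 6,
                 dimnames = list(NULL, letters[1:6]))
    l <- rep(c(0, 1), 4)
    rel <- apply(xr, 2, function(g) mutual_information(g, l))
    best <- names(rel)[order(-rel, names(rel))][1]
    expect_identical(mrmr_rank(xr, l, 1), best)
  }
})

test_that("loocv_size picks the smallest size at minimal error", {
  set.seed(804)
  lab <- rep(c(0, 1), each = 10)
  x <- cbind(s1 = lab * 4 + rnorm(20, sd = 0.1),
             s2 = rnorm(20), s3 = rnorm(20))
  r <- loocv_size(x, lab, max_size = 3)
  expect_length(r$error_curve, 3)
  expect_equal(r$error_curve[1], 0)
  expect_identical(r$module_size, 1L)
  expect_error(loocv_size(x, c(rep(0, 19), 1), 2), ">= 2")

  # random labels stay near chance
  null_err <- vapply(1:8, function(s) {
    set.seed(900 + s)
    xs <- matrix(rnorm(60), 20, 3)
    min(loocv_size(xs, sample(rep(c(0, 1), each = 10)), 3)$error_curve)
  }, numeric(1))
  expect_gte(median(null_err), 0.2)
})

test_that("find_modules recovers planted driver modules", {
  g <- generate_cohort(eqtl_cohort_config(seed = 3))
  anno <- g$cohort$annotations
  expr <- paired_view(median_normalize(g$cohort$expression), anno)
  mut <- paired_view(g$cohort$mutation, anno)
  d <- g$truth$driver_mutation_ids
  mods <- suppressWarnings(
    find_modules(expr$tumor, expr$normal, mut$tumor, d))
  expect_named(mods, d)
  m <- mods[[d]]
  expect_true(all(m$module_gene_ids %in% m$mrmr_order))
  expect_identical(m$module_gene_ids, m$mrmr_order[seq_len(m$module_size)])
  expect_equal(m$loocv_error_curve[m$module_size],
               min(m$loocv_error_curve))
  expect_gte(length(intersect(m$module_gene_ids,
                              g$truth$module_map[[d]])), 4)
  expect_true(m$informative)
  # deterministic
  mods2 <- suppressWarnings(
    find_modules(expr$tumor, expr$normal, mut$tumor, d))
  expect_identical(mods, mods2)
})

test_that("find_modules skips rare mutations and flags null ones", {
  g <- generate_cohort(eqtl_cohort_config(seed = 4))
  anno <- g$cohort$annotations
  expr <- paired_view(median_normalize(g$cohort$expression), anno)
  mut <- paired_view(g$cohort$mutation, anno)
  cs <- colSums(mut$tumor)
  rare <- names(cs)[cs %in% 1:2][1]
  expect_warning(
    mods <- find_modules(expr$tumor, expr$normal, mut$tumor, rare),
    "skipped")
  expect_length(mods, 0)

  # a balanced mutation independent of expression: near-chance LOOCV error
  set.seed(41)
  fake <- cbind(mut$tumor, fakeM = rbinom(nrow(mut$tumor), 1, 0.5))
  mods_bg <- suppressWarnings(
    find_modules(expr$tumor, expr$normal, fake, "fakeM"))
  expect_gte(min(mods_bg[["fakeM"]]$loocv_error_curve), 0.2)
})
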