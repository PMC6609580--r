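# Shared fixture builders. All cohorts are generated in code at test time;
# sizes are scaled down from the default world to keep the suite fast.

small_cohort_config <- function(seed = 1, ...) {
  synthetic_config(n_tissues = 4, samples_per_tissue = 20, n_cpgs = 400,
                   n_aging_cpgs = 10, n_genes = 150, n_mutation_genes = 40,
                   n_driver_mutations = 2, module_size = 5, seed = seed, ...)
}

null_cohort_config <- function(seed = 1, ...) {
  synthetic_config(n_tissues = 4, samples_per_tissue = 20, n_cpgs = 500,
                   n_aging_cpgs = 0, n_genes = 50, n_mutation_genes = 20,
                   n_driver_mutations = 0, tumor_accel_effect = 0,
                   driver_accel_effect = 0, module_effect = 0,
                   seed = seed, ...)
}

# single-cancer world sized for the eQTL chain
eqtl_cohort_config <- function(seed = 1, ...) {
  synthetic_config(n_tissues = 1, samples_per_tissue = 40, n_cpgs = 50,
                   n_aging_cpgs = 5, n_genes = 200, n_mutation_genes = 40,
                   n_driver_mutations = 1, module_size = 6, module_effect = 2,
                   seed = seed, ...)
}

# adjacent-normal methylation view of a (preprocessed) cohort
normal_view <- function(cohort) {
  anno <- cohort$annotations
  ni <- anno$status == "normal"
  list(dnam = cohort$dnam[anno$sample_id[ni], , drop = FALSE],
       labels = age_label(anno$age[ni]),
       tissues = anno$tissue[ni])
}

# paired tumor/normal views of one matrix
paired_view <- function(mat, annotations) {
  agingaccel:::pair_matrices(mat, annotations)
}

# independent mutual-information oracle (entropy difference, natural
# implementation distinct from the package's joint-table product form)
mi_oracle <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  ent(x) + ent(y) - ent(paste(x, y, sep = "\r"))
}

# independent K-S oracle: direct mean-based ECDF comparison on a grid
ks_oracle <- function(a, b) {
  grid <- c(a, b)
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# random two-cancer module-expression fixture for similarity tests
make_sim_fixture <- function(seed, n_g1 = 2, n_g2 = 2, n_acc = 4, n_non = 5) {
  set.seed(seed)
  ids1 <- sprintf("a%02d", seq_len(n_acc + n_non))
  ids2 <- sprintf("b%02d", seq_len(n_acc + n_non))
  e1 <- matrix(rnorm((n_acc + n_non) * n_g1), ncol = n_g1,
               dimnames = list(ids1, paste0("x", seq_len(n_g1))))
  e2 <- matrix(rnorm((n_acc + n_non) * n_g2), ncol = n_g2,
               dimnames = list(ids2, paste0("y", seq_len(n_g2))))
  s1 <- list(accelerated = ids1[seq_len(n_acc)],
             non_accelerated = ids1[-seq_len(n_acc)])
  s2 <- list(accelerated = ids2[seq_len(n_acc)],
             non_accelerated = ids2[-seq_len(n_acc)])
  list(e1 = e1, e2 = e2, s1 = s1, s2 = s2)
}

# brute-force similarity oracle: double loop over gene pairs with the
# mean-based K-S oracle
sim_oracle <- function(f) {
  acc1 <- f$e1[f$s1$accelerated, , drop = FALSE]
  non1 <- f$e1[f$s1$non_accelerated, , drop = FALSE]
  acc2 <- f$e2[f$s2$accelerated, , drop = FALSE]
  non2 <- f$e2[f$s2$non_accelerated, , drop = FALSE]
  tot <- 0
  for (i in seq_len(ncol(f$e1))) for (j in seq_len(ncol(f$e2)))
    tot <- tot + abs(ks_oracle(acc1[, i], acc2[, j]) -
                     ks_oracle(non1[, i], non2[, j]))
  tot / (log(ncol(f$e1)) + log(ncol(f$e2)))
}

# scaled-down pipeline world used by determinism tests
pipeline_test_config <- function(out_dir, seed = 5) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    synthetic = synthetic_config(
      n_tissues = 4, samples_per_tissue = 18, n_cpgs = 300,
      n_aging_cpgs = 10, n_genes = 120, n_mutation_genes = 40,
      n_driver_mutations = 2, module_size = 5, seed = seed))
}

run_quiet <- function(cfg) {
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
}

output_hashes <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  h <- tools::md5sum(file.path(dir, files))
  names(h) <- files
  h
}
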