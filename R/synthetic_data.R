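#' Configuration for the paired multi-omics cohort simulator
#'
#' Defines the stated world of the simulator: pseudo-tissues with paired
#' tumor/adjacent-normal samples, a minority of CpGs whose methylation shifts
#' with age group, tumors with elevated aging scores, and driver mutations
#' that both add aging acceleration and perturb planted expression modules.
#'
#' @param n_tissues number of pseudo-tissues.
#' @param samples_per_tissue patients (tumor/normal pairs) per tissue.
#' @param n_cpgs total CpGs.
#' @param n_aging_cpgs planted age-associated CpGs.
#' @param aging_effect mean beta-value difference between old (> 60 y) and
#'   young (<= 60 y) samples at planted CpGs.
#' @param n_genes expression genes.
#' @param n_mutation_genes mutation genes.
#' @param n_driver_mutations planted driver mutations.
#' @param driver_accel_effect added aging acceleration (score units) per
#'   carried driver mutation.
#' @param tumor_accel_effect mean baseline aging acceleration (score units)
#'   of tumors, independent of drivers.
#' @param accel_sd between-pair standard deviation of the baseline tumor
#'   acceleration; keeps a minority of pairs non-accelerated, as in real
#'   cohorts.
#' @param module_size genes perturbed per driver.
#' @param module_effect log2 fold change on perturbed genes.
#' @param noise_sd beta-scale Gaussian noise on methylation.
#' @param n_batch_factors latent technical factors on methylation (the
#'   variation the SVD step exists to remove); per-sample scores are
#'   standard normal.
#' @param batch_sd beta-scale standard deviation of the per-CpG loadings of
#'   each technical factor.
#' @param expr_noise_sd log2-scale Gaussian noise on expression.
#' @param age_range ages are uniform over `[min, max]` years.
#' @param driver_rate per-tumor Bernoulli rate of each driver mutation.
#' @param background_rate per-tumor Bernoulli rate of non-driver mutations.
#' @param seed integer seed; generation is deterministic given the config.
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tissues = 11, samples_per_tissue = 30,
                             n_cpgs = 2000, n_aging_cpgs = 20,
                             aging_effect = 0.3,
                             n_genes = 1000, n_mutation_genes = 300,
                             n_driver_mutations = 3,
                             driver_accel_effect = 0.3,
                             tumor_accel_effect = 0.3, accel_sd = 0.25,
                             module_size = 6, module_effect = 2,
                             noise_sd = 0.05, expr_noise_sd = 1,
                             n_batch_factors = 3, batch_sd = 0.02,
                             age_range = c(30, 85),
                             driver_rate = 0.3, background_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_tissues = n_tissues, samples_per_tissue = samples_per_tissue,
              n_cpgs = n_cpgs, n_aging_cpgs = n_aging_cpgs,
              aging_effect = aging_effect, n_genes = n_genes,
              n_mutation_genes = n_mutation_genes,
              n_driver_mutations = n_driver_mutations,
              driver_accel_effect = driver_accel_effect,
              tumor_accel_effect = tumor_accel_effect, accel_sd = accel_sd,
              module_size = module_size, module_effect = module_effect,
              noise_sd = noise_sd, expr_noise_sd = expr_noise_sd,
              n_batch_factors = n_batch_factors, batch_sd = batch_sd,
              age_range = age_range, driver_rate = driver_rate,
              background_rate = background_rate, seed = as.integer(seed))
  counts <- c("n_tissues", "samples_per_tissue", "n_cpgs", "n_genes",
              "n_mutation_genes", "module_size")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1)
      stop("invalid config: ", f, " must be a positive count")
  for (f in c("n_aging_cpgs", "n_driver_mutations"))
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  if (cfg$n_aging_cpgs > cfg$n_cpgs)
    stop("invalid config: n_aging_cpgs <= n_cpgs violated")
  if (cfg$n_driver_mutations > cfg$n_mutation_genes)
    stop("invalid config: n_driver_mutations <= n_mutation_genes violated")
  if (cfg$module_size * cfg$n_driver_mutations > cfg$n_genes)
    stop("invalid config: module_size * n_driver_mutations <= n_genes violated")
  if (cfg$noise_sd <= 0)
    stop("invalid config: noise_sd > 0 violated")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop("invalid config: age_range must be [min, max] with min < max")
  structure(cfg, class = "synthetic_config")
}

#' Generate a paired multi-omics cohort with known ground truth
#'
#' Simulates `n_tissues` pseudo-tissues, each with `samples_per_tissue`
#' patients contributing one tumor and one adjacent-normal sample. Planted
#' aging CpGs differ by `aging_effect` between old and young samples; tumor
#' samples additionally shift those CpGs in the age direction by
#' `a_i * aging_effect` beta units, where the pair's injected acceleration
#' `a_i ~ N(tumor_accel_effect, accel_sd) + k * driver_accel_effect` for `k`
#' carried drivers, so aging acceleration emerges through the clock rather
#' than being injected post hoc. Planted module genes are upregulated
#' by `module_effect` (log2) in all tumors of the cohort, plus a further
#' `module_effect` in driver-carrying tumors.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `cohort` (class `paired_cohort`: matrices
#'   `dnam`, `expression`, `mutation` and a data frame `annotations`) and
#'   `truth` (class `ground_truth`: `aging_cpg_ids`, `driver_mutation_ids`,
#'   `module_map`, `per_sample_acceleration` named by pair id).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_pairs <- config$n_tissues * config$samples_per_tissue
  tissue <- rep(sprintf("tissue%02d", seq_len(config$n_tissues)),
                each = config$samples_per_tissue)
  pair_id <- sprintf("%s_p%03d", tissue,
                     rep(seq_len(config$samples_per_tissue), config$n_tissues))
  age <- stats::runif(n_pairs, config$age_range[1], config$age_range[2])
  old <- as.integer(age > 60)

  cpg_ids <- sprintf("cg%05d", seq_len(config$n_cpgs))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  mut_ids <- sprintf("mg%04d", seq_len(config$n_mutation_genes))

  aging_cpgs <- sort(sample(cpg_ids, config$n_aging_cpgs))
  drivers <- if (config$n_driver_mutations > 0)
    sort(sample(mut_ids, config$n_driver_mutations)) else character(0)
  module_pool <- sample(gene_ids, config$module_size * length(drivers))
  module_map <- if (length(drivers) > 0)
    stats::setNames(split(module_pool,
                          rep(seq_along(drivers), each = config$module_size)),
                    drivers) else list()

  # mutations: somatic, tumor-only
  mutation_t <- matrix(0L, n_pairs, config$n_mutation_genes,
                       dimnames = list(NULL, mut_ids))
  bg <- setdiff(mut_ids, drivers)
  mutation_t[, bg] <- matrix(
    stats::rbinom(n_pairs * length(bg), 1, config$background_rate),
    n_pairs, length(bg))
  if (length(drivers) > 0)
    mutation_t[, drivers] <- matrix(
      stats::rbinom(n_pairs * length(drivers), 1, config$driver_rate),
      n_pairs, length(drivers))
  k_drivers <- if (length(drivers) > 0)
    rowSums(mutation_t[, drivers, drop = FALSE]) else rep(0L, n_pairs)
  # realized per-pair acceleration, in aging-score units
  accel <- (if (config$tumor_accel_effect != 0)
    stats::rnorm(n_pairs, config$tumor_accel_effect, config$accel_sd)
    else rep(0, n_pairs)) + k_drivers * config$driver_accel_effect

  # DNAm on the beta scale; aging CpGs use a narrower baseline band so the
  # planted shifts rarely hit the [0, 1] clipping boundary
  base_cpg <- stats::runif(config$n_cpgs, 0.2, 0.8)
  names(base_cpg) <- cpg_ids
  base_cpg[aging_cpgs] <- stats::runif(length(aging_cpgs), 0.3, 0.7)
  direction <- stats::setNames(sample(c(-1, 1), length(aging_cpgs), TRUE),
                               aging_cpgs)
  batch_loadings <- if (config$n_batch_factors > 0)
    matrix(stats::rnorm(config$n_cpgs * config$n_batch_factors,
                        sd = config$batch_sd),
           config$n_cpgs, config$n_batch_factors) else NULL
  make_dnam <- function(tumor) {
    m <- matrix(stats::rnorm(n_pairs * config$n_cpgs, sd = config$noise_sd),
                n_pairs, config$n_cpgs, dimnames = list(NULL, cpg_ids))
    m <- sweep(m, 2, base_cpg, "+")
    if (!is.null(batch_loadings)) {
      fac <- matrix(stats::rnorm(n_pairs * config$n_batch_factors),
                    n_pairs, config$n_batch_factors)
      m <- m + fac %*% t(batch_loadings)
    }
    if (length(aging_cpgs) > 0) {
      shift <- outer(old - 0.5, direction) * config$aging_effect
      if (tumor)
        shift <- shift + outer(accel * config$aging_effect, direction)
      m[, aging_cpgs] <- m[, aging_cpgs] + shift
    }
    pmin(pmax(m, 0), 1)
  }
  dnam_n <- make_dnam(FALSE)
  dnam_t <- make_dnam(TRUE)

  # expression: log2-normal around per-gene baselines
  base_gene <- stats::runif(config$n_genes, 3, 8)
  make_expr <- function(tumor) {
    l <- matrix(stats::rnorm(n_pairs * config$n_genes, sd = config$expr_noise_sd),
                n_pairs, config$n_genes, dimnames = list(NULL, gene_ids))
    l <- sweep(l, 2, base_gene, "+")
    if (tumor && length(drivers) > 0 && config$module_effect != 0) {
      for (d in drivers) {
        gset <- module_map[[d]]
        l[, gset] <- l[, gset] + config$module_effect +
          config$module_effect * mutation_t[, d]
      }
    }
    2^l
  }
  expr_n <- make_expr(FALSE)
  expr_t <- make_expr(TRUE)

  # interleave tumor/normal rows per pair
  sample_id <- as.vector(rbind(paste0(pair_id, "_T"), paste0(pair_id, "_N")))
  idx <- rep(seq_len(n_pairs), each = 2)
  status <- rep(c("tumor", "normal"), n_pairs)
  weave <- function(mt, mn) {
    out <- matrix(NA_real_, 2 * n_pairs, ncol(mt),
                  dimnames = list(sample_id, colnames(mt)))
    out[status == "tumor", ] <- mt
    out[status == "normal", ] <- mn
    out
  }
  mutation_n <- matrix(0L, n_pairs, config$n_mutation_genes,
                       dimnames = list(NULL, mut_ids))
  annotations <- data.frame(
    sample_id = sample_id, pair_id = pair_id[idx], tissue = tissue[idx],
    age = age[idx], status = status, stringsAsFactors = FALSE)

  mutation <- weave(mutation_t, mutation_n)
  storage.mode(mutation) <- "integer"
  cohort <- structure(list(
    dnam = weave(dnam_t, dnam_n),
    expression = weave(expr_t, expr_n),
    mutation = mutation,
    annotations = annotations), class = "paired_cohort")
  truth <- structure(list(
    aging_cpg_ids = aging_cpgs,
    driver_mutation_ids = drivers,
    module_map = module_map,
    per_sample_acceleration = stats::setNames(accel, pair_id)),
    class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("paired multi-omics cohort:",
      nrow(x$annotations), "samples (",
      length(unique(x$annotations$pair_id)), "pairs,",
      length(unique(x$annotations$tissue)), "tissues )\n")
  cat("  dnam:", ncol(x$dnam), "CpGs | expression:", ncol(x$expression),
      "genes | mutation:", ncol(x$mutation), "genes\n")
  invisible(x)
}

.cohort_files <- c(dnam = "dnam.tsv", expression = "expression.tsv",
                   mutation = "mutation.tsv", annotations = "annotations.tsv")

#' Write / read a cohort directory
#'
#' The on-disk layout is plain TSV: `dnam.tsv`, `expression.tsv`,
#' `mutation.tsv` (first column `sample_id`, header row of feature ids),
#' `annotations.tsv`, and optionally `ground_truth.json`. The round trip is
#' lossless up to numeric text representation (15 significant digits).
#'
#' @param cohort a `paired_cohort`.
#' @param directory target directory (created if absent).
#' @param truth optional `ground_truth` to serialize alongside.
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a list
#'   with `cohort` and (when present on disk) `truth`.
#' @export
write_cohort <- function(cohort, directory, truth = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.cohort_files)[1:3]) {
    m <- cohort[[nm]]
    dt <- data.table::data.table(sample_id = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, file.path(directory, .cohort_files[[nm]]),
                       sep = "\t")
  }
  data.table::fwrite(cohort$annotations,
                     file.path(directory, "annotations.tsv"), sep = "\t")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(aging_cpg_ids = truth$aging_cpg_ids,
           driver_mutation_ids = truth$driver_mutation_ids,
           module_map = truth$module_map,
           per_sample_acceleration = as.list(truth$per_sample_acceleration)),
      file.path(directory, "ground_truth.json"),
      auto_unbox = FALSE, digits = NA)
  }
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  for (f in .cohort_files)
    if (!file.exists(file.path(directory, f)))
      stop("cohort directory is missing file: ", f)
  read_mat <- function(f, integer = FALSE) {
    dt <- data.table::fread(file.path(directory, f), sep = "\t")
    ids <- dt[[1]]
    m <- as.matrix(dt[, -1])
    rownames(m) <- ids
    if (integer) storage.mode(m) <- "integer"
    m
  }
  dnam <- read_mat("dnam.tsv")
  expression <- read_mat("expression.tsv")
  mutation <- read_mat("mutation.tsv", integer = TRUE)
  annotations <- as.data.frame(
    data.table::fread(file.path(directory, "annotations.tsv"), sep = "\t"))
  for (nm in c("dnam", "expression", "mutation")) {
    ids <- rownames(get(nm))
    if (anyDuplicated(ids))
      stop("duplicate sample ids in ", .cohort_files[[nm]])
    bad <- which(ids != annotations$sample_id)
    if (length(ids) != nrow(annotations) || length(bad) > 0) {
      first <- if (length(bad) > 0) ids[bad[1]] else ids[1]
      stop("sample ids in ", .cohort_files[[nm]],
           " disagree with annotations; first mismatched id: ", first)
    }
  }
  cohort <- structure(list(dnam = dnam, expression = expression,
                           mutation = mutation, annotations = annotations),
                      class = "paired_cohort")
  truth <- NULL
  tf <- file.path(directory, "ground_truth.json")
  if (file.exists(tf)) {
    j <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- structure(list(
      aging_cpg_ids = as.character(j$aging_cpg_ids),
      driver_mutation_ids = as.character(j$driver_mutation_ids),
      module_map = lapply(j$module_map, as.character),
      per_sample_acceleration = unlist(j$per_sample_acceleration)),
      class = "ground_truth")
  }
  list(cohort = cohort, truth = truth)
}

# split a cohort matrix into aligned tumor/normal matrices with pair-id rows
pair_matrices <- function(mat, annotations) {
  tum <- annotations[annotations$status == "tumor", ]
  nor <- annotations[annotations$status == "normal", ]
  common <- intersect(tum$pair_id, nor$pair_id)
  unpaired <- setdiff(union(tum$pair_id, nor$pair_id), common)
  if (length(unpaired) > 0)
    stop("unpaired sample for pair id: ", unpaired[1])
  tum <- tum[match(common, tum$pair_id), ]
  nor <- nor[match(common, nor$pair_id), ]
  t_m <- mat[tum$sample_id, , drop = FALSE]
  n_m <- mat[nor$sample_id, , drop = FALSE]
  rownames(t_m) <- rownames(n_m) <- common
  list(tumor = t_m, normal = n_m, pair_ids = common,
       tumor_anno = tum, normal_anno = nor)
}
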