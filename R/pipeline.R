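#' Pipeline configuration
#'
#' Bundles every stage's parameters: retention thresholds (p < 0.05,
#' FDR < 0.2, fold change > 2, score threshold 0.5), LASSO folds (5),
#' network edge rules (top k = 10, cutoff = 100), the root seed, and either
#' a synthetic-cohort configuration or an input directory.
#'
#' @param out_dir output directory.
#' @param synthetic a [synthetic_config()] (used when `input_dir` is NULL).
#' @param input_dir existing cohort directory (overrides simulation).
#' @param gmt optional GMT path for enrichment; when NULL and simulating,
#'   a synthetic collection is built around the planted modules.
#' @param seed root seed; each stage derives its own seed from it.
#' @param network_k,network_cutoff edge-selection parameters.
#' @param min_mutated,max_rank,max_size eQTL-stage controls.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synthetic = synthetic_config(),
                            input_dir = NULL, gmt = NULL, seed = 1L,
                            network_k = 10, network_cutoff = 100,
                            min_mutated = 3, max_rank = 30, max_size = 15) {
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 input_dir = input_dir, gmt = gmt, seed = as.integer(seed),
                 network_k = network_k, network_cutoff = network_cutoff,
                 min_mutated = min_mutated, max_rank = max_rank,
                 max_size = max_size),
            class = "pipeline_config")
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    dt <- data.table::data.table(V1 = rownames(x))
    data.table::setnames(dt, "V1", rownames_as)
    x <- cbind(dt, data.table::as.data.table(as.data.frame(x)))
  }
  data.table::fwrite(x, path, sep = "\t")
  path
}

#' Run the full pipeline
#'
#' Executes simulate (unless an input directory is given), preprocess,
#' clock, modules, eqtl, enrichment and network, writing machine-readable
#' outputs under `config$out_dir` and a JSON run manifest. A rerun with the
#' same configuration and seed reproduces all outputs bitwise (manifest
#' wall times excepted). Every tissue is treated as one cancer type.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    manifest[[name]] <<- list(stage = name,
                              elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
                              outputs = res$outputs %||% character(0))
    res$value
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  # -- simulate / load ------------------------------------------------------
  sim <- t_stage("simulate", {
    if (!is.null(config$input_dir)) {
      if (!dir.exists(config$input_dir))
        stop("input directory does not exist: ", config$input_dir)
      r <- read_cohort(config$input_dir)
      list(value = r, outputs = character(0))
    } else {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      g <- generate_cohort(do.call(synthetic_config, unclass(cfg)))
      d <- file.path(out, "cohort")
      write_cohort(g$cohort, d, g$truth)
      list(value = g, outputs = d)
    }
  })
  cohort <- sim$cohort
  truth <- sim$truth

  # -- preprocess -----------------------------------------------------------
  norm <- t_stage("preprocess", {
    n <- preprocess_cohort(cohort)
    f <- write_tsv(n$dnam, file.path(out, "dnam_normalized.tsv"),
                   rownames_as = "sample_id")
    list(value = n, outputs = f)
  })

  anno <- norm$annotations

  # -- clock ----------------------------------------------------------------
  clock <- t_stage("clock", {
    normal_idx <- anno$status == "normal"
    dn <- norm$dnam[anno$sample_id[normal_idx], , drop = FALSE]
    labels <- age_label(anno$age[normal_idx])
    tissues <- anno$tissue[normal_idx]
    cands <- screen_markers(dn, labels)
    model <- train_clock(dn, labels, tissues, cands$cpg_id)
    scores <- score_samples(model, norm$dnam, anno)
    at <- acceleration_test(scores$pairs$tumor_score,
                            scores$pairs$normal_score)
    f1 <- file.path(out, "clock_model.json")
    jsonlite::write_json(
      list(marker_ids = model$marker_ids,
           weights = unname(model$svr$weights), offset = model$svr$offset,
           center = unname(model$svr$center), scale = unname(model$svr$scale),
           score_threshold = model$score_threshold,
           learning_curve = model$learning_curve,
           acceleration_test = at),
      f1, auto_unbox = TRUE, digits = NA)
    sc <- merge(scores$samples,
                anno[, c("sample_id", "pair_id", "status")], by = "sample_id")
    sc <- merge(sc, scores$pairs[, c("pair_id", "acceleration")],
                by = "pair_id", all.x = TRUE)
    f2 <- write_tsv(sc[order(sc$sample_id),
                       c("sample_id", "score", "label", "pair_id",
                         "acceleration")],
                    file.path(out, "scores.tsv"))
    f3 <- write_tsv(cands, file.path(out, "candidate_markers.tsv"))
    list(value = list(model = model, scores = scores, candidates = cands),
         outputs = c(f1, f2, f3))
  })
  scores <- clock$scores
  tissues <- sort(unique(anno$tissue))
  pair_tissue <- anno$tissue[match(scores$pairs$pair_id, anno$pair_id)]
  acc <- stats::setNames(scores$pairs$acceleration, scores$pairs$pair_id)
  expr_norm <- norm$expression

  per_cancer_pairs <- lapply(stats::setNames(tissues, tissues), function(ts)
    scores$pairs$pair_id[pair_tissue == ts])

  # -- modules --------------------------------------------------------------
  modules <- t_stage("modules", {
    res <- list(); outs <- character(0)
    for (ts in tissues) {
      pid <- per_cancer_pairs[[ts]]
      sub <- anno[anno$tissue == ts, ]
      mut <- pair_matrices(norm$mutation[sub$sample_id, , drop = FALSE], sub)
      expr <- pair_matrices(expr_norm[sub$sample_id, , drop = FALSE], sub)
      deltas <- expression_delta(expr$tumor, expr$normal)
      res[[ts]] <- accel_modules(mut$tumor[pid, , drop = FALSE],
                                 deltas[pid, , drop = FALSE], acc,
                                 min_mutated = config$min_mutated,
                                 seed = config$seed + match(ts, tissues))
      f <- write_tsv(res[[ts]]$edges,
                     file.path(out, paste0("edges_", ts, ".tsv")))
      outs <- c(outs, f)
    }
    sel <- do.call(rbind, lapply(tissues, function(ts) {
      n_m <- length(res[[ts]]$mutation_fit$selected_ids)
      n_e <- length(res[[ts]]$expression_fit$selected_ids)
      data.frame(
        cancer = rep(ts, n_m + n_e),
        type = rep(c("mutation", "expression"), c(n_m, n_e)),
        feature_id = c(res[[ts]]$mutation_fit$selected_ids,
                       res[[ts]]$expression_fit$selected_ids),
        coefficient = unname(c(res[[ts]]$mutation_fit$coefficients,
                               res[[ts]]$expression_fit$coefficients)),
        stringsAsFactors = FALSE)
    }))
    f <- write_tsv(sel, file.path(out, "selected_modules.tsv"))
    list(value = res, outputs = c(f, outs))
  })

  # -- eqtl -----------------------------------------------------------------
  eqtl <- t_stage("eqtl", {
    res <- list(); rows <- list()
    for (ts in tissues) {
      sub <- anno[anno$tissue == ts, ]
      mut <- pair_matrices(norm$mutation[sub$sample_id, , drop = FALSE], sub)
      expr <- pair_matrices(expr_norm[sub$sample_id, , drop = FALSE], sub)
      sel_mut <- modules[[ts]]$mutation_fit$selected_ids
      if (length(sel_mut) == 0) next
      mods <- withCallingHandlers(
        find_modules(expr$tumor, expr$normal, mut$tumor, sel_mut,
                     min_mutated = config$min_mutated,
                     max_rank = config$max_rank, max_size = config$max_size),
        warning = function(w) invokeRestart("muffleWarning"))
      res[[ts]] <- mods
      for (m in names(mods))
        rows[[paste(ts, m)]] <- data.frame(
          cancer = ts, mutation_id = m,
          rank = seq_along(mods[[m]]$mrmr_order),
          gene_id = mods[[m]]$mrmr_order,
          in_module = seq_along(mods[[m]]$mrmr_order) <=
            mods[[m]]$module_size,
          stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cancer = character(0), mutation_id = character(0),
                 rank = integer(0), gene_id = character(0),
                 in_module = logical(0))
    f <- write_tsv(tab, file.path(out, "eqtl_modules.tsv"))
    list(value = res, outputs = f)
  })

  module_genes <- lapply(eqtl, function(mods)
    sort(unique(unlist(lapply(mods, `[[`, "module_gene_ids")))))
  module_genes <- module_genes[lengths(module_genes) > 0]

  # -- enrichment -----------------------------------------------------------
  enr <- t_stage("enrichment", {
    collection <- if (!is.null(config$gmt)) {
      read_gmt(config$gmt)
    } else if (!is.null(truth)) {
      coll <- synthetic_gene_sets(colnames(cohort$expression), truth,
                                  seed = config$seed)
      write_gmt(coll, file.path(out, "synthetic_gene_sets.gmt"))
      coll
    } else stop("no GMT supplied and no ground truth to build one from")
    tables <- lapply(module_genes, function(g)
      tryCatch(enrich(g, collection), error = function(e) NULL))
    tables <- Filter(Negate(is.null), tables)
    fdr_tab <- NULL; cc <- NULL
    outs <- character(0)
    if (length(tables) > 0) {
      long <- do.call(rbind, Map(function(ts, tab)
        cbind(cancer = ts, tab), names(tables), tables))
      outs <- write_tsv(long, file.path(out, "enrichment.tsv"))
      fdr_tab <- t(vapply(tables, function(tab)
        tab$fdr[match(names(collection$sets), tab$set_name)],
        numeric(length(collection$sets))))
      colnames(fdr_tab) <- names(collection$sets)
      if (nrow(fdr_tab) >= 2) {
        cc <- cancer_correlation(fdr_tab)
        outs <- c(outs, write_tsv(cc, file.path(out, "cancer_correlation.tsv"),
                                  rownames_as = "cancer"))
      }
    }
    list(value = list(collection = collection, tables = tables,
                      correlation = cc),
         outputs = outs)
  })

  # -- network --------------------------------------------------------------
  net <- t_stage("network", {
    eligible <- list(); splits <- list()
    for (ts in names(module_genes)) {
      sub <- anno[anno$tissue == ts, ]
      expr <- pair_matrices(expr_norm[sub$sample_id, , drop = FALSE], sub)
      sp <- split_by_acceleration(
        scores$pairs[scores$pairs$pair_id %in% rownames(expr$tumor), ])
      if (length(sp$accelerated) < 2 || length(sp$non_accelerated) < 2) {
        message("cancer ", ts, " lacks >= 2 samples on a split side; ",
                "excluded from the similarity network")
        next
      }
      eligible[[ts]] <- expr$tumor[, module_genes[[ts]], drop = FALSE]
      splits[[ts]] <- sp
    }
    if (length(eligible) < 2) {
      message("fewer than two eligible cancers; network skipped")
      list(value = NULL, outputs = character(0))
    } else {
      sm <- similarity_matrix(eligible, splits)
      topk <- build_network(sm$edges, "top_k", config$network_k)
      thr <- build_network(sm$edges, "threshold", config$network_cutoff)
      f1 <- write_tsv(sm$matrix, file.path(out, "similarity_matrix.tsv"),
                      rownames_as = "cancer")
      f2 <- write_tsv(sm$edges, file.path(out, "similarity_edges.tsv"))
      f3 <- file.path(out, "network.json")
      jsonlite::write_json(
        list(top_k = list(mode = topk$mode, parameter = topk$parameter,
                          edges = topk$edges,
                          degrees = as.list(topk$degrees)),
             threshold = list(mode = thr$mode, parameter = thr$parameter,
                              edges = thr$edges,
                              degrees = as.list(thr$degrees))),
        f3, auto_unbox = TRUE, digits = NA)
      list(value = list(similarity = sm, top_k = topk, threshold = thr),
           outputs = c(f1, f2, f3))
    }
  })

  manifest_out <- list(seed = config$seed, stages = unname(manifest))
  jsonlite::write_json(manifest_out, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest_out, clock = clock, modules = modules,
                 eqtl = eqtl, enrichment = enr, network = net))
}

#' Synthetic gene-set collection around planted modules
#'
#' Builds a labelled-synthetic GMT-style collection over the expression
#' universe: one set per planted driver containing its module genes plus
#' random filler, and random background sets.
#'
#' @param universe expression gene ids.
#' @param truth a `ground_truth`.
#' @param n_background number of random background sets (default 30).
#' @param set_size genes per set (default 50).
#' @param seed RNG seed.
#' @return a `gene_set_collection`.
#' @export
synthetic_gene_sets <- function(universe, truth, n_background = 30,
                                set_size = 50, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sets <- list()
  for (d in names(truth$module_map)) {
    genes <- truth$module_map[[d]]
    filler <- sample(setdiff(universe, genes),
                     max(0, set_size - length(genes)))
    sets[[paste0("PLANTED_", d)]] <- sort(c(genes, filler))
  }
  for (i in seq_len(n_background))
    sets[[sprintf("RANDOM_%02d", i)]] <- sort(sample(universe, set_size))
  gene_set_collection(sets, universe = sort(universe))
}
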