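#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Duplicate genes within a set are
#' removed. The universe defaults to the union of all set genes.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe.
#' @return object of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `universe`, `universe_size`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      message("duplicate gene(s) in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0 || any(lengths(sets) == 0))
    stop("collection must contain only nonempty sets")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  stray <- setdiff(unlist(sets), universe)
  if (length(stray) > 0)
    stop("set gene(s) outside the universe: ", stray[1])
  structure(list(sets = sets, universe = universe,
                 universe_size = length(universe)),
            class = "gene_set_collection")
}

#' Write a collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' One record per set: the exact upper-tail hypergeometric p-value of the
#' overlap between the query module and the set, with the universe as
#' background; Benjamini-Hochberg adjustment over all sets in the
#' collection; significance at p < 0.05 and FDR < 0.2; sorted by p.
#'
#' @param module_genes nonempty gene-id vector (intersecting the universe).
#' @param collection a `gene_set_collection`.
#' @param p_cut,fdr_cut significance thresholds.
#' @return data frame `set_name`, `M`, `n`, `k`, `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich <- function(module_genes, collection, p_cut = 0.05, fdr_cut = 0.2) {
  if (length(module_genes) == 0) stop("module must be nonempty")
  query <- intersect(unique(module_genes), collection$universe)
  if (length(query) == 0)
    stop("module is disjoint from the collection universe")
  N <- collection$universe_size
  n <- length(query)
  recs <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    k <- length(intersect(query, set))
    data.frame(set_name = nm, M = length(set), n = n, k = k,
               p_value = hypergeom_upper(N, length(set), n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$p_value < p_cut & out$fdr < fdr_cut
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Cross-cancer correlation of enrichment profiles
#'
#' Pearson correlation between cancers of their `(1 - FDR)` profiles over
#' gene sets; sets untested in a cancer are imputed FDR = 1. A cancer with a
#' zero-variance profile has undefined correlations, reported as `NA`.
#'
#' @param fdr_table cancer x set matrix of FDR values (`NA` = untested).
#' @return symmetric cancer x cancer correlation matrix with unit diagonal.
#' @export
cancer_correlation <- function(fdr_table) {
  if (nrow(fdr_table) < 2 || ncol(fdr_table) < 2)
    stop("need >= 2 cancers and >= 2 sets")
  x <- 1 - ifelse(is.na(fdr_table), 1, fdr_table)
  degenerate <- apply(x, 1, stats::sd) == 0
  if (any(degenerate))
    message("zero-variance profile(s): ",
            paste(rownames(x)[degenerate], collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[degenerate, ] <- NA_real_
  cc[, degenerate] <- NA_real_
  diag(cc) <- 1
  cc
}
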