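#' @title Three-study outlier overlap and empirical-null replication
#' @description The replication scheme of the scan: each discovery study
#' flags the bottom 1% of genes by gene p-value (rank-based, boundary ties
#' included); genes flagged in both discovery studies form the candidate
#' overlap; candidates replicate when their p-value in a third study falls
#' strictly below the 1st percentile of the p-values of randomly selected
#' null genes in that study.
#' @name cross_study
NULL

#' Per-study significant gene set (bottom quantile by rank)
#'
#' Returns the `ceiling(quantile * G)` genes with the smallest gene p-value;
#' all genes tied with the boundary p-value are included (and the excess over
#' the nominal count is reported via a message). A table with fewer than 100
#' genes triggers a warning that the bottom-1% set is degenerate.
#'
#' @param table per-study gene table (e.g. from [gene_lead_table()]).
#' @param quantile flagged fraction of genes (default 0.01).
#' @param p_col column holding the gene p-value (default `"lead_p"`; use
#'   `"magma_p"` for the gamma-aggregated analysis).
#' @return character vector of significant gene ids.
#' @export
study_significant <- function(table, quantile = 0.01, p_col = "lead_p") {
  if (!nrow(table)) stop("empty gene table")
  if (nrow(table) < 100) {
    warning("fewer than 100 genes: the bottom ", quantile * 100,
            "% set is degenerate")
  }
  p <- table[[p_col]]
  k <- ceiling(quantile * nrow(table))
  cut <- sort(p, partial = k)[k]
  sel <- which(p <= cut)
  if (length(sel) > k) {
    message(length(sel) - k, " boundary tie(s) included beyond the nominal ",
            k, " genes")
  }
  table$gene_id[sel]
}

#' Overlap of two significant gene sets
#'
#' Set intersection with a deterministic (sorted) output order.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return sorted character vector of shared gene ids.
#' @export
overlap_significant <- function(set_a, set_b) {
  sort(intersect(set_a, set_b))
}

#' Empirical-null percentile threshold
#'
#' Lower-interpolation empirical percentile of null gene p-values: the k-th
#' order statistic with `k = ceiling(percentile/100 * n)`. With fewer than
#' 100 null values the 1st percentile is the minimum order statistic, which
#' is flagged with a warning.
#'
#' @param null_p numeric vector of null gene p-values.
#' @param percentile percentile in (0, 100), default 1.
#' @return the threshold value.
#' @export
empirical_null_threshold <- function(null_p, percentile = 1) {
  stopifnot(length(null_p) > 0, percentile > 0, percentile < 100)
  if (length(null_p) < 100) {
    warning("fewer than 100 null genes: the ", percentile,
            "th percentile is the minimum order statistic")
  }
  k <- ceiling(percentile / 100 * length(null_p))
  sort(null_p)[k]
}

#' Replicate candidate genes against an empirical null in a third study
#'
#' A candidate is cross-study significant when its gene p-value in the
#' replication study is strictly below the empirical-null threshold computed
#' from the designated null genes in that same study. Candidates missing
#' from the replication table are recorded as untested.
#'
#' @param candidates character vector of candidate gene ids (the discovery
#'   overlap).
#' @param replication_table gene table of the replication study.
#' @param null_gene_ids ids of the null genes (must be disjoint from
#'   `candidates` and present in the replication table).
#' @param percentile passed to [empirical_null_threshold()].
#' @inheritParams study_significant
#' @return object of class `cross_study_report`: a list with the candidate
#'   set, null gene ids, `null_threshold`, `cross_study_significant`,
#'   `untested`, and a per-candidate tibble `detail`.
#' @export
replicate_candidates <- function(candidates, replication_table, null_gene_ids,
                                 percentile = 1, p_col = "lead_p") {
  if (length(intersect(candidates, null_gene_ids))) {
    stop("null genes must be disjoint from the candidate set")
  }
  p <- setNames(replication_table[[p_col]], replication_table$gene_id)
  null_p <- p[null_gene_ids]
  if (any(is.na(null_p))) {
    stop(sum(is.na(null_p)), " null gene(s) missing from the replication table")
  }
  thr <- empirical_null_threshold(unname(null_p), percentile = percentile)
  cand_p <- p[candidates]
  untested <- candidates[is.na(cand_p)]
  detail <- tibble::tibble(
    gene_id = candidates,
    replication_p = unname(cand_p),
    status = dplyr::case_when(
      is.na(cand_p) ~ "untested",
      cand_p < thr ~ "significant",
      TRUE ~ "not_significant"
    )
  )
  structure(
    list(
      candidates = candidates,
      null_gene_ids = null_gene_ids,
      null_threshold = thr,
      percentile = percentile,
      p_col = p_col,
      cross_study_significant = detail$gene_id[detail$status == "significant"],
      untested = untested,
      detail = detail
    ),
    class = "cross_study_report"
  )
}

#' @export
print.cross_study_report <- function(x, ...) {
  cat("<cross_study_report>\n")
  if (!is.null(x$discovery_studies)) {
    cat("  discovery:", paste(x$discovery_studies, collapse = " + "),
        "-> replication:", x$replication_study, "\n")
    cat(sprintf("  per-study significant: %s\n",
                paste(sprintf("%s=%d", names(x$per_study_significant),
                              lengths(x$per_study_significant)),
                      collapse = ", ")))
  }
  cat(sprintf("  candidates: %d | null genes: %d | threshold: %.3g\n",
              length(x$candidates), length(x$null_gene_ids), x$null_threshold))
  cat(sprintf("  cross-study significant: %d (%s)\n",
              length(x$cross_study_significant),
              paste(x$cross_study_significant, collapse = ", ")))
  if (length(x$untested)) {
    cat("  untested (missing from replication table):",
        paste(x$untested, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full three-study outlier-replication scan
#'
#' Runs the whole scheme over per-study gene tables: bottom-quantile flags in
#' the two discovery studies, overlap, sampling of null genes (uniformly
#' without replacement from the replication study's non-candidate genes),
#' and empirical-null replication. Given identical inputs and
#' `null_gene_ids`, the report is reproduced exactly.
#'
#' @param tables named list of per-study gene tables (e.g. from
#'   [gene_lead_table()]); names are study ids.
#' @param discovery two study ids used for the bottom-quantile stages.
#' @param replication study id used for the empirical-null replication.
#' @param quantile per-study flagged fraction (default 0.01).
#' @param n_null number of null genes (default 200).
#' @param percentile empirical-null percentile (default 1).
#' @param null_gene_ids optional explicit null gene ids; when `NULL` they
#'   are sampled with the current RNG state (seed the session for
#'   reproducibility).
#' @inheritParams study_significant
#' @return a `cross_study_report` with the per-study sets, overlap and
#'   replication results.
#' @export
cross_study_scan <- function(tables, discovery = names(tables)[1:2],
                             replication = names(tables)[3],
                             quantile = 0.01, n_null = 200, percentile = 1,
                             null_gene_ids = NULL, p_col = "lead_p") {
  stopifnot(length(discovery) == 2, length(replication) == 1)
  stopifnot(all(c(discovery, replication) %in% names(tables)))
  sig <- lapply(tables[discovery], study_significant,
                quantile = quantile, p_col = p_col)
  candidates <- overlap_significant(sig[[1]], sig[[2]])
  rep_table <- tables[[replication]]
  if (is.null(null_gene_ids)) {
    pool <- setdiff(rep_table$gene_id, candidates)
    if (length(pool) < n_null) {
      stop("replication table has only ", length(pool),
           " non-candidate genes; cannot sample ", n_null, " null genes")
    }
    null_gene_ids <- sample(pool, n_null)
  }
  report <- replicate_candidates(candidates, rep_table, null_gene_ids,
                                 percentile = percentile, p_col = p_col)
  report$discovery_studies <- discovery
  report$replication_study <- replication
  report$per_study_significant <- sig
  report$quantile <- quantile
  report
}
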