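#' @title Gene-level aggregation of per-SNP statistics
#' @description Two gene-level summaries are provided. The primary one is the
#' lead-SNP rule: a gene's p-value is the smallest p-value among its SNPs,
#' with exact ties broken by the larger absolute male-female frequency
#' difference and then by position. The second is an LD-aware weighted-sum
#' statistic in the style of MAGMA / Brown's method: SNP p-values are
#' transformed (by default to chi-square(2) deviates, `-2 ln p`), summed with
#' weights, and the null of the sum is approximated by a gamma distribution
#' whose moments account for the pairwise correlation of the SNPs.
#' @name gene_agg
NULL

#' Lead SNP of a gene
#'
#' Selects the minimum-p SNP among a gene's SNP results; exact p-value ties
#' are broken by the greatest `|delta_freq|`, remaining ties by the smallest
#' position (deterministic).
#'
#' @param gene_id gene identifier for the output row.
#' @param snp_results data frame with columns `snp_id`, `p_value`,
#'   `delta_freq`, and optionally `pos` (needed only to break double ties).
#' @return one-row tibble: `gene_id`, `lead_snp_id`, `lead_p`,
#'   `lead_delta_freq`, `n_snps`.
#' @export
lead_snp <- function(gene_id, snp_results) {
  if (!nrow(snp_results)) stop("no SNP results supplied for gene ", gene_id)
  pos <- if ("pos" %in% names(snp_results)) snp_results$pos else seq_len(nrow(snp_results))
  ord <- order(snp_results$p_value, -abs(snp_results$delta_freq), pos)
  i <- ord[1]
  tibble::tibble(
    gene_id = gene_id,
    lead_snp_id = snp_results$snp_id[i],
    lead_p = snp_results$p_value[i],
    lead_delta_freq = snp_results$delta_freq[i],
    n_snps = nrow(snp_results)
  )
}

#' Per-gene lead-SNP table for one study
#'
#' Applies [lead_snp()] to every gene of a SNP-to-gene mapping. Genes with no
#' assigned SNP are omitted (with a message naming how many).
#'
#' @param snp_stats per-SNP results from [snp_scan()].
#' @param gene_map named list from [map_snps_to_genes()].
#' @param study_id optional study label added as a column.
#' @return tibble with one row per gene carrying lead-SNP fields.
#' @export
gene_lead_table <- function(snp_stats, gene_map, study_id = NULL) {
  idx <- split(seq_len(nrow(snp_stats)), snp_stats$snp_id)
  rows <- lapply(names(gene_map), function(g) {
    i <- unlist(idx[gene_map[[g]]], use.names = FALSE)
    if (!length(i)) return(NULL)
    lead_snp(g, snp_stats[i, , drop = FALSE])
  })
  empty <- sum(vapply(rows, is.null, logical(1)))
  if (empty) message(empty, " gene(s) had no SNPs and were omitted")
  out <- dplyr::bind_rows(rows)
  if (!is.null(study_id)) out <- dplyr::mutate(out, study_id = study_id, .before = 1)
  out
}

#' Pairwise SNP correlation matrix from dosages
#'
#' Pearson correlation of dosage columns (0/1/2 or imputed reals), with
#' monomorphic columns set to zero correlation off the diagonal, and linear
#' shrinkage toward the identity, `C <- (1 - lambda) C + lambda I`, to keep
#' the matrix positive semi-definite.
#'
#' @param dosages numeric matrix, individuals x SNPs; column names are the
#'   SNP ids.
#' @param shrinkage shrinkage weight `lambda` toward the identity
#'   (default 0.001).
#' @return symmetric correlation matrix with unit diagonal and the SNP ids
#'   as dimnames.
#' @export
estimate_correlations <- function(dosages, shrinkage = 0.001) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2) stop("at least two individuals are required")
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp_", seq_len(ncol(dosages)))
  }
  suppressWarnings(C <- stats::cor(dosages))
  C[is.na(C)] <- 0 # monomorphic columns: zero correlation
  diag(C) <- 1
  C <- (1 - shrinkage) * C + shrinkage * diag(ncol(C))
  dimnames(C) <- list(colnames(dosages), colnames(dosages))
  C
}

#' Covariance of transformed p-values for two correlated SNPs
#'
#' Approximate covariance of the transformed statistics of two SNPs whose
#' underlying Z scores have correlation `r`. For the default `chisq2`
#' transform (`-2 ln p`, two-sided p-values) the Brown-style polynomial
#' `c(r) = r^2 (3.875 + 0.125 r^2)` is used: it is exact at the endpoints
#' (`c(0) = 0`, `c(1) = 4 = Var(-2 ln p)`) and was fitted against
#' large-sample Monte-Carlo covariances of two-sided chi-square p-values
#' (within ~1% for `|r| >= 0.2`). For the `neg_log10` transform the
#' same polynomial is rescaled by `1 / (2 ln 10)^2`. A Monte-Carlo estimate
#' under bivariate-normal Z scores is available as an independent check via
#' `monte_carlo = TRUE`.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param transform `"chisq2"` (default) or `"neg_log10"`.
#' @param monte_carlo estimate by simulation instead of the polynomial.
#' @param n_draws number of Monte-Carlo draws.
#' @return covariance value(s).
#' @export
transform_covariance <- function(r, transform = c("chisq2", "neg_log10"),
                                 monte_carlo = FALSE, n_draws = 1e6) {
  transform <- match.arg(transform)
  stopifnot(all(abs(r) <= 1))
  if (monte_carlo) {
    cv <- vapply(r, function(ri) {
      z1 <- stats::rnorm(n_draws)
      z2 <- ri * z1 + sqrt(1 - ri^2) * stats::rnorm(n_draws)
      t1 <- -2 * stats::pchisq(z1^2, 1, lower.tail = FALSE, log.p = TRUE)
      t2 <- -2 * stats::pchisq(z2^2, 1, lower.tail = FALSE, log.p = TRUE)
      stats::cov(t1, t2)
    }, 0)
  } else {
    cv <- r^2 * (3.875 + 0.125 * r^2)
  }
  if (transform == "neg_log10") cv <- cv / (2 * log(10))^2
  cv
}

#' Gamma-approximated gene statistic from correlated SNP p-values
#'
#' Weighted sum of transformed SNP p-values with a moment-matched gamma null.
#' With the default `chisq2` transform, `T = sum w_i (-2 ln p_i)` has null
#' moments `E(T) = 2 sum w_i` and
#' `Var(T) = 4 sum w_i^2 + 2 sum_{i<j} w_i w_j c(r_ij)`
#' with `c()` from [transform_covariance()], and the gene p-value is the
#' upper tail of a gamma with shape `E^2/Var` and scale `Var/E` at `T` (for a
#' single SNP this reduces exactly to the SNP p-value). `variant = "printed"`
#' instead reproduces a published parameterisation verbatim — `-log10`
#' transform, `E(T) = sum w_i`, shape `E/Var`, scale `Var/E` — which is not
#' internally consistent (its gamma always has mean 1) and is retained only
#' for comparison; its output is labelled accordingly.
#'
#' @param p_values SNP p-values in (0, 1]; zeros are clamped to `p_floor`
#'   with a warning.
#' @param C correlation matrix from [estimate_correlations()] (or any
#'   symmetric PSD matrix with unit diagonal); `NULL` means independent SNPs.
#' @param weights per-SNP weights, default all 1.
#' @param transform transformation of p-values; see [transform_covariance()].
#' @param variant `"matched"` (moment-matched gamma, default) or
#'   `"printed"` (published parameterisation, for comparison only).
#' @param p_floor clamp for zero p-values.
#' @param gene_id optional label for the output row.
#' @return one-row tibble: `gene_id`, `magma_T`, `magma_alpha`,
#'   `magma_theta`, `magma_p`, `variant`, `n_snps`.
#' @examples
#' magma_gene_statistic(c(0.05, 0.05), C = diag(2))
#' @export
magma_gene_statistic <- function(p_values, C = NULL, weights = NULL,
                                 transform = c("chisq2", "neg_log10"),
                                 variant = c("matched", "printed"),
                                 p_floor = 1e-300, gene_id = NA_character_) {
  transform <- match.arg(transform)
  variant <- match.arg(variant)
  n <- length(p_values)
  if (any(p_values <= 0)) {
    warning("p-value(s) of 0 clamped to ", p_floor)
    p_values <- pmax(p_values, p_floor)
  }
  stopifnot(all(p_values <= 1))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (is.null(C)) C <- diag(n)
  C <- as.matrix(C)
  stopifnot(nrow(C) == n, ncol(C) == n)
  if (n > 1) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite; ",
           "increase the shrinkage in estimate_correlations()")
    }
  }
  if (variant == "printed") transform <- "neg_log10"
  t_vals <- switch(transform,
    chisq2 = -2 * log(p_values),
    neg_log10 = -log10(p_values)
  )
  T_stat <- sum(weights * t_vals)

  cmat <- transform_covariance(C, transform = if (variant == "printed") "chisq2" else transform)
  off <- sum(weights * (cmat %*% weights)) - sum(weights^2 * diag(cmat))
  if (variant == "matched") {
    per_var <- switch(transform, chisq2 = 4, neg_log10 = 4 / (2 * log(10))^2)
    per_mean <- switch(transform, chisq2 = 2, neg_log10 = 2 / (2 * log(10)))
    ET <- per_mean * sum(weights)
    VarT <- per_var * sum(weights^2) + off
    alpha <- ET^2 / VarT
    theta <- VarT / ET
  } else {
    # published form, taken verbatim: E(T) = sum w_i, Var(T) = 4 sum w_i^2 +
    # 2 sum_{i<j} w_i w_j C_ij, alpha = E/Var, theta = Var/E
    ET <- sum(weights)
    VarT <- 4 * sum(weights^2) + off
    alpha <- ET / VarT
    theta <- VarT / ET
  }
  p <- stats::pgamma(T_stat, shape = alpha, scale = theta, lower.tail = FALSE)
  tibble::tibble(
    gene_id = gene_id, magma_T = T_stat, magma_alpha = alpha,
    magma_theta = theta, magma_p = max(p, .Machine$double.xmin),
    variant = variant, n_snps = n
  )
}

#' Per-gene gamma-aggregated table for one study
#'
#' Applies [magma_gene_statistic()] to every gene of a SNP-to-gene mapping,
#' using per-gene correlation matrices where available and independence
#' otherwise, and merges the result with the lead-SNP table.
#'
#' @inheritParams gene_lead_table
#' @param corr named list of per-gene correlation matrices (dimnames = SNP
#'   ids), e.g. from [estimate_correlations()] on per-gene dosage blocks;
#'   genes absent from the list are treated as having independent SNPs.
#' @param ... passed to [magma_gene_statistic()].
#' @return tibble with lead-SNP and gamma-aggregation columns per gene.
#' @export
gene_magma_table <- function(snp_stats, gene_map, corr = NULL,
                             study_id = NULL, ...) {
  leads <- gene_lead_table(snp_stats, gene_map, study_id = study_id)
  p_by_snp <- setNames(snp_stats$p_value, snp_stats$snp_id)
  rows <- lapply(leads$gene_id, function(g) {
    ids <- intersect(gene_map[[g]], snp_stats$snp_id)
    Cg <- if (!is.null(corr) && g %in% names(corr)) {
      corr[[g]][ids, ids, drop = FALSE]
    } else {
      NULL
    }
    magma_gene_statistic(unname(p_by_snp[ids]), C = Cg, gene_id = g, ...)
  })
  dplyr::left_join(leads, dplyr::bind_rows(rows), by = "gene_id")
}
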