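#' @title Allele sign concordance across studies
#' @description If a locus is genuinely under sex-differential selection, the
#' same allele should be more frequent in males than in females in every
#' study. These functions polarize each SNP by the allele that is more
#' frequent in males of a designated reference study, take the sign of the
#' male-minus-female frequency difference of that allele in each study, and
#' summarise concordance both at the per-study lead SNPs (six pairwise
#' comparisons per gene) and at a single composite SNP — the SNP with the
#' highest summed LD to the three lead SNPs.
#' @name concordance
NULL

.freths <- function(ds, snp_id) {
  i <- match(snp_id, ds$counts$snp_id)
  if (is.na(i)) return(NULL)
  x <- ds$counts[i, ]
  list(
    allele_a = x$allele_a, allele_b = x$allele_b,
    male_a = x$male_count_a / (x$male_count_a + x$male_count_b),
    female_a = x$female_count_a / (x$female_count_a + x$female_count_b)
  )
}

#' Polarize a SNP by the male-more-frequent allele of a reference study
#'
#' Returns whichever allele has the strictly higher male frequency in the
#' reference study; an exact tie returns `allele_a` deterministically, with
#' the `tie` flag set.
#'
#' @param snp_id SNP identifier.
#' @param reference_study a [study_dataset()] containing the SNP.
#' @return one-row tibble: `snp_id`, `polarized_allele`, `tie`.
#' @export
polarize <- function(snp_id, reference_study) {
  f <- .freths(reference_study, snp_id)
  if (is.null(f)) {
    stop("SNP ", snp_id, " is absent from reference study ",
         reference_study$study_id)
  }
  tie <- f$male_a == 0.5
  tibble::tibble(
    snp_id = snp_id,
    polarized_allele = if (f$male_a >= 0.5) f$allele_a else f$allele_b,
    tie = tie
  )
}

#' Sign of the male-minus-female frequency difference of an allele
#'
#' @param ds a [study_dataset()].
#' @param snp_id SNP identifier.
#' @param allele which allele's frequency difference to sign (must be one of
#'   the SNP's two alleles in `ds`).
#' @return `+1`, `-1`, or `0` (exact equality); `NA` when the SNP is absent
#'   from the study.
#' @export
allele_sign <- function(ds, snp_id, allele) {
  f <- .freths(ds, snp_id)
  if (is.null(f)) return(NA_integer_)
  d <- if (allele == f$allele_a) {
    f$male_a - f$female_a
  } else if (allele == f$allele_b) {
    (1 - f$male_a) - (1 - f$female_a)
  } else {
    stop("allele ", allele, " is not one of the SNP's alleles in study ",
         ds$study_id)
  }
  as.integer(sign(d))
}

#' Six pairwise lead-SNP sign comparisons for one gene
#'
#' Each study's lead SNP is polarized by the reference study and its sign is
#' compared between the lead's own study and each of the other two studies
#' (3 leads x 2 comparisons = 6). A comparison whose SNP is missing from
#' either study involved (or from the reference) is `"untestable"`; a sign
#' of exactly zero makes the comparison discordant and is flagged.
#'
#' @param gene_id gene label for the output.
#' @param leads named character vector `study_id -> lead snp_id` (three
#'   studies).
#' @param studies named list of [study_dataset()] objects covering those
#'   study ids.
#' @param reference study id used for polarization.
#' @return tibble with one row per comparison: `gene_id`, `lead_study`,
#'   `snp_id`, `other_study`, `sign_lead`, `sign_other`, `status`
#'   (`"concordant"`, `"discordant"` or `"untestable"`), plus a
#'   `testable_comparisons` attribute.
#' @export
lead_snp_sign_concordance <- function(gene_id, leads, studies,
                                      reference = names(studies)[1]) {
  stopifnot(length(leads) == 3, !is.null(names(leads)))
  rows <- list()
  for (ls in names(leads)) {
    snp <- leads[[ls]]
    pol <- tryCatch(polarize(snp, studies[[reference]]), error = function(e) NULL)
    s_own <- if (is.null(pol)) NA_integer_ else allele_sign(studies[[ls]], snp, pol$polarized_allele)
    for (os in setdiff(names(studies), ls)) {
      s_oth <- if (is.null(pol)) NA_integer_ else allele_sign(studies[[os]], snp, pol$polarized_allele)
      status <- if (is.na(s_own) || is.na(s_oth)) {
        "untestable"
      } else if (s_own == s_oth && s_own != 0L) {
        "concordant"
      } else {
        "discordant"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id, lead_study = ls, snp_id = snp, other_study = os,
        sign_lead = s_own, sign_other = s_oth, status = status
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "testable_comparisons") <- sum(out$status != "untestable")
  out
}

#' Composite SNP: highest summed LD with the three lead SNPs
#'
#' Scores every SNP of a gene by the sum over the three leads of its LD with
#' that lead (`r^2` by default, `|r|` optionally), where each lead's LD is
#' looked up in the correlation matrix of a designated source study (so a
#' study without genotype data can borrow another study's panel). Returns
#' the argmax, ties broken by smallest position.
#'
#' @param gene_snps data frame with columns `snp_id` and `pos` listing the
#'   gene's SNPs.
#' @param leads named character vector `study_id -> lead snp_id`.
#' @param ld_matrices named list of per-study SNP correlation matrices (from
#'   [estimate_correlations()]); names are study ids.
#' @param ld_source_map named character vector mapping each lead's study to
#'   the study whose matrix supplies its LD values; defaults to each study
#'   itself.
#' @param measure `"r2"` (default) or `"abs_r"`.
#' @return the composite `snp_id`; the per-SNP scores and a coverage flag
#'   (TRUE when every lead-SNP pair was available) are attached as
#'   attributes `"scores"` and `"full_coverage"`.
#' @export
highest_sum_ld_snp <- function(gene_snps, leads, ld_matrices,
                               ld_source_map = NULL,
                               measure = c("r2", "abs_r")) {
  measure <- match.arg(measure)
  if (is.null(ld_source_map)) {
    ld_source_map <- setNames(names(leads), names(leads))
  }
  ids <- gene_snps$snp_id
  scores <- setNames(numeric(length(ids)), ids)
  covered <- TRUE
  for (ls in names(leads)) {
    M <- ld_matrices[[ld_source_map[[ls]]]]
    lead <- leads[[ls]]
    if (is.null(M) || !(lead %in% rownames(M))) {
      covered <- FALSE
      next
    }
    have <- ids %in% colnames(M)
    if (!all(have)) covered <- FALSE
    r <- M[lead, ids[have]]
    scores[ids[have]] <- scores[ids[have]] +
      if (measure == "r2") r^2 else abs(r)
  }
  ord <- order(-scores, gene_snps$pos)
  out <- ids[ord[1]]
  attr(out, "scores") <- scores
  attr(out, "full_coverage") <- covered
  out
}

#' Composite sign concordance for one gene
#'
#' Polarizes the composite SNP by the reference study and counts in how many
#' of the three studies the sign of the male-minus-female frequency
#' difference agrees with the reference study's sign (reported as k of 3;
#' the reference always agrees with itself).
#'
#' @param gene_id gene label.
#' @param composite_snp SNP id (e.g. from [highest_sum_ld_snp()]).
#' @param studies named list of three [study_dataset()] objects.
#' @param reference study id used for polarization and as the comparison
#'   baseline.
#' @return one-row tibble: `gene_id`, `composite_snp`, per-study signs (one
#'   column per study, `sign_<id>`), `concordant_studies` (k), `n_studies`.
#' @export
composite_concordance <- function(gene_id, composite_snp, studies,
                                  reference = names(studies)[1]) {
  pol <- polarize(composite_snp, studies[[reference]])
  signs <- vapply(studies, allele_sign, integer(1),
                  snp_id = composite_snp, allele = pol$polarized_allele)
  ref_sign <- signs[[reference]]
  k <- sum(!is.na(signs) & signs == ref_sign)
  out <- tibble::tibble(gene_id = gene_id, composite_snp = composite_snp)
  for (s in names(studies)) out[[paste0("sign_", s)]] <- signs[[s]]
  out$concordant_studies <- k
  out$n_studies <- length(studies)
  out
}
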