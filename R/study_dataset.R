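#' @title Sex-stratified SNP count datasets
#' @description A `study_dataset` bundles one study's per-SNP sex-stratified
#' allele (and optionally genotype) counts with the study's identifier and
#' sample sizes. The count table is an ordinary tibble with one row per
#' biallelic SNP and the columns listed under [read_count_table()]; genotype
#' columns may be absent (`NA`), in which case Hardy-Weinberg stages report
#' the SNP as not computable.
#' @name study_dataset
NULL

.count_cols_mandatory <- c(
  "snp_id", "chrom", "pos", "allele_a", "allele_b",
  "male_count_a", "male_count_b", "female_count_a", "female_count_b"
)
.count_cols_geno <- c(
  "male_n_AA", "male_n_AB", "male_n_BB",
  "female_n_AA", "female_n_AB", "female_n_BB"
)

#' Construct a study dataset
#'
#' @param counts data frame of per-SNP counts; mandatory columns `snp_id`,
#'   `chrom`, `pos`, `allele_a`, `allele_b`, `male_count_a`, `male_count_b`,
#'   `female_count_a`, `female_count_b`; optional genotype columns
#'   `male_n_AA`, `male_n_AB`, `male_n_BB` and the female equivalents.
#' @param study_id single string naming the study.
#' @param n_males,n_females numbers of sampled individuals per sex; when
#'   `NULL` they are inferred as the largest per-sex allele total divided
#'   by two.
#' @param validate check record invariants (allele/genotype consistency,
#'   biallelic sites, unique SNP ids) and fail on violations.
#' @return A `study_dataset` object (list with elements `study_id`, `counts`,
#'   `n_males`, `n_females`).
#' @examples
#' counts <- tibble::tibble(
#'   snp_id = "rs1", chrom = "1", pos = 1000L,
#'   allele_a = "A", allele_b = "C",
#'   male_count_a = 40, male_count_b = 60,
#'   female_count_a = 55, female_count_b = 45
#' )
#' study_dataset(counts, "toy")
#' @export
study_dataset <- function(counts, study_id, n_males = NULL, n_females = NULL,
                          validate = TRUE) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  counts <- tibble::as_tibble(counts)
  missing_cols <- setdiff(.count_cols_mandatory, names(counts))
  if (length(missing_cols)) {
    stop("count table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .count_cols_geno) {
    if (!col %in% names(counts)) counts[[col]] <- NA_integer_
  }
  counts <- counts[, c(.count_cols_mandatory, .count_cols_geno)]
  if (is.null(n_males)) {
    n_males <- .infer_n(counts$male_count_a + counts$male_count_b)
  }
  if (is.null(n_females)) {
    n_females <- .infer_n(counts$female_count_a + counts$female_count_b)
  }
  ds <- structure(
    list(study_id = study_id, counts = counts,
         n_males = n_males, n_females = n_females),
    class = "study_dataset"
  )
  if (validate) {
    bad <- validate_study_dataset(ds)
    if (nrow(bad)) {
      stop("invalid count record(s):\n",
           paste(sprintf("  [%s] %s", bad$snp_id, bad$problem), collapse = "\n"),
           call. = FALSE)
    }
  }
  ds
}

.infer_n <- function(allele_totals) {
  if (!length(allele_totals) || all(is.na(allele_totals))) return(NA_real_)
  max(allele_totals, na.rm = TRUE) / 2
}

#' Validate the record invariants of a study dataset
#'
#' Checks, per SNP: alleles differ (biallelic site), counts are non-negative,
#' SNP ids are unique, and — where genotype counts are present — that the
#' allele count equals `2 * n_AA + n_AB` within each sex.
#'
#' @param ds a [study_dataset()].
#' @return tibble with columns `snp_id` and `problem`; zero rows when valid.
#' @export
validate_study_dataset <- function(ds) {
  x <- ds$counts
  probs <- list()
  note <- function(idx, msg) {
    idx <- which(idx)
    if (length(idx)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        snp_id = x$snp_id[idx],
        problem = if (length(msg) == 1L) msg else msg[idx]
      )
    }
  }
  note(duplicated(x$snp_id), "duplicate snp_id within study")
  note(x$allele_a == x$allele_b, "allele_a equals allele_b (not biallelic)")
  cnt <- c("male_count_a", "male_count_b", "female_count_a", "female_count_b")
  neg <- Reduce(`|`, lapply(cnt, function(cc) !is.na(x[[cc]]) & x[[cc]] < 0))
  note(neg, "negative allele count")
  for (sex in c("male", "female")) {
    nAA <- x[[paste0(sex, "_n_AA")]]
    nAB <- x[[paste0(sex, "_n_AB")]]
    nBB <- x[[paste0(sex, "_n_BB")]]
    have <- !is.na(nAA) & !is.na(nAB) & !is.na(nBB)
    ca <- x[[paste0(sex, "_count_a")]]
    cb <- x[[paste0(sex, "_count_b")]]
    note(have & (ca != 2 * nAA + nAB),
         sprintf("%s_count_a != 2*n_AA + n_AB (expected %s)", sex, 2 * nAA + nAB))
    note(have & (cb != 2 * nBB + nAB),
         sprintf("%s_count_b != 2*n_BB + n_AB (expected %s)", sex, 2 * nBB + nAB))
    note(have & (nAA < 0 | nAB < 0 | nBB < 0),
         sprintf("negative %s genotype count", sex))
  }
  if (!length(probs)) {
    return(tibble::tibble(snp_id = character(), problem = character()))
  }
  dplyr::bind_rows(probs)
}

#' @export
print.study_dataset <- function(x, ...) {
  has_geno <- any(!is.na(x$counts$male_n_AA)) || any(!is.na(x$counts$female_n_AA))
  cat(sprintf(
    "<study_dataset> %s: %d SNPs, n_males = %s, n_females = %s, genotypes: %s\n",
    x$study_id, nrow(x$counts),
    format(x$n_males), format(x$n_females),
    if (has_geno) "present" else "absent"
  ))
  print(utils::head(x$counts, 5))
  invisible(x)
}

#' Read a sex-stratified count table
#'
#' Reads a tab-separated table with one row per biallelic SNP and a header
#' naming the columns `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`,
#' `male_count_a`, `male_count_b`, `female_count_a`, `female_count_b`, and
#' optionally `male_n_AA`, `male_n_AB`, `male_n_BB`, `female_n_AA`,
#' `female_n_AB`, `female_n_BB`. Missing mandatory columns raise a format
#' error naming the column; rows whose allele counts contradict their
#' genotype counts raise a validation error naming the SNP.
#'
#' @param path path to the TSV file.
#' @param study_id study identifier stored on the returned dataset.
#' @inheritParams study_dataset
#' @return A [study_dataset()].
#' @export
read_count_table <- function(path, study_id, n_males = NULL, n_females = NULL) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  x$chrom <- as.character(x$chrom)
  study_dataset(x, study_id, n_males = n_males, n_females = n_females)
}

#' Write a sex-stratified count table
#'
#' Inverse of [read_count_table()]: emits the tab-separated format, dropping
#' the genotype columns when no SNP carries genotype counts.
#'
#' @param ds a [study_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ds, path) {
  x <- ds$counts
  if (all(is.na(x$male_n_AA)) && all(is.na(x$female_n_AA))) {
    x <- x[, .count_cols_mandatory]
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
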