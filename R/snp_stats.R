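#' @title Per-SNP sex-difference and Hardy-Weinberg statistics
#' @description The two per-SNP tests of the scan: a Pearson chi-square test
#' (1 df, no continuity correction) on the male/female x allele-a/allele-b
#' 2x2 allele-count table, and the exact conditional test on the heterozygote
#' count for deviation from Hardy-Weinberg equilibrium, evaluated per sex.
#' All factorial arithmetic is done in log space; above a configurable cutoff
#' `ln n!` uses Ramanujan's approximation so the test scales to biobank-size
#' samples.
#' @name snp_stats
NULL

#' Chi-square test for male-female allele frequency difference
#'
#' Pearson chi-square statistic (no continuity correction) on the 2x2 table
#' of allele counts `[male_a, male_b; female_a, female_b]`, with the p-value
#' from the upper tail of the 1-df chi-square distribution. `delta_freq` is
#' the male frequency of `allele_a` minus the female frequency of `allele_a`.
#' Degenerate tables (a zero row or column sum: a monomorphic site, or one
#' sex unobserved) are flagged and returned with statistic 0 and p-value 1.
#'
#' All arguments are vectorised, so the whole scan over a study is a single
#' call (see [snp_scan()]).
#'
#' @param male_a,male_b,female_a,female_b non-negative allele counts.
#' @param snp_id optional SNP identifiers carried through to the output.
#' @return tibble with columns `snp_id`, `statistic`, `p_value`,
#'   `delta_freq`, `degenerate`.
#' @examples
#' chi_square_sex_diff(60, 40, 40, 60, snp_id = "rs1")
#' @export
chi_square_sex_diff <- function(male_a, male_b, female_a, female_b,
                                snp_id = NULL) {
  k <- length(male_a)
  stopifnot(length(male_b) == k, length(female_a) == k, length(female_b) == k)
  male_a <- as.numeric(male_a)
  male_b <- as.numeric(male_b)
  female_a <- as.numeric(female_a)
  female_b <- as.numeric(female_b)
  if (any(c(male_a, male_b, female_a, female_b) < 0, na.rm = TRUE)) {
    stop("allele counts must be non-negative")
  }
  if (is.null(snp_id)) snp_id <- paste0("snp_", seq_len(k))
  rm_ <- male_a + male_b
  rf <- female_a + female_b
  ca <- male_a + female_a
  cb <- male_b + female_b
  n <- rm_ + rf
  degenerate <- rm_ == 0 | rf == 0 | ca == 0 | cb == 0
  stat <- numeric(k)
  ok <- !degenerate
  # closed form for the 2x2 Pearson statistic: n (ad - bc)^2 / (r1 r2 c1 c2)
  stat[ok] <- n[ok] * (male_a[ok] * female_b[ok] - male_b[ok] * female_a[ok])^2 /
    (rm_[ok] * rf[ok] * ca[ok] * cb[ok])
  p <- rep(1, k)
  p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
  delta <- ifelse(rm_ > 0 & rf > 0, male_a / rm_ - female_a / rf, NA_real_)
  tibble::tibble(
    snp_id = snp_id, statistic = stat, p_value = p,
    delta_freq = delta, degenerate = degenerate
  )
}

#' Log factorial with Ramanujan large-n approximation
#'
#' Returns `ln(n!)`. Below `cutoff` the value is the exact sum of logs of the
#' integers 1..n; at or above it, Ramanujan's approximation
#' `ln n! ~ n ln n - n + ln(8n^3 + 4n^2 + n + 1/30)/6 + ln(pi)/2`
#' is used. The approximation's absolute error decays like `n^-4` (5.7e-9 at
#' n = 20, below 1e-12 past n = 500); since exact summation is essentially
#' free at these sizes, the default cutoff keeps every factorial accurate to
#' ~1e-12 while biobank-scale counts still use the closed form. Set
#' `cutoff = Inf` for fully exact summation (a cumulative table is built once
#' per call, so large vectors stay cheap).
#'
#' @param n vector of non-negative integers.
#' @param cutoff smallest n at which the approximation is used (default 500).
#' @return numeric vector of `ln(n!)` values; `log_factorial(0) = 0`.
#' @export
log_factorial <- function(n, cutoff = 500) {
  if (any(n < 0)) stop("n must be non-negative")
  n <- as.numeric(n)
  out <- numeric(length(n))
  small <- n < cutoff
  if (any(small)) {
    m <- max(n[small])
    tbl <- c(0, cumsum(log(seq_len(m))))
    out[small] <- tbl[n[small] + 1]
  }
  if (any(!small)) {
    m <- n[!small]
    out[!small] <- m * log(m) - m +
      log(8 * m^3 + 4 * m^2 + m + 1 / 30) / 6 + log(pi) / 2
  }
  out
}

#' Exact conditional distribution of the heterozygote count
#'
#' Probabilities `P(N_AB = k | N, n_A)` for every feasible heterozygote count
#' `k` (same parity as `n_A`, `0 <= k <= min(n_A, n_B)`), computed in log
#' space from
#' `P = 2^k N! / (n_AA! k! n_BB!) * n_A! n_B! / (2N)!`.
#'
#' @param n_AA,n_AB,n_BB observed genotype counts (n_AB fixes parity and the
#'   allele counts; the distribution depends only on `N` and `n_A`).
#' @param cutoff passed to [log_factorial()].
#' @return tibble with columns `k` and `prob` (unnormalised by construction;
#'   sums to 1 up to floating-point error).
#' @export
hwe_exact_distribution <- function(n_AA, n_AB, n_BB, cutoff = 500) {
  lp <- .hwe_logprobs(n_AA, n_AB, n_BB, cutoff)
  tibble::tibble(k = lp$k, prob = exp(lp$logp))
}

.hwe_logprobs <- function(n_AA, n_AB, n_BB, cutoff) {
  N <- n_AA + n_AB + n_BB
  n_A <- 2 * n_AA + n_AB
  n_B <- 2 * n_BB + n_AB
  ks <- seq.int(n_A %% 2, min(n_A, n_B), by = 2)
  lf <- function(x) log_factorial(x, cutoff = cutoff)
  logp <- ks * log(2) + lf(N) - lf((n_A - ks) / 2) - lf(ks) - lf((n_B - ks) / 2) +
    lf(n_A) + lf(n_B) - lf(2 * N)
  list(k = ks, logp = logp)
}

# stable log(sum(exp(x))), summing the small terms first
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(sort(x) - m)))
}

#' Exact test for deviation from Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count: the p-value is the sum
#' of `P(N_AB = k | N, n_A)` over all `k` whose probability is less than or
#' equal to that of the observed count (with a relative tolerance of 1e-12
#' for ties). The tail is assembled entirely in log space (log-sum-exp over
#' the selected support, smallest terms first), so deep tails at biobank
#' sample sizes do not underflow; probabilities are normalised over the
#' feasible support so the Ramanujan factorial approximation cannot push the
#' total above 1.
#'
#' @inheritParams hwe_exact_distribution
#' @param snp_id,sex optional labels carried to the output.
#' @return tibble with columns `snp_id`, `sex`, `n`, `n_A`, `n_AB`,
#'   `p_value`, `method` (`"enumeration"` below the factorial cutoff,
#'   `"ramanujan"` once any factorial uses the approximation).
#' @examples
#' exact_hwe_pvalue(88, 19, 3)
#' @export
exact_hwe_pvalue <- function(n_AA, n_AB, n_BB, cutoff = 500,
                             snp_id = NA_character_, sex = NA_character_) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be non-negative")
  N <- n_AA + n_AB + n_BB
  if (N < 1) stop("at least one individual is required")
  n_A <- 2 * n_AA + n_AB
  n_B <- 2 * n_BB + n_AB
  lp <- .hwe_logprobs(n_AA, n_AB, n_BB, cutoff)
  lnp <- lp$logp - .logsumexp(lp$logp) # normalised log probabilities
  lnp_obs <- lnp[match(n_AB, lp$k)]
  sel <- lnp <= lnp_obs + log1p(1e-12)
  p <- exp(.logsumexp(lnp[sel]))
  method <- if (max(2 * N, 1) < cutoff) "enumeration" else "ramanujan"
  tibble::tibble(
    snp_id = snp_id, sex = sex, n = N, n_A = n_A, n_AB = n_AB,
    p_value = max(min(p, 1), .Machine$double.xmin), method = method
  )
}

#' Sex-stratified exact Hardy-Weinberg tests for one SNP
#'
#' Applies [exact_hwe_pvalue()] independently to the male and the female
#' genotype counts of a count-table row. A sex whose genotype counts are
#' absent (allele counts only) is reported with `p_value = NA` and method
#' `"not_computable"`.
#'
#' @param rec single-row data frame in count-table format (see
#'   [read_count_table()]).
#' @inheritParams hwe_exact_distribution
#' @return two-row tibble (male, female) in [exact_hwe_pvalue()] format.
#' @export
sex_stratified_hwe <- function(rec, cutoff = 500) {
  stopifnot(nrow(rec) == 1)
  one <- function(sex) {
    g <- as.numeric(rec[paste0(sex, c("_n_AA", "_n_AB", "_n_BB"))])
    if (any(is.na(g))) {
      return(tibble::tibble(
        snp_id = rec$snp_id, sex = sex, n = NA_real_, n_A = NA_real_,
        n_AB = NA_real_, p_value = NA_real_, method = "not_computable"
      ))
    }
    exact_hwe_pvalue(g[1], g[2], g[3], cutoff = cutoff,
                     snp_id = rec$snp_id, sex = sex)
  }
  dplyr::bind_rows(one("male"), one("female"))
}

#' Per-SNP scan over a study dataset
#'
#' Runs [chi_square_sex_diff()] on every SNP and, where genotype counts are
#' present, the sex-stratified exact Hardy-Weinberg test. The chi-square part
#' is fully vectorised; set `hwe = FALSE` to skip the per-SNP enumeration
#' when only the frequency-difference scan is needed.
#'
#' @param ds a [study_dataset()].
#' @param hwe also compute per-sex exact HWE p-values (default FALSE).
#' @param cutoff factorial cutoff passed to [log_factorial()].
#' @return tibble with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `statistic`, `p_value`, `delta_freq`, `degenerate`, and when
#'   `hwe = TRUE` also `hwe_p_male`, `hwe_p_female`.
#' @export
snp_scan <- function(ds, hwe = FALSE, cutoff = 500) {
  x <- ds$counts
  res <- chi_square_sex_diff(x$male_count_a, x$male_count_b,
                             x$female_count_a, x$female_count_b,
                             snp_id = x$snp_id)
  res <- dplyr::bind_cols(res[, "snp_id"], x[, c("chrom", "pos")],
                          res[, c("statistic", "p_value", "delta_freq", "degenerate")])
  if (hwe) {
    hp <- function(nAA, nAB, nBB) {
      if (any(is.na(c(nAA, nAB, nBB)))) return(NA_real_)
      exact_hwe_pvalue(nAA, nAB, nBB, cutoff = cutoff)$p_value
    }
    res$hwe_p_male <- mapply(hp, x$male_n_AA, x$male_n_AB, x$male_n_BB)
    res$hwe_p_female <- mapply(hp, x$female_n_AA, x$female_n_AB, x$female_n_BB)
  }
  res
}
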