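# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# A small hand-made count table with genotype columns.
toy_counts <- function() {
  tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1500L, 2500L, 800L),
    allele_a = c("A", "G", "T"),
    allele_b = c("C", "T", "G"),
    male_count_a = c(40L, 10L, 100L),
    male_count_b = c(60L, 90L, 100L),
    female_count_a = c(55L, 12L, 90L),
    female_count_b = c(45L, 88L, 110L),
    male_n_AA = c(8L, 1L, 25L),
    male_n_AB = c(24L, 8L, 50L),
    male_n_BB = c(18L, 41L, 25L),
    female_n_AA = c(15L, 1L, 20L),
    female_n_AB = c(25L, 10L, 50L),
    female_n_BB = c(10L, 39L, 30L)
  )
}

toy_dataset <- function(study_id = "toy") {
  study_dataset(toy_counts(), study_id)
}

# Random valid count table (no genotype columns) for property tests.
random_counts <- function(n, seed = NULL, chroms = as.character(1:22)) {
  if (!is.null(seed)) set.seed(seed)
  ma <- rbinom(n, 200, 0.5)
  fa <- rbinom(n, 200, 0.5)
  tibble::tibble(
    snp_id = sprintf("s%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(1e6, n),
    allele_a = "A",
    allele_b = "C",
    male_count_a = ma,
    male_count_b = 200L - ma,
    female_count_a = fa,
    female_count_b = 200L - fa
  )
}

# Exact-HWE enumeration oracle, independent of the package implementation:
# direct lgamma-based probabilities over the feasible heterozygote support,
# normalised to machine precision, with the tail summed by a plain filter.
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  N <- n_AA + n_AB + n_BB
  nA <- 2 * n_AA + n_AB
  nB <- 2 * N - nA
  ks <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- ks * log(2) + lgamma(N + 1) - lgamma((nA - ks) / 2 + 1) -
    lgamma(ks + 1) - lgamma((nB - ks) / 2 + 1) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * N + 1)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[ks == n_AB]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# A random feasible heterozygote count given allele counts nA, nB.
.feasible_het <- function(nA, nB) {
  ks <- seq(nA %% 2, min(nA, nB), by = 2)
  ks[sample.int(length(ks), 1)]
}

# Brute-force SNP-to-gene interval assignment (strand-aware upstream window).
map_oracle <- function(counts, genes, upstream = 1000L) {
  strip <- function(x) sub("^chr", "", x)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    lo <- if (g$strand == "-") g$start else g$start - upstream
    hi <- if (g$strand == "-") g$end + upstream else g$end
    counts$snp_id[strip(counts$chrom) == strip(g$chrom) &
                    counts$pos >= lo & counts$pos <= hi]
  })
  names(out) <- genes$gene_id
  out
}
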