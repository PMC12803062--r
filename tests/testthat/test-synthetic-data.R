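test_that("scenario constructor enforces neutrality and parameter ranges", {
  expect_error(selection_scenario("none", tau_x = 0.6), "neutral")
  expect_error(selection_scenario("none", w_male = c(1, 0.9, 1)), "neutral")
  expect_error(selection_scenario("gametic", f_male = 0.2), "not defined")
  expect_error(selection_scenario("viability", w_male = c(1, 1, 2)))
  # cytoplasmic bridge sharing nullifies haplotype-level sperm selection
  sc <- selection_scenario("gametic", tau_x = 0.9, tau_y = 0.1,
                           shared_bridge = TRUE)
  expect_equal(sc$tau_x, 0.5)
  expect_equal(sc$tau_y, 0.5)
})

test_that("expected frequencies: neutral modes return the base frequency", {
  none <- selection_scenario("none")
  out <- expected_sex_freqs(none, 0.3)
  expect_equal(out$p_male, 0.3)
  expect_equal(out$p_female, 0.3)
  expect_equal(unname(out$geno_male), c(0.09, 0.42, 0.49))

  flat <- selection_scenario("viability", w_male = c(1, 1, 1) * 0.7,
                             w_female = c(0.4, 0.4, 0.4))
  out2 <- expected_sex_freqs(flat, 0.3)
  expect_equal(out2$p_male, 0.3)
  expect_equal(out2$p_female, 0.3)

  neutral_tau <- selection_scenario("gametic", tau_x = 0.5, tau_y = 0.5)
  out3 <- expected_sex_freqs(neutral_tau, 0.42)
  expect_equal(out3$p_male, 0.42)
  expect_equal(out3$p_female, 0.42)
})

test_that("viability closed form matches the one-locus post-selection formula and MC", {
  sc <- selection_scenario("viability", w_male = c(1, 1, 0.5))
  out <- expected_sex_freqs(sc, 0.5)
  # (p^2 w_AA + p q w_AB) / wbar with wbar = 0.25 + 0.5 + 0.125
  expect_equal(out$p_male, (0.25 + 0.25) / 0.875)
  expect_equal(out$p_female, 0.5)

  # direct Monte-Carlo: HWE genotypes thinned by fitness
  set.seed(89)
  # A-dosage g ~ HWE(0.5); fitnesses c(AA, AB, BB) = c(1, 1, 0.5) indexed by
  # dosage give acceptance probabilities c(0.5, 1, 1)[g + 1]
  g <- sample(0:2, 2e5, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  keep <- runif(2e5) < c(0.5, 1, 1)[g + 1]
  p_mc <- mean(g[keep]) / 2
  expect_equal(p_mc, out$p_male, tolerance = 3 * 0.5 / sqrt(sum(keep)))

  # participation bias is the same reweighting in expectation
  sp <- selection_scenario("participation", w_male = c(1, 1, 0.5))
  expect_equal(expected_sex_freqs(sp, 0.5), expected_sex_freqs(sc, 0.5))
})

test_that("gametic closed form biases each sex through its sperm class", {
  sc <- selection_scenario("gametic", tau_x = 0.55, tau_y = 0.45)
  out <- expected_sex_freqs(sc, 0.5)
  # paternal transmission p0^2 + 2 p0 q0 tau
  expect_equal(out$p_female, (0.5 + 0.25 + 0.5 * 0.55) / 2) # 0.5125
  expect_equal(out$p_male, (0.5 + 0.25 + 0.5 * 0.45) / 2)   # 0.4875
  # offspring genotype frequencies multiply the two parental streams
  pd <- 0.25 + 0.5 * 0.55
  expect_equal(unname(out$geno_female),
               c(0.5 * pd, 0.5 * (1 - pd) + 0.5 * pd, 0.5 * (1 - pd)))
})

test_that("F distortion shifts genotype but not allele frequencies", {
  sc <- selection_scenario("viability", f_male = 0.2)
  out <- expected_sex_freqs(sc, 0.4)
  expect_equal(out$p_male, 0.4) # allele frequency untouched
  expect_equal(unname(out$geno_male),
               c(0.16 + 0.2 * 0.24, 0.48 * 0.8, 0.36 + 0.2 * 0.24))
  # negative F (heterozygote excess) supported by the closed form
  sc2 <- selection_scenario("viability", f_female = -0.3)
  out2 <- expected_sex_freqs(sc2, 0.4)
  expect_equal(unname(out2$geno_female[2]), 0.48 * 1.3)

  expect_error(
    expected_sex_freqs(selection_scenario("viability", w_male = c(0, 0, 0)), 0.5)
  )
})

test_that("simulated tables satisfy every count invariant and reproduce exactly", {
  cfg <- simulation_config(n_genes = 12, snps_per_gene = 4, ld_block_rho = 0.4,
                           studies = biobank_study_presets(scale = 0.002),
                           seed = 7)
  sim <- simulate_multi_study(cfg)
  expect_named(sim$studies, c("A", "B", "C"))
  for (ds in sim$studies) {
    expect_equal(nrow(validate_study_dataset(ds)), 0)
    x <- ds$counts
    expect_true(all(x$male_count_a + x$male_count_b == 2 * ds$n_males))
    expect_true(all(x$female_count_a + x$female_count_b == 2 * ds$n_females))
  }
  # same master seed reproduces bit-for-bit; a study simulated alone matches
  sim2 <- simulate_multi_study(cfg)
  expect_identical(sim$studies$B$counts, sim2$studies$B$counts)
  solo <- simulate_study(cfg, "B")
  expect_identical(solo$counts, sim$studies$B$counts)
})

test_that("both sampling paths converge to the closed-form sex frequencies", {
  # class-count path (few SNPs) and per-individual path (many SNPs / dosages)
  for (snps in c(5, 9)) {
    cfg <- simulation_config(
      n_genes = 2, snps_per_gene = snps, ld_block_rho = 0.3,
      studies = tibble::tibble(study_id = "A", n_males = 30000L,
                               n_females = 30000L),
      scenarios = list(
        selection_scenario("viability", target_gene = "g0001",
                           target_freq = 0.5, w_male = c(1, 1, 0.5)),
        selection_scenario("gametic", target_gene = "g0002",
                           target_freq = 0.4, tau_x = 0.6, tau_y = 0.45)
      ),
      seed = 11 + snps
    )
    ds <- simulate_study(cfg, "A")
    x <- ds$counts
    freqs <- function(snp) {
      r <- x[x$snp_id == snp, ]
      c(m = r$male_count_a / (2 * ds$n_males),
        f = r$female_count_a / (2 * ds$n_females))
    }
    se <- 0.5 / sqrt(2 * 30000)

    t1 <- sprintf("g0001_s%d", ceiling(snps / 2))
    exp1 <- expected_sex_freqs(cfg$scenarios[[1]], 0.5)
    got1 <- freqs(t1)
    expect_lt(abs(got1["m"] - exp1$p_male), 4 * se)
    expect_lt(abs(got1["f"] - exp1$p_female), 4 * se)

    t2 <- sprintf("g0002_s%d", ceiling(snps / 2))
    exp2 <- expected_sex_freqs(cfg$scenarios[[2]], 0.4)
    got2 <- freqs(t2)
    expect_lt(abs(got2["m"] - exp2$p_male), 4 * se)
    expect_lt(abs(got2["f"] - exp2$p_female), 4 * se)
  }
})

test_that("null simulations are exchangeable between the sexes and calibrated", {
  cfg <- simulation_config(n_genes = 100, snps_per_gene = 8, ld_block_rho = 0.3,
                           studies = tibble::tibble(study_id = "A",
                                                    n_males = 2000L,
                                                    n_females = 2000L),
                           seed = 13)
  ds <- simulate_study(cfg, "A")
  res <- snp_scan(ds)
  # chi-square p-values approximately uniform over the 800 null SNPs
  expect_lt(max(abs(ecdf(res$p_value)(seq(0.05, 0.95, 0.05)) -
                      seq(0.05, 0.95, 0.05))), 0.06)
  expect_gt(mean(res$delta_freq > 0), 0.4)
  expect_lt(mean(res$delta_freq > 0), 0.6)
})

test_that("Hardy-Weinberg distortion in one sex is detected in that sex only", {
  cfg <- simulation_config(
    n_genes = 60, snps_per_gene = 3, ld_block_rho = 0,
    studies = tibble::tibble(study_id = "A", n_males = 1500L,
                             n_females = 1500L),
    scenarios = lapply(sprintf("g%04d", 1:30), function(g) {
      selection_scenario("viability", target_gene = g, f_male = 0.15)
    }),
    seed = 17
  )
  ds <- simulate_study(cfg, "A")
  res <- snp_scan(ds, hwe = TRUE)
  targets <- sprintf("g%04d_s2", 1:30)
  on_target <- res$snp_id %in% targets
  # males at distorted SNPs strongly reject HWE; females stay uniform
  expect_gt(mean(res$hwe_p_male[on_target] < 0.05), 0.8)
  expect_lt(mean(res$hwe_p_female[on_target] < 0.05), 0.2)
  # undistorted genes: neither sex enriched
  expect_lt(mean(res$hwe_p_male[!on_target &
                                  grepl("_s2$", res$snp_id)] < 0.05), 0.15)
})

test_that("hitchhiking at neighbours requires within-gene correlation", {
  base <- list(
    n_genes = 40, snps_per_gene = 5,
    studies = tibble::tibble(study_id = "A", n_males = 4000L,
                             n_females = 4000L),
    scenarios = lapply(sprintf("g%04d", 1:40), function(g) {
      selection_scenario("viability", target_gene = g, target_freq = 0.5,
                         w_male = c(1, 0.75, 0.5))
    })
  )
  neighbour_delta <- function(rho, seed) {
    cfg <- do.call(simulation_config,
                   c(base, list(ld_block_rho = rho, seed = seed)))
    ds <- simulate_study(cfg, "A")
    res <- snp_scan(ds)
    mean(res$delta_freq[grepl("_s2$", res$snp_id)])
  }
  d0 <- neighbour_delta(0, 19)
  d8 <- neighbour_delta(0.8, 23)
  expect_lt(abs(d0), 0.015) # no correlation, no spillover
  expect_gt(d8, 0.03)       # strong correlation drags neighbours along
})

test_that("dosage output matches counts and carries the copula correlation", {
  cfg <- simulation_config(n_genes = 3, snps_per_gene = 4, ld_block_rho = 0.6,
                           studies = tibble::tibble(study_id = "A",
                                                    n_males = 2000L,
                                                    n_females = 2000L),
                           seed = 29)
  ds <- simulate_study(cfg, "A", dosages = TRUE)
  dos <- attr(ds, "dosages")
  expect_named(dos, c("g0001", "g0002", "g0003"))
  d <- dos$g0001
  expect_equal(dim(d), c(4000L, 4L))
  # column sums reproduce the study-wide allele counts
  x <- ds$counts[ds$counts$snp_id == "g0001_s1", ]
  expect_equal(sum(d[, "g0001_s1"]), x$male_count_a + x$female_count_a)
  # neighbouring SNPs are positively correlated through the copula
  C <- estimate_correlations(d, shrinkage = 0)
  expect_gt(min(C[upper.tri(C)]), 0.15)
})

test_that("shared scenarios diverge in every study; study-specific ones in theirs only", {
  scen <- selection_scenario("viability", target_gene = "g0001",
                             target_freq = 0.5, w_male = c(1, 0.85, 0.7))
  cfg <- simulation_config(n_genes = 30, snps_per_gene = 3, ld_block_rho = 0.2,
                           studies = biobank_study_presets(scale = 0.05),
                           scenarios = list(scen), seed = 31)
  sim <- simulate_multi_study(cfg)
  expect_equal(sim$truth$mode[1], "viability")
  expect_equal(sim$truth$applies_in[1], "A,B,C")
  deltas <- sapply(sim$studies, function(ds) {
    x <- ds$counts[ds$counts$snp_id == sim$truth$target_snp[1], ]
    x$male_count_a / (2 * ds$n_males) - x$female_count_a / (2 * ds$n_females)
  })
  expect_true(all(deltas > 0.02)) # all studies share the direction

  cfg2 <- cfg
  cfg2$shared_across_studies <- FALSE
  sim2 <- simulate_multi_study(cfg2)
  expect_equal(sim2$truth$applies_in[1], "A")
  dA <- sim2$studies$A
  dB <- sim2$studies$B
  xa <- dA$counts[dA$counts$snp_id == sim2$truth$target_snp[1], ]
  xb <- dB$counts[dB$counts$snp_id == sim2$truth$target_snp[1], ]
  expect_gt(xa$male_count_a / (2 * dA$n_males) -
              xa$female_count_a / (2 * dA$n_females), 0.02)
  expect_lt(abs(xb$male_count_a / (2 * dB$n_males) -
                  xb$female_count_a / (2 * dB$n_females)), 0.02)
})

test_that("YAML configurations and on-disk simulations round-trip", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_genes: 15",
    "snps_per_gene: 4",
    "ld_block_rho: 0.2",
    "seed: 91",
    "studies:",
    "  - {study_id: A, n_males: 400, n_females: 500}",
    "  - {study_id: B, n_males: 300, n_females: 300}",
    "scenarios:",
    "  - {mode: viability, target_gene: g0001, target_freq: 0.5, w_male: [1, 0.9, 0.8]}",
    "  - {mode: gametic, target_gene: g0002, tau_x: 0.6, tau_y: 0.4, studies: [A]}"
  ), cfg_file)
  cfg <- read_simulation_config(cfg_file)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$studies$n_males, c(400L, 300L))
  expect_equal(cfg$scenarios[[2]]$tau_x, 0.6)
  expect_equal(cfg$scenarios[[2]]$studies, "A")

  ref <- simulation_config(
    n_genes = 15, snps_per_gene = 4, ld_block_rho = 0.2, seed = 91,
    studies = tibble::tibble(study_id = c("A", "B"),
                             n_males = c(400L, 300L),
                             n_females = c(500L, 300L)),
    scenarios = list(
      selection_scenario("viability", target_gene = "g0001",
                         target_freq = 0.5, w_male = c(1, 0.9, 0.8)),
      selection_scenario("gametic", target_gene = "g0002",
                         tau_x = 0.6, tau_y = 0.4, studies = "A")
    )
  )
  # identical configuration yields an identical simulation
  expect_identical(simulate_study(cfg, "A")$counts,
                   simulate_study(ref, "A")$counts)

  sim <- simulate_multi_study(cfg)
  out_dir <- withr::local_tempdir()
  write_simulation(sim, out_dir)
  expect_setequal(list.files(out_dir),
                  c("A.tsv", "B.tsv", "truth.tsv", "genes.tsv",
                    "provenance.json"))
  back <- read_count_table(file.path(out_dir, "A.tsv"), "A")
  expect_equal(as.data.frame(back$counts), as.data.frame(sim$studies$A$counts))
  truth <- utils::read.delim(file.path(out_dir, "truth.tsv"))
  expect_equal(truth$mode[1:2], c("viability", "gametic"))
  prov <- jsonlite::read_json(file.path(out_dir, "provenance.json"))
  expect_equal(prov$seed, 91L)
  expect_equal(prov$config$n_genes, 15L)
})
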