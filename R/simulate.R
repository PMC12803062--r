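#' @title Forward one-generation simulator of sex-divergence mechanisms
#' @description Generates multi-study sex-stratified count tables under four
#' mechanisms that can push male and female allele frequencies apart within
#' a single generation: `gametic` (X- vs Y-bearing sperm transmit an
#' autosomal allele at different rates), `viability` (per-sex genotype
#' fitnesses between conception and sampling), `participation` (per-sex
#' genotype-dependent sampling weights — mathematically a reweighting, like
#' viability, but representing recruitment bias), and `none`. A per-sex
#' inbreeding-like coefficient `F` additionally distorts genotype (not
#' allele) frequencies away from Hardy-Weinberg proportions. Within a gene,
#' haplotypes follow a single-factor Gaussian copula with exchangeable
#' correlation `rho`, so selection at the target SNP drags correlated
#' neighbours along (hitchhiking) and the LD-aware gene statistics have
#' structure to exploit. One generation only: divergence between autosomes
#' and sex chromosomes resets at every meiosis, so nothing accumulates.
#' @name synthetic_data
NULL

#' Describe one selection / divergence scenario
#'
#' @param mode `"none"`, `"gametic"`, `"viability"`, or `"participation"`.
#' @param target_gene gene id the scenario acts on.
#' @param target_snp SNP id selection acts on; `NULL` picks the gene's
#'   middle SNP.
#' @param target_freq base allele-A frequency pinned at the target SNP;
#'   `NULL` keeps the randomly drawn one.
#' @param tau_x,tau_y gametic mode: probability that a heterozygous father's
#'   fertilizing X-bearing (daughters) resp. Y-bearing (sons) sperm carries
#'   allele A; 0.5 is neutral.
#' @param w_male,w_female viability/participation mode: genotype weights
#'   `c(AA, AB, BB)` in `[0, 1]` per sex (relative survival or sampling
#'   probability).
#' @param f_male,f_female inbreeding-like Hardy-Weinberg distortion per sex
#'   (genotype frequencies `p^2 + Fpq`, `2pq(1-F)`, `q^2 + Fpq`); the
#'   simulator supports `F` in `[0, 1)`, [expected_sex_freqs()] any
#'   `F` in `(-1, 1)`.
#' @param studies study ids the scenario applies to; `NULL` means all
#'   studies when the configuration is shared across studies, otherwise the
#'   first study only (a study-specific artifact).
#' @param shared_bridge gametic mode: if `TRUE`, sperm share gene products
#'   through cytoplasmic bridges, so haplotype-level selection is nullified
#'   (`tau_x` and `tau_y` are forced to 0.5).
#' @return a `selection_scenario` object (list).
#' @export
selection_scenario <- function(mode = c("none", "gametic", "viability", "participation"),
                               target_gene = NA_character_, target_snp = NULL,
                               target_freq = NULL,
                               tau_x = 0.5, tau_y = 0.5,
                               w_male = c(1, 1, 1), w_female = c(1, 1, 1),
                               f_male = 0, f_female = 0,
                               studies = NULL, shared_bridge = FALSE) {
  mode <- match.arg(mode)
  stopifnot(
    tau_x >= 0, tau_x <= 1, tau_y >= 0, tau_y <= 1,
    length(w_male) == 3, length(w_female) == 3,
    all(w_male >= 0), all(w_male <= 1), all(w_female >= 0), all(w_female <= 1),
    f_male > -1, f_male < 1, f_female > -1, f_female < 1
  )
  if (shared_bridge) {
    tau_x <- 0.5
    tau_y <- 0.5
  }
  if (mode == "gametic" && (f_male != 0 || f_female != 0)) {
    stop("Hardy-Weinberg distortion F is not defined for gametic mode")
  }
  if (mode == "none") {
    neutral <- tau_x == 0.5 && tau_y == 0.5 &&
      all(w_male == w_male[1]) && all(w_female == w_female[1]) &&
      f_male == 0 && f_female == 0
    if (!neutral) stop("mode 'none' requires neutral parameters")
  }
  structure(
    list(mode = mode, target_gene = target_gene, target_snp = target_snp,
         target_freq = target_freq, tau_x = tau_x, tau_y = tau_y,
         w_male = w_male, w_female = w_female,
         f_male = f_male, f_female = f_female,
         studies = studies, shared_bridge = shared_bridge),
    class = "selection_scenario"
  )
}

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs per gene.
#' @param ld_block_rho exchangeable within-gene haplotype correlation of the
#'   Gaussian copula, in `[0, 1)`.
#' @param base_freq_range range the shared base allele-A frequencies are
#'   drawn from (uniform).
#' @param studies data frame with columns `study_id`, `n_males`,
#'   `n_females`; see [biobank_study_presets()] for biobank-proportioned
#'   defaults.
#' @param scenarios list of [selection_scenario()] objects.
#' @param shared_across_studies if `TRUE` (true sex-differential selection)
#'   scenarios without an explicit `studies` field apply in every study;
#'   if `FALSE` they apply in the first study only (artifact).
#' @param seed master seed; all per-study substreams derive from it.
#' @return a `simulation_config` object (list).
#' @export
simulation_config <- function(n_genes = 200, snps_per_gene = 8,
                              ld_block_rho = 0.3,
                              base_freq_range = c(0.05, 0.95),
                              studies = biobank_study_presets(scale = 0.01),
                              scenarios = list(),
                              shared_across_studies = TRUE,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, snps_per_gene >= 1,
    ld_block_rho >= 0, ld_block_rho < 1,
    length(base_freq_range) == 2, base_freq_range[1] > 0,
    base_freq_range[2] < 1, base_freq_range[1] <= base_freq_range[2],
    all(c("study_id", "n_males", "n_females") %in% names(studies)),
    all(studies$n_males >= 1), all(studies$n_females >= 1)
  )
  structure(
    list(n_genes = n_genes, snps_per_gene = snps_per_gene,
         ld_block_rho = ld_block_rho, base_freq_range = base_freq_range,
         studies = tibble::as_tibble(studies), scenarios = scenarios,
         shared_across_studies = shared_across_studies,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Study sample-size presets proportioned like the three biobank cohorts
#'
#' Full-scale sizes: 186,936/220,062 (males/females, study A), 79,983/124,205
#' (study B), 14,343/19,686 (study C). `scale` shrinks them proportionally
#' for desk-scale simulation.
#'
#' @param scale multiplicative factor applied to every sample size.
#' @param study_ids labels for the three studies.
#' @return tibble with `study_id`, `n_males`, `n_females`.
#' @export
biobank_study_presets <- function(scale = 1, study_ids = c("A", "B", "C")) {
  tibble::tibble(
    study_id = study_ids,
    n_males = pmax(1L, as.integer(round(c(186936, 79983, 14343) * scale))),
    n_females = pmax(1L, as.integer(round(c(220062, 124205, 19686) * scale)))
  )
}

#' Expected post-selection sex-specific frequencies (closed form)
#'
#' Deterministic expectations against which the simulator converges.
#' Gametic mode: mothers transmit allele A with probability `p0`; fathers
#' with probability `p0^2 + 2 p0 q0 tau` (tau = `tau_x` for daughters,
#' `tau_y` for sons), and offspring genotype frequencies are products of the
#' two independent parental transmission probabilities. Viability and
#' participation modes: per-sex genotype frequencies start at Hardy-Weinberg
#' proportions (optionally F-distorted), are multiplied by the genotype
#' weights and renormalised by the mean weight; the allele frequency is
#' `f_AA + f_AB / 2`.
#'
#' @param scenario a [selection_scenario()].
#' @param p0 base allele-A frequency in (0, 1).
#' @return list with `p_male`, `p_female`, `geno_male`, `geno_female`
#'   (genotype frequency vectors `c(AA, AB, BB)`).
#' @examples
#' sc <- selection_scenario("viability", w_male = c(1, 1, 0.5))
#' expected_sex_freqs(sc, 0.5)
#' @export
expected_sex_freqs <- function(scenario, p0) {
  stopifnot(p0 > 0, p0 < 1)
  q0 <- 1 - p0
  hwe_f <- function(f) {
    c(AA = p0^2 + f * p0 * q0, AB = 2 * p0 * q0 * (1 - f), BB = q0^2 + f * p0 * q0)
  }
  if (scenario$mode == "gametic") {
    cross <- function(tau) {
      pd <- p0^2 + 2 * p0 * q0 * tau # paternal transmission of A
      list(p = (p0 + pd) / 2,
           geno = c(AA = p0 * pd, AB = p0 * (1 - pd) + q0 * pd, BB = q0 * (1 - pd)))
    }
    daughters <- cross(scenario$tau_x)
    sons <- cross(scenario$tau_y)
    return(list(p_male = sons$p, p_female = daughters$p,
                geno_male = sons$geno, geno_female = daughters$geno))
  }
  post <- function(w, f) {
    g <- hwe_f(f) * w
    if (sum(g) <= 0) stop("degenerate selection weights (all zero)")
    g / sum(g)
  }
  gm <- post(scenario$w_male, scenario$f_male)
  gf <- post(scenario$w_female, scenario$f_female)
  list(p_male = unname(gm[1] + gm[2] / 2), p_female = unname(gf[1] + gf[2] / 2),
       geno_male = gm, geno_female = gf)
}

# Deterministic gene/SNP layout shared by all studies of a configuration:
# genes round-robin over autosomes 1-22, SNPs 1 kb apart inside the body.
.sim_layout <- function(config) {
  ng <- config$n_genes
  S <- config$snps_per_gene
  gene_id <- sprintf("g%04d", seq_len(ng))
  chrom <- as.character(((seq_len(ng) - 1) %% 22) + 1)
  slot <- (seq_len(ng) - 1) %/% 22
  start <- 1e5 + slot * (S + 10) * 1000
  end <- start + S * 1000 + 500
  genes <- tibble::tibble(gene_id = gene_id, chrom = chrom,
                          start = as.integer(start), end = as.integer(end),
                          strand = "+")
  gene_rep <- rep(gene_id, each = S)
  snp_no <- rep(seq_len(S), ng)
  snps <- tibble::tibble(
    gene_id = gene_rep,
    snp_id = paste0(gene_rep, "_s", snp_no),
    chrom = rep(chrom, each = S),
    pos = as.integer(rep(start, each = S) + 500 + (snp_no - 1) * 1000)
  )
  set.seed(config$seed)
  snps$base_freq <- stats::runif(nrow(snps), config$base_freq_range[1],
                                 config$base_freq_range[2])
  study_seeds <- sample.int(.Machine$integer.max - 1, nrow(config$studies))
  # resolve scenario targets and pin target frequencies
  scen <- lapply(config$scenarios, function(sc) {
    if (is.na(sc$target_gene) || !sc$target_gene %in% gene_id) {
      stop("scenario target gene ", sc$target_gene, " is not in the layout")
    }
    if (is.null(sc$target_snp)) {
      ids <- snps$snp_id[snps$gene_id == sc$target_gene]
      sc$target_snp <- ids[ceiling(length(ids) / 2)]
    }
    if (is.null(sc$studies)) {
      sc$studies <- if (config$shared_across_studies) {
        config$studies$study_id
      } else {
        config$studies$study_id[1]
      }
    }
    sc
  })
  for (sc in scen) {
    if (!is.null(sc$target_freq)) {
      snps$base_freq[snps$snp_id == sc$target_snp] <- sc$target_freq
    }
  }
  list(genes = genes, snps = snps, scenarios = scen, study_seeds = study_seeds)
}

# ---- class-count sampling path -------------------------------------------
# Conditional on its factor W, a haplotype's alleles are independent across
# SNPs, so the distribution over the 2^S haplotype classes is the 1-D
# integral  P(h) = E_W prod_j pi_j(W)^h_j (1-pi_j(W))^(1-h_j),  evaluated by
# Gauss-Hermite quadrature. Individuals are haplotype pairs, so per-SNP
# genotype counts follow a multinomial over the K^2 pair cells — sampled
# directly, without simulating individuals. Selection reweights the cells:
# genotype weights at the target SNP (viability/participation), an IBD
# mixture (F), or the tau-biased paternal transmission law (gametic). This
# is the same model as the per-individual kernel, just marginalised; it is
# used whenever 2^S is small and no dosage matrix is requested.
.sim_cache <- new.env(parent = emptyenv())

.gh_rule <- function(order = 48) {
  key <- paste0("gh", order)
  if (is.null(.sim_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    .sim_cache[[key]] <- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .sim_cache[[key]]
}

.hap_classes <- function(S) {
  key <- paste0("S", S)
  if (is.null(.sim_cache[[key]])) {
    H <- as.matrix(expand.grid(rep(list(0:1), S)))
    dimnames(H) <- NULL
    K <- nrow(H)
    i1 <- rep(seq_len(K), times = K)
    i2 <- rep(seq_len(K), each = K)
    G <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE] # A-dosage per pair cell
    .sim_cache[[key]] <- list(
      H = H, i1 = i1, i2 = i2, diag = i1 == i2, G = G,
      M0 = (G == 0) + 0, M1 = (G == 1) + 0, M2 = (G == 2) + 0
    )
  }
  .sim_cache[[key]]
}

.class_probs <- function(p0, rho, cls) {
  gh <- .gh_rule()
  th <- stats::qnorm(p0)
  if (rho == 0) {
    pi_ <- matrix(p0, ncol = 1)
    wgt <- 1
  } else {
    pi_ <- stats::pnorm((outer(th, sqrt(rho) * gh$z, `-`)) / sqrt(1 - rho))
    wgt <- gh$w
  }
  pi_ <- pmin(pmax(pi_, 1e-300), 1 - 1e-16)
  logM <- cls$H %*% log(pi_) + (1 - cls$H) %*% log1p(-pi_)
  P <- as.vector(exp(logM) %*% wgt)
  P / sum(P)
}

.sim_gene_classes <- function(n, p0, rho, sc, sex) {
  S <- length(p0)
  cls <- .hap_classes(S)
  P <- .class_probs(p0, rho, cls)
  t_idx <- if (is.null(sc)) 1L else match(sc$target_snp, names(p0))
  mode <- if (is.null(sc)) "none" else sc$mode
  if (mode == "gametic") {
    tau <- if (sex == "male") sc$tau_y else sc$tau_x
    pt <- sum(P[cls$H[, t_idx] == 1])
    trans_w <- ifelse(cls$H[, t_idx] == 1,
                      2 * (pt / 2 + (1 - pt) * tau),
                      2 * ((1 - pt) / 2 + pt * (1 - tau)))
    Ptrans <- P * trans_w
    cellp <- P[cls$i1] * Ptrans[cls$i2]
  } else {
    f <- if (is.null(sc)) 0 else if (sex == "male") sc$f_male else sc$f_female
    cellp <- (1 - f) * P[cls$i1] * P[cls$i2]
    if (f > 0) cellp[cls$diag] <- cellp[cls$diag] + f * P
    if (mode %in% c("viability", "participation")) {
      w <- if (sex == "male") sc$w_male else sc$w_female
      w_dos <- rev(w) # index by A-dosage: BB, AB, AA
      if (all(w_dos == 0)) stop("degenerate selection weights (all zero)")
      cellp <- cellp * w_dos[cls$G[, t_idx] + 1L]
    }
  }
  cnt <- stats::rmultinom(1, n, cellp)[, 1]
  counts <- rbind(as.vector(cnt %*% cls$M2),
                  as.vector(cnt %*% cls$M1),
                  as.vector(cnt %*% cls$M0))
  storage.mode(counts) <- "integer"
  list(counts = counts)
}

# Simulate one gene x one sex; returns 3 x S genotype counts (+ dosages).
# Dispatches to the marginalised class sampler when the class space is small
# and no per-individual dosages are needed; otherwise to the per-individual
# C++ kernel.
.sim_gene_sex <- function(n, p0, rho, sc, sex, want_dosages) {
  if (!want_dosages && length(p0) <= 8) {
    return(.sim_gene_classes(n, p0, rho, sc, sex))
  }
  .sim_gene_individuals(n, p0, rho, sc, sex, want_dosages)
}

.sim_gene_individuals <- function(n, p0, rho, sc, sex, want_dosages) {
  thresh <- stats::qnorm(p0)
  target <- if (is.null(sc)) 1L else match(sc$target_snp, names(p0))
  if (is.null(sc) || sc$mode == "none") {
    f <- if (is.null(sc)) 0 else if (sex == "male") sc$f_male else sc$f_female
    return(sim_gene_counts_cpp(n, thresh, rho, 0L, f, c(1, 1, 1), 0.5,
                               target - 1L, want_dosages))
  }
  if (sc$mode == "gametic") {
    tau <- if (sex == "male") sc$tau_y else sc$tau_x
    return(sim_gene_counts_cpp(n, thresh, rho, 2L, 0, c(1, 1, 1), tau,
                               target - 1L, want_dosages))
  }
  w <- if (sex == "male") sc$w_male else sc$w_female
  f <- if (sex == "male") sc$f_male else sc$f_female
  # kernel weights are indexed by A-allele dosage (BB, AB, AA)
  sim_gene_counts_cpp(n, thresh, rho, 1L, f, rev(w), 0.5,
                      target - 1L, want_dosages)
}

#' Simulate one study's count table
#'
#' Generates the sex-stratified allele and genotype counts of every SNP of
#' the configuration for one study, applying each scenario that is active in
#' that study. The layout (gene/SNP coordinates, shared base frequencies)
#' and the study's RNG substream are both derived deterministically from
#' `config$seed`, so studies can be simulated independently and reproduce
#' [simulate_multi_study()] exactly.
#'
#' @param config a [simulation_config()].
#' @param study study id (must appear in `config$studies`).
#' @param dosages also return per-gene A-allele dosage matrices
#'   (individuals x SNPs, males stacked above females) for LD estimation.
#' @return a [study_dataset()]; when `dosages = TRUE` the named list of
#'   dosage matrices is attached as attribute `"dosages"`.
#' @export
simulate_study <- function(config, study, dosages = FALSE) {
  layout <- .sim_layout(config)
  si <- match(study, config$studies$study_id)
  if (is.na(si)) stop("unknown study id: ", study)
  set.seed(layout$study_seeds[si])
  n_m <- config$studies$n_males[si]
  n_f <- config$studies$n_females[si]
  scen_by_gene <- list()
  for (sc in layout$scenarios) {
    if (study %in% sc$studies) scen_by_gene[[sc$target_gene]] <- sc
  }
  snps <- layout$snps
  gene_ids <- layout$genes$gene_id
  idx_by_gene <- split(seq_len(nrow(snps)), snps$gene_id)[gene_ids]
  dos_list <- if (dosages) setNames(vector("list", length(gene_ids)), gene_ids)
  geno <- matrix(0L, nrow = nrow(snps), ncol = 6,
                 dimnames = list(NULL, c("male_n_AA", "male_n_AB", "male_n_BB",
                                         "female_n_AA", "female_n_AB", "female_n_BB")))
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    idx <- idx_by_gene[[gi]]
    p0 <- setNames(snps$base_freq[idx], snps$snp_id[idx])
    sc <- scen_by_gene[[g]]
    m <- .sim_gene_sex(n_m, p0, config$ld_block_rho, sc, "male", dosages)
    f <- .sim_gene_sex(n_f, p0, config$ld_block_rho, sc, "female", dosages)
    geno[idx, 1:3] <- t(m$counts)
    geno[idx, 4:6] <- t(f$counts)
    if (dosages) {
      d <- rbind(m$dosages, f$dosages)
      colnames(d) <- snps$snp_id[idx]
      dos_list[[g]] <- d
    }
  }
  counts <- tibble::tibble(
    snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
    allele_a = "A", allele_b = "C",
    male_count_a = 2L * geno[, 1] + geno[, 2],
    male_count_b = 2L * geno[, 3] + geno[, 2],
    female_count_a = 2L * geno[, 4] + geno[, 5],
    female_count_b = 2L * geno[, 6] + geno[, 5],
    male_n_AA = geno[, 1], male_n_AB = geno[, 2], male_n_BB = geno[, 3],
    female_n_AA = geno[, 4], female_n_AB = geno[, 5], female_n_BB = geno[, 6]
  )
  ds <- study_dataset(counts, study,
                      n_males = n_m, n_females = n_f, validate = FALSE)
  if (dosages) attr(ds, "dosages") <- dos_list
  ds
}

#' Simulate all studies of a configuration, with a truth table
#'
#' @inheritParams simulate_study
#' @return list with `studies` (named list of [study_dataset()]s), `genes`
#'   (annotation tibble usable with [map_snps_to_genes()]), `snps` (layout
#'   incl. shared base frequencies), and `truth` (one row per gene:
#'   `gene_id`, `mode`, `target_snp`, `applies_in`).
#' @export
simulate_multi_study <- function(config, dosages = FALSE) {
  layout <- .sim_layout(config)
  studies <- lapply(config$studies$study_id, function(s) {
    simulate_study(config, s, dosages = dosages)
  })
  names(studies) <- config$studies$study_id
  truth <- tibble::tibble(
    gene_id = layout$genes$gene_id, mode = "none",
    target_snp = NA_character_, applies_in = NA_character_
  )
  for (sc in layout$scenarios) {
    i <- match(sc$target_gene, truth$gene_id)
    truth$mode[i] <- sc$mode
    truth$target_snp[i] <- sc$target_snp
    truth$applies_in[i] <- paste(sc$studies, collapse = ",")
  }
  list(studies = studies, genes = layout$genes, snps = layout$snps,
       truth = truth, config = config)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the arguments of [simulation_config()]: scalar fields at
#' the top level, `studies` as a list of `{study_id, n_males, n_females}`
#' records, and `scenarios` as a list of records whose fields are the
#' arguments of [selection_scenario()].
#'
#' @param path YAML file.
#' @return a [simulation_config()].
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "n_genes: 10", "snps_per_gene: 4", "ld_block_rho: 0.2", "seed: 3",
#'   "studies:",
#'   "  - {study_id: A, n_males: 500, n_females: 500}",
#'   "scenarios:",
#'   "  - {mode: viability, target_gene: g0001, w_male: [1, 0.9, 0.8]}"
#' ), cfg_file)
#' read_simulation_config(cfg_file)
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen <- lapply(y$scenarios, function(s) {
    for (f in c("w_male", "w_female")) {
      if (!is.null(s[[f]])) s[[f]] <- as.numeric(unlist(s[[f]]))
    }
    if (!is.null(s$studies)) s$studies <- as.character(unlist(s$studies))
    do.call(selection_scenario, s)
  })
  args <- y[setdiff(names(y), c("scenarios", "studies"))]
  if (!is.null(y$studies)) {
    args$studies <- dplyr::bind_rows(lapply(y$studies, tibble::as_tibble))
  }
  args$scenarios <- scen
  do.call(simulation_config, args)
}

#' Write a multi-study simulation to disk
#'
#' Emits one count-table TSV per study, the truth table (`truth.tsv`), the
#' gene annotations (`genes.tsv`), and a provenance record
#' (`provenance.json`) holding the seed and the full configuration, which is
#' sufficient to regenerate the simulation exactly.
#'
#' @param sim result of [simulate_multi_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$studies)) {
    write_count_table(sim$studies[[s]], file.path(dir, paste0(s, ".tsv")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  prov <- list(
    package = "sdscan",
    version = as.character(utils::packageVersion("sdscan")),
    seed = cfg$seed,
    config = list(
      n_genes = cfg$n_genes, snps_per_gene = cfg$snps_per_gene,
      ld_block_rho = cfg$ld_block_rho, base_freq_range = cfg$base_freq_range,
      studies = cfg$studies, shared_across_studies = cfg$shared_across_studies,
      scenarios = lapply(cfg$scenarios, unclass)
    )
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
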