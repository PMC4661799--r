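one_frag_cfg <- function(L = 5000L, theta = 0.003, seed = 1L, ...) {
  sim_config(fragments = data.frame(name = "FR", length = L),
             theta_per_site = theta, seed = seed, ...)
}

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_dams = 0), "positive")
  expect_error(sim_config(h2_polygenic = 1), "h2_polygenic")
  expect_error(one_frag_cfg(L = 0L), "positive")
  expect_error(sim_config(depth_model = list(grand = 100, ind_sd = -1,
                                             frag_sd = 1, resid_sd = 1,
                                             taper_width = 0,
                                             base_cv = 0)), "SD")
})

test_that("founder pool: no mutation, determinism, segregating sites", {
  cfg0 <- one_frag_cfg(theta = 0, seed = 4)
  fp0 <- simulate_founder_haplotypes(cfg0)
  expect_equal(ncol(fp0$fragments$FR$haps), 0L)

  fp_a <- simulate_founder_haplotypes(one_frag_cfg(seed = 9))
  fp_b <- simulate_founder_haplotypes(one_frag_cfg(seed = 9))
  expect_identical(fp_a, fp_b)

  # Watterson expectation: mean S over replicates within 3 SE of
  # theta * L * a_n, a_n computed by direct summation (n = 82 haplotypes)
  n_h <- 2L * (12L + 29L)
  a_n <- sum(1 / seq_len(n_h - 1L))
  expected <- 0.003 * 5000 * a_n
  S <- vapply(seq_len(200), function(r) {
    fp <- simulate_founder_haplotypes(one_frag_cfg(seed = 1000L + r))
    length(fp$fragments$FR$pos)
  }, numeric(1))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("neutral founder pools have mean Tajima's D near zero", {
  D <- vapply(seq_len(200), function(r) {
    cfg <- sim_config(n_dams = 8L, n_sires = 12L,
                      fragments = data.frame(name = "FR", length = 2000L),
                      theta_per_site = 0.004, div_prop = 0,
                      seed = 5000L + r)
    fp <- simulate_founder_haplotypes(cfg)
    h <- fp$fragments$FR$haps
    if (ncol(h) == 0) return(NA_real_)
    tajimas_d(h)
  }, numeric(1))
  D <- D[!is.na(D)]
  expect_gt(length(D), 150)
  expect_lt(abs(mean(D)), 3 * stats::sd(D) / sqrt(length(D)))
})

test_that("mass cross: gametes, monomorphic sites, empty cohort", {
  cfg <- one_frag_cfg(seed = 21, n_offspring = 25L)
  cfg$recomb_per_bp <- 0
  fp <- simulate_founder_haplotypes(cfg)
  cr <- simulate_mass_cross(fp, cfg)
  # with no recombination every gamete is an intact parental haplotype
  fr <- fp$fragments$FR
  for (i in seq_len(5)) {
    off <- cr$pedigree$offspring[i]
    g1 <- cr$haplotypes$FR[paste0(off, "_1"), ]
    dam <- cr$pedigree$dam[i]
    expect_true(identical(g1, fr$haps[paste0(dam, "_1"), ]) ||
                  identical(g1, fr$haps[paste0(dam, "_2"), ]))
  }
  # offspring alleles always drawn from the recorded parents' haplotypes
  cfg2 <- one_frag_cfg(seed = 22, n_offspring = 30L)
  fp2 <- simulate_founder_haplotypes(cfg2)
  cr2 <- simulate_mass_cross(fp2, cfg2)
  fr2 <- fp2$fragments$FR
  for (i in seq_len(cfg2$n_offspring)) {
    for (p in 1:2) {
      par <- cr2$pedigree[[c("dam", "sire")[p]]][i]
      gam <- cr2$haplotypes$FR[paste0(cr2$pedigree$offspring[i], "_", p), ]
      ok <- gam == fr2$haps[paste0(par, "_1"), ] |
        gam == fr2$haps[paste0(par, "_2"), ]
      expect_true(all(ok))
    }
  }
  # monomorphic founder site stays monomorphic
  fp3 <- fp2
  fp3$fragments$FR$haps[, 1] <- 0L
  cr3 <- simulate_mass_cross(fp3, cfg2)
  expect_true(all(cr3$genotypes$geno[, 1] == 0L))
  # empty cohort is fine
  cfg0 <- one_frag_cfg(seed = 2, n_offspring = 0L)
  cr0 <- simulate_mass_cross(simulate_founder_haplotypes(cfg0), cfg0)
  expect_equal(nrow(cr0$genotypes$geno), 0L)
})

test_that("full sibs show ~0.25 genomic kinship against founder freqs", {
  # covariance identity: E[(x_i - p)(x_j - p)] = f_ij p(1-p) with x the
  # individual allele frequency and p the founder-pool frequency
  est <- c(); truth <- c()
  for (r in 1:10) {
    cfg <- one_frag_cfg(seed = 300L + r, n_offspring = 60L)
    fp <- simulate_founder_haplotypes(cfg)
    cr <- simulate_mass_cross(fp, cfg)
    p <- colMeans(fp$fragments$FR$haps)
    keep <- p > 0.05 & p < 0.95
    x <- cr$genotypes$geno[, keep, drop = FALSE] / 2
    pk <- p[keep]
    P <- pedigree_kinship(cr$pedigree)
    for (i in 1:20) for (j in (i + 1):21) {
      f_hat <- sum((x[i, ] - pk) * (x[j, ] - pk)) / sum(pk * (1 - pk))
      est <- c(est, f_hat); truth <- c(truth, P[i, j])
    }
  }
  fs <- truth == 0.25
  un <- truth == 0
  expect_gt(sum(fs), 5)
  se <- stats::sd(est[fs]) / sqrt(sum(fs))
  expect_lt(abs(mean(est[fs]) - 0.25), 3 * se + 0.02)
  expect_lt(abs(mean(est[un])), 3 * stats::sd(est[un]) / sqrt(sum(un)) + 0.02)
})

test_that("phenotypes: null settings, slope recovery, d/a boundary", {
  # a = d = 0, h2 = 0, no structure: SL is iid noise around its mean
  cfg <- one_frag_cfg(seed = 31, n_offspring = 400L)
  cfg$qtl$a <- 0; cfg$qtl$d <- 0
  cfg$h2_polygenic <- 0; cfg$struct_shift <- 0
  fp <- simulate_founder_haplotypes(cfg)
  cr <- simulate_mass_cross(fp, cfg)
  ph <- simulate_phenotypes(cr$genotypes, pedigree_kinship(cr$pedigree),
                            cfg, cr$ancestry)
  expect_equal(ph$truth$realized_r2, 0)
  expect_lt(abs(stats::sd(ph$phenotypes$SL) - cfg$sigma_env), 0.2)

  # additive-only QTL: OLS slope on the QTL genotype recovers a
  cfg2 <- one_frag_cfg(seed = 32, n_offspring = 800L)
  cfg2$qtl$a <- 1.2; cfg2$qtl$d <- 0
  cfg2$h2_polygenic <- 0; cfg2$struct_shift <- 0; cfg2$assort <- 0
  fp2 <- simulate_founder_haplotypes(cfg2)
  cr2 <- simulate_mass_cross(fp2, cfg2)
  ph2 <- simulate_phenotypes(cr2$genotypes, pedigree_kinship(cr2$pedigree),
                             cfg2, cr2$ancestry)
  x <- cr2$genotypes$geno[, ph2$truth$qtl_index]
  fit <- stats::lm(ph2$truth$latent ~ x)
  se <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(stats::coef(fit)["x"] - 1.2), 3 * se)
  ga <- gene_action(mean(ph2$truth$latent[x == 0]),
                    mean(ph2$truth$latent[x == 1]),
                    mean(ph2$truth$latent[x == 2]))
  expect_lt(abs(ga$d_over_a), 0.25)

  # d = a/2 lands near the additive/dominance boundary
  cfg3 <- one_frag_cfg(seed = 33, n_offspring = 2000L)
  cfg3$qtl$a <- 1; cfg3$qtl$d <- 0.5
  cfg3$h2_polygenic <- 0; cfg3$struct_shift <- 0; cfg3$sigma_env <- 0.3
  fp3 <- simulate_founder_haplotypes(cfg3)
  cr3 <- simulate_mass_cross(fp3, cfg3)
  ph3 <- simulate_phenotypes(cr3$genotypes, pedigree_kinship(cr3$pedigree),
                             cfg3, cr3$ancestry)
  x3 <- cr3$genotypes$geno[, ph3$truth$qtl_index]
  ga3 <- gene_action(mean(ph3$phenotypes$SL[x3 == 0]),
                     mean(ph3$phenotypes$SL[x3 == 1]),
                     mean(ph3$phenotypes$SL[x3 == 2]))
  expect_lt(abs(abs(ga3$d_over_a) - 0.5), 0.1)
})

test_that("depth profiles: degenerate settings and variance structure", {
  dm0 <- list(grand = 80, ind_sd = 0, frag_sd = 0, resid_sd = 0,
              taper_width = 0L, base_cv = 0)
  cfg <- sim_config(n_offspring = 12L,
                    fragments = data.frame(name = c("A", "B"),
                                           length = c(150L, 120L)),
                    depth_model = dm0, seed = 3)
  dp <- simulate_depth_profiles(cfg)
  expect_true(all(abs(dp$means - 80) < 1e-9))
  expect_true(all(dp$depths$A == dp$depths$A[1, 1]))  # flat profile

  # fragment/individual variance-component ratio recovered by two-way
  # ANOVA (method of moments) on the log-scale amplicon means
  ratio <- replicate(40, {
    s <- sample.int(1e6, 1)
    cfgv <- sim_config(n_offspring = 60L,
                       fragments = data.frame(name = paste0("F", 1:4),
                                              length = rep(100L, 4)),
                       depth_model = list(grand = 110, ind_sd = 0.35,
                                          frag_sd = 0.565, resid_sd = 0.25,
                                          taper_width = 0L, base_cv = 0),
                       seed = s)
    dpv <- simulate_depth_profiles(cfgv)
    st <- data.frame(individual = rep(rownames(dpv$means), 4),
                     fragment = rep(colnames(dpv$means), each = 60),
                     mean_depth = log(as.vector(dpv$means)),
                     sensitivity = NA)
    vc <- anova_variance_components(two_way_anova(st, "mean_depth"))
    c(vc["sigma2_fragment"], vc["sigma2_individual"])
  })
  r_hat <- mean(ratio[1, ]) / mean(ratio[2, ])
  expect_lt(abs(r_hat - (0.565 / 0.35)^2), 0.8)
  expect_error(sim_config(depth_model = list(grand = 1, ind_sd = 0,
                                             frag_sd = -0.1, resid_sd = 0,
                                             taper_width = 0,
                                             base_cv = 0)), "SD")
})

test_that("dataset writing round-trips and is byte-reproducible", {
  cfg <- sim_config(n_offspring = 20L, seed = 77,
                    fragments = data.frame(name = c("FA", "FB"),
                                           length = c(1500L, 1200L)))
  ds <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(ds, d1)
  rd <- read_dataset(d1)
  expect_identical(unname(rd$genotypes$geno), unname(ds$genotypes$geno))
  expect_equal(rd$genotypes$sites$pos, ds$genotypes$sites$pos)
  expect_identical(unname(rd$depths$depths$FA),
                   unname(ds$depths$depths$FA))
  # VCF positions 1-based sorted within contig
  vcf_lines <- readLines(file.path(d1, "genotypes.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  chrom <- vapply(strsplit(body, "\t"), `[`, "", 1)
  expect_true(all(pos >= 1))
  expect_true(all(unlist(tapply(pos, chrom, diff)) > 0))
  # truth JSON records the seed; rerunning from it reproduces the files
  expect_equal(rd$truth$seed, 77)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in c("genotypes.vcf", "phenotypes.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_error(write_dataset(ds, file.path("/proc/no/way")), "directory")
})
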