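test_that("amplicon stats match direct counting", {
  dp <- structure(list(depths = list(F1 = matrix(c(12, 12, 5, 20), 1)),
                       means = matrix(12.25, 1, 1,
                                      dimnames = list("I1", "F1")),
                       fragments = data.frame(name = "F1", length = 4L)),
                  class = "depth_profile")
  rownames(dp$depths$F1) <- "I1"
  st <- compute_amplicon_stats(dp, min_depth = 10)
  expect_equal(st$mean_depth, 12.25)
  expect_equal(st$sensitivity, 0.75)

  dp$depths$F1[] <- 0
  st0 <- compute_amplicon_stats(dp)
  expect_equal(st0$mean_depth, 0); expect_equal(st0$sensitivity, 0)

  dp$depths$F1[] <- c(10, 11, 300, 10)
  expect_equal(compute_amplicon_stats(dp)$sensitivity, 1)

  dp$depths$F1 <- dp$depths$F1[, 0, drop = FALSE]
  expect_error(compute_amplicon_stats(dp), "zero length")
})

test_that("genotype calls follow the closed 10-90% variant-read band", {
  expect_equal(classify_genotype(5, 10), 1L)     # 50% het
  expect_equal(classify_genotype(19, 20), 2L)    # 95% hom-alt
  expect_equal(classify_genotype(0, 30), 0L)
  expect_equal(classify_genotype(1, 10), 1L)     # boundary 10% inclusive
  expect_equal(classify_genotype(9, 10), 1L)     # boundary 90% inclusive
  expect_equal(classify_genotype(c(2, 28), c(30, 30)), c(0L, 2L))
  expect_error(classify_genotype(5, 0), ">= 1")
  expect_error(classify_genotype(11, 10), "exceeds")
})

# construct a minimal VCF-like input for filter_variants
toy_vcf <- function(geno, qual = 60, mq = 60, bq = 30, indel = FALSE,
                    dp = NULL, ad = NULL) {
  m <- ncol(geno); n <- nrow(geno)
  gm <- toy_genotypes(geno)
  list(genotypes = gm,
       records = cbind(gm$sites,
                       data.frame(qual = rep_len(qual, m),
                                  mq = rep_len(mq, m),
                                  bq = rep_len(bq, m),
                                  is_indel = rep_len(indel, m))),
       dp = dp %||% matrix(50L, n, m),
       ad_alt = ad)
}

test_that("site-level quality criteria reject whole records", {
  g <- rbind(c(0L, 1L), c(1L, 2L))
  expect_equal(filter_variants(toy_vcf(g, bq = c(19, 30)))$n_dropped_sites, 1)
  expect_equal(filter_variants(toy_vcf(g, bq = c(20, 30)))$n_dropped_sites, 0)
  expect_equal(filter_variants(toy_vcf(g, mq = c(30, 19)))$n_dropped_sites, 1)
  expect_equal(filter_variants(toy_vcf(g, qual = 19.9))$n_dropped_sites, 2)
  fv <- filter_variants(toy_vcf(g, indel = c(TRUE, FALSE)))
  expect_equal(fv$log$reason[1], "indel")
  expect_equal(ncol(fv$genotypes$geno), 1L)
})

test_that("depth criterion masks per genotype, not per site", {
  g <- rbind(c(1L, 1L), c(0L, 2L), c(2L, 0L))
  dp <- rbind(c(9L, 40L), c(40L, 40L), c(40L, 40L))
  fv <- filter_variants(toy_vcf(g, dp = dp))
  expect_equal(fv$n_masked_genotypes, 1)
  expect_true(is.na(fv$genotypes$geno[1, 1]))
  expect_equal(fv$genotypes$geno[2, 1], 0L)
  expect_equal(ncol(fv$genotypes$geno), 2L)  # site survives via others
  # a site whose only variant carrier is masked is dropped
  g2 <- cbind(c(1L, 0L, 0L))
  dp2 <- cbind(c(9L, 40L, 40L))
  fv2 <- filter_variants(toy_vcf(g2, dp = dp2))
  expect_equal(ncol(fv2$genotypes$geno), 0L)
  expect_equal(fv2$log$reason[1], "no_passing_variant")
})

test_that("filtering is idempotent and monotone in thresholds", {
  set.seed(42)
  for (r in 1:20) {
    n <- 12L; m <- 15L
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * m, TRUE,
                       prob = c(.5, .3, .15, .05)), n, m)
    vcf <- toy_vcf(g, qual = runif(m, 10, 80), mq = runif(m, 10, 80),
                   bq = runif(m, 10, 40), indel = runif(m) < 0.1,
                   dp = matrix(rpois(n * m, 20), n, m))
    f1 <- filter_variants(vcf)
    # idempotence: re-filtering the accepted output changes nothing
    vcf2 <- list(genotypes = f1$genotypes,
                 records = vcf$records[f1$log$kept, , drop = FALSE],
                 dp = vcf$dp[, f1$log$kept, drop = FALSE], ad_alt = NULL)
    f2 <- filter_variants(vcf2)
    expect_identical(f2$genotypes$geno, f1$genotypes$geno)
    # monotonicity: relaxing any threshold never loses sites
    th <- qc_thresholds()
    for (relax in list(qc_thresholds(min_base_q = 0),
                       qc_thresholds(min_map_q = 0),
                       qc_thresholds(min_depth = 0),
                       qc_thresholds(min_var_q = 0),
                       qc_thresholds(drop_indels = FALSE))) {
      expect_gte(ncol(filter_variants(vcf, relax)$genotypes$geno),
                 ncol(f1$genotypes$geno))
    }
  }
})

test_that("clean simulated data passes QC unchanged", {
  cfg <- sim_config(n_offspring = 25L, seed = 12, missing_rate = 0,
                    fragments = data.frame(name = "FX", length = 2500L),
                    depth_model = list(grand = 200, ind_sd = 0.1,
                                       frag_sd = 0.1, resid_sd = 0.05,
                                       taper_width = 0L, base_cv = 0))
  ds <- simulate_dataset(cfg)
  dir <- tempfile(); write_dataset(ds, dir)
  vcf <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  fv <- filter_variants(vcf)
  poly <- colSums(ds$genotypes$geno > 0, na.rm = TRUE) > 0
  expect_equal(fv$genotypes$sites$site_id,
               ds$genotypes$sites$site_id[poly])
  expect_identical(unname(fv$genotypes$geno),
                   unname(ds$genotypes$geno[, poly]))
})

test_that("common-SNP extraction uses strict printed inequalities", {
  # 10 individuals; craft exact MAF values
  g <- cbind(c(rep(1L, 1), rep(0L, 9)),   # MAF 0.05 -> excluded
             c(rep(1L, 2), rep(0L, 8)),   # MAF 0.10 -> kept
             rep(0L, 10))                 # monomorphic -> excluded
  gm <- toy_genotypes(g)
  out <- extract_common_snps(gm)
  expect_equal(out$sites$pos, 20L)
  # missing fraction 0.19 retained, 0.20 dropped (strict <)
  g2 <- matrix(1L, 100, 2)
  g2[1:19, 1] <- NA; g2[1:20, 2] <- NA
  out2 <- extract_common_snps(toy_genotypes(g2))
  expect_equal(out2$sites$pos, 10L)
  # thresholds wide open retain every polymorphic site, order preserved
  set.seed(7)
  g3 <- matrix(sample(0:2, 338 * 20, TRUE), 20, 338)
  gm3 <- toy_genotypes(g3)
  out3 <- extract_common_snps(gm3, maf_min = 0, max_missing = 1)
  keep <- site_maf(gm3) > 0
  expect_equal(out3$sites$site_id, gm3$sites$site_id[keep])
})

test_that("codon annotation distinguishes synonymous changes", {
  # fragment: 9 bp CDS at 4..12 = ATG TTA CTA, SNPs inside and outside
  ref <- c("AAA", "ATGTTACTA", "AAAAA")
  seqs <- stats::setNames(paste(ref, collapse = ""), "FZ")
  gmod <- data.frame(fragment = "FZ", feature = "CDS", start = 4L,
                     end = 12L, strand = "+")
  sites <- data.frame(
    fragment = "FZ",
    pos = c(9L, 10L, 8L, 2L, 14L),
    ref = c("A", "C", "T", "A", "A"),
    alt = c("G", "T", "C", "G", "C"), stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(0L, 2, 5), sites)
  ann <- annotate_sites(gm, gmod, seqs)
  # TTA -> TTG (Leu/Leu) synonymous third position
  expect_equal(ann$sites$class[1], "synonymous")
  # CTA -> TTA (Leu/Leu) first-position but degenerate -> synonymous
  expect_equal(ann$sites$class[2], "synonymous")
  # TTA -> TCA (Leu -> Ser) non-synonymous
  expect_equal(ann$sites$class[3], "non-synonymous")
  # intergenic / intron positions are silent
  expect_equal(ann$sites$class[4:5], c("silent", "silent"))
  # CDS length not divisible by 3 rejects the model
  gmod_bad <- data.frame(fragment = "FZ", feature = "CDS", start = 4L,
                         end = 11L, strand = "+")
  expect_error(annotate_sites(gm, gmod_bad, seqs), "divisible")
})
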