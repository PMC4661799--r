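# two-deme genotype builder with strong allele-frequency divergence
two_deme_genotypes <- function(n_per = 40, L = 80, seed = 1) {
  set.seed(seed)
  p1 <- runif(L, 0.05, 0.45); p2 <- p1 + 0.5
  g <- rbind(matrix(rbinom(n_per * L, 2, rep(p1, each = n_per)), n_per, L),
             matrix(rbinom(n_per * L, 2, rep(p2, each = n_per)), n_per, L))
  list(gm = toy_genotypes(g), deme = rep(1:2, each = n_per))
}

test_that("kinship: ordering, equivariance, degenerate input", {
  cfg <- sim_config(n_offspring = 70L, seed = 8,
                    fragments = data.frame(name = "FR", length = 4000L))
  ds <- simulate_dataset(cfg)
  com <- extract_common_snps(ds$genotypes)
  K <- suppressWarnings(kinship_matrix(com))
  expect_true(isSymmetric(K))
  expect_true(all(K >= 0))
  P <- ds$truth$kinship
  ut <- upper.tri(K)
  fs <- P[ut] == 0.25; un <- P[ut] == 0
  expect_gt(mean(K[ut][fs]), mean(K[ut][un]))
  # identical genotype vectors in an unrelated background: maximal pair
  set.seed(2)
  gu <- matrix(rbinom(40 * 120, 2, 0.35), 40, 120)
  gu[2, ] <- gu[1, ]
  Ku <- kinship_matrix(toy_genotypes(gu))
  expect_equal(unname(Ku[1, 2]), max(Ku[upper.tri(Ku)]))
  # permuting individuals permutes rows and columns consistently
  perm <- sample(nrow(com$geno))
  Kp <- suppressWarnings(
    kinship_matrix(genotype_matrix(com$geno[perm, ], com$sites,
                                   com$individuals[perm])))
  K2 <- suppressWarnings(kinship_matrix(com))
  expect_equal(as.vector(Kp), as.vector(K2[perm, perm]),
               tolerance = 1e-12)
  # monomorphic-only input rejected
  mono <- genotype_matrix(matrix(0L, 5, 3),
                          data.frame(fragment = "F", pos = 1:3,
                                     ref = "A", alt = "G"))
  expect_error(kinship_matrix(mono), "polymorphic")
  expect_warning(kinship_matrix(
    genotype_matrix(matrix(sample(0:2, 50, TRUE), 10, 5),
                    data.frame(fragment = "F", pos = 1:5,
                               ref = "A", alt = "G"))), "fewer than 50")
})

test_that("admixture EM: K = 1, divergence, label symmetry, selection", {
  td <- two_deme_genotypes(seed = 5)
  q1 <- admixture_q(td$gm, 1)
  expect_true(all(q1$Q == 1))
  q2 <- suppressWarnings(admixture_q(td$gm, 2, n_restarts = 8, seed = 2))
  expect_equal(rowSums(q2$Q), rep(1, 80), tolerance = 1e-9)
  assign2 <- (q2$Q[, 1] > 0.5) + 1L
  acc <- mean(assign2 == td$deme)
  expect_gt(max(acc, 1 - acc), 0.95)       # label switching allowed
  expect_gt(q2$loglik, q1$loglik)
  sel <- suppressWarnings(select_k(td$gm, k_max = 4, n_restarts = 4,
                                   seed = 3))
  expect_equal(sel$k, 2L)
  # flat trace (single panmictic deme) plateaus at K = 1
  set.seed(9)
  g0 <- matrix(rbinom(60 * 60, 2, 0.4), 60, 60)
  sel0 <- suppressWarnings(select_k(toy_genotypes(g0), k_max = 3,
                                    n_restarts = 4, seed = 1))
  expect_equal(sel0$k, 1L)
})

test_that("MLM collapses to one-way ANOVA without structure", {
  set.seed(14)
  n <- 90
  x <- sample(0:2, n, TRUE, prob = c(.4, .4, .2))
  y <- rnorm(n) + 0.3 * x
  gm <- toy_genotypes(matrix(x, ncol = 1))
  ph <- data.frame(individual_id = gm$individuals, TR = y)
  scan <- mlm_scan(ph, gm, Q = NULL, K = NULL, traits = "TR")
  p_aov <- anova(lm(y ~ factor(x)))[["Pr(>F)"]][1]
  expect_equal(scan$p, p_aov, tolerance = 1e-10)
  # additive coding drops to a 1-df test
  scan_add <- mlm_scan(ph, gm, K = NULL, traits = "TR", additive = TRUE)
  p_lin <- anova(lm(y ~ x))[["Pr(>F)"]][1]
  expect_equal(scan_add$p, p_lin, tolerance = 1e-10)
})

test_that("spectral REML and GLS match a dense-matrix oracle", {
  set.seed(15)
  n <- 40
  cfg <- sim_config(n_offspring = n, seed = 15,
                    fragments = data.frame(name = "FR", length = 3000L))
  ds <- simulate_dataset(cfg)
  com <- extract_common_snps(ds$genotypes)
  K <- ds$truth$kinship
  ph <- ds$phenotypes
  scan <- mlm_scan(ph, com, Q = NULL, K = K, traits = "SL")
  lam <- scan$lambda[1]
  # dense restricted likelihood, written independently
  G <- 2 * K
  X <- matrix(1, n, 1)
  y <- ph$SL
  dense_reml <- function(l) {
    V <- l * G + diag(n)
    Vi <- solve(V)
    B <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% B
    rss <- drop(t(r) %*% Vi %*% r)
    0.5 * ((n - 1) * log(rss) + determinant(V)$modulus +
             determinant(t(X) %*% Vi %*% X)$modulus)
  }
  lam_dense <- exp(optimize(function(ll) dense_reml(exp(ll)),
                            c(-10, 10))$minimum)
  expect_lt(abs(log(lam + 1e-8) - log(lam_dense + 1e-8)), 0.05)
  # dense GLS F-test for one marker at the fitted lambda
  s <- which.max(site_maf(com))
  x <- com$geno[, s]; x[is.na(x)] <- round(mean(x, na.rm = TRUE))
  V <- lam * G + diag(n); Vi <- solve(V)
  M <- cbind(1, outer(x, sort(unique(x))[-1], "=="))
  gls_rss <- function(Xm) {
    B <- solve(t(Xm) %*% Vi %*% Xm, t(Xm) %*% Vi %*% y)
    r <- y - Xm %*% B
    drop(t(r) %*% Vi %*% r)
  }
  r0 <- gls_rss(matrix(1, n, 1)); r1 <- gls_rss(M)
  q <- ncol(M) - 1
  f <- ((r0 - r1) / q) / (r1 / (n - ncol(M)))
  p_dense <- pf(f, q, n - ncol(M), lower.tail = FALSE)
  row <- scan[scan$site_id == com$sites$site_id[s], ]
  expect_equal(row$p, p_dense, tolerance = 1e-6)
})

test_that("MLM type-I error is calibrated under structure + kinship", {
  set.seed(16)
  n <- 100
  # fixed structured world: two demes + family blocks
  deme <- rep(0:1, each = n / 2)
  blocks <- rep(1:10, each = n / 10)
  Kmat <- 0.25 * outer(blocks, blocks, "==")
  diag(Kmat) <- 0.5
  rownames(Kmat) <- colnames(Kmat) <- sprintf("I%03d", 1:n)
  Qm <- cbind(1 - deme, deme)
  ch <- chol(2 * Kmat + diag(1e-8, n))
  rej <- replicate(200, {
    x <- rbinom(n, 2, 0.3 + 0.3 * deme)       # marker tracks structure
    y <- 0.8 * deme + drop(crossprod(ch, rnorm(n))) * 0.7 + rnorm(n)
    gm <- toy_genotypes(matrix(x, ncol = 1))
    ph <- data.frame(individual_id = gm$individuals, TR = y)
    scan <- tryCatch(mlm_scan(ph, gm, Q = Qm, K = Kmat, traits = "TR"),
                     error = function(e) NULL)
    if (is.null(scan) || is.na(scan$p)) NA else scan$p < 0.05
  })
  rej <- rej[!is.na(rej)]
  expect_gt(length(rej), 150)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / length(rej)))
})

test_that("planted QTL is detected and its R2 recovered", {
  # kinship/structure come from the pedigree truth, mirroring the study
  # design where both were estimated from independent genome-wide
  # markers rather than the candidate amplicons themselves
  hits <- 0; r2_err <- c(); n_rep <- 12
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_offspring = 159L, seed = 7000L + r)
    ds <- simulate_dataset(cfg)
    com <- extract_common_snps(ds$genotypes)
    K <- ds$truth$kinship
    Qm <- cbind(1 - ds$truth$ancestry, ds$truth$ancestry)
    scan <- mlm_scan(ds$phenotypes, com, Q = Qm, K = K, traits = "SL")
    qtl <- ds$truth$qtl$qtl_site
    # significant at FDR 0.05 at the QTL or a marker in strong LD with it
    sig <- scan$site_id[!is.na(scan$q) & scan$q < 0.05]
    if (length(sig)) {
      xq <- ds$genotypes$geno[, qtl]
      in_ld <- vapply(sig, function(s) {
        x2 <- ds$genotypes$geno[, s]
        ok <- !is.na(xq) & !is.na(x2)
        cor(xq[ok], x2[ok])^2 > 0.3
      }, TRUE)
      if (any(in_ld)) hits <- hits + 1
    }
    row <- scan[scan$site_id == qtl, ]
    if (nrow(row) == 1 && !is.na(row$r2_pct)) {
      r2_err <- c(r2_err, row$r2_pct / 100 - ds$truth$qtl$realized_r2)
    }
  }
  expect_gt(hits / n_rep, 0.5)
  # mixed-model R2 is attenuated by the polygenic absorption but should
  # track the truth within a loose simulation band
  expect_lt(abs(mean(r2_err)), 0.08)
})

test_that("BH step-up matches p.adjust and the printed example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  for (r in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.5)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("marker R2 endpoints behave", {
  set.seed(18)
  n <- 60
  x <- rep(0:2, each = n / 3)
  gm <- toy_genotypes(matrix(x, ncol = 1))
  # orthogonal marker: R2 near zero
  ph0 <- data.frame(individual_id = gm$individuals, TR = rnorm(n))
  s0 <- mlm_scan(ph0, gm, K = NULL, traits = "TR")
  expect_lt(s0$r2_pct, 10)
  # perfect determination: R2 = 100
  ph1 <- data.frame(individual_id = gm$individuals,
                    TR = c(1, 5, 9)[x + 1])
  s1 <- mlm_scan(ph1, gm, K = NULL, traits = "TR")
  expect_equal(s1$r2_pct, 100, tolerance = 1e-8)
})

test_that("gene action arithmetic and classification", {
  ga <- gene_action(10, 12, 14)
  expect_equal(ga$two_a, 4); expect_equal(ga$d, 0)
  expect_equal(ga$d_over_a, 0); expect_equal(ga$action, "additive")
  expect_equal(gene_action(0, 1.51, 2)$action, "partial-to-full dominance")
  expect_equal(gene_action(0, 2.3, 2)$action, "over/underdominance")
  expect_equal(gene_action(0, 1.5, 2)$action, "additive")  # boundary <= 0.5
  expect_true(is.na(gene_action(1, 2, 1)$d_over_a))        # 2a = 0
  expect_true(is.na(gene_action(NA, 2, 3)$action))
})

test_that("condition factor follows the cubic allometry", {
  expect_equal(condition_factor(100, 10), 10)
  expect_equal(condition_factor(100, 20), condition_factor(100, 10) / 8)
  expect_error(condition_factor(100, 0), "positive")
  # sub-cubic weight growth makes K fall with length
  set.seed(19)
  SL <- exp(rnorm(500, log(17), 0.2))
  BWT <- 0.05 * SL^2.5 * exp(rnorm(500, 0, 0.05))
  expect_lt(cor(condition_factor(BWT, SL), SL), 0)
})

test_that("trait correlations: structure of the matrix", {
  set.seed(20)
  ph <- data.frame(individual_id = sprintf("I%02d", 1:50),
                   A = rnorm(50), B = rnorm(50), C = rnorm(50))
  ph$D <- ph$A * 0.9 + rnorm(50, 0, 0.3)
  tc <- trait_correlations(ph)
  expect_equal(diag(tc$r), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(tc$r))
  expect_lt(tc$p["A", "D"], 1e-6)
  expect_gt(tc$p["A", "B"], 0.001)
  ph$E <- 1
  tc2 <- trait_correlations(ph)
  expect_true(all(is.na(tc2$r["E", c("A", "B", "C", "D")])))
})
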