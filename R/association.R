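#' Pairwise kinship matrix (Loiselle estimator)
#'
#' Multilocus kinship from individual allele frequencies x in {0, 0.5, 1}
#' relative to cohort frequencies, with the small-sample bias term
#' p(1-p)/(n-1) per locus, summed over loci and normalised by the total
#' p(1-p). Missing genotypes contribute nothing (mean imputation).
#' Negative estimates are truncated at zero and counted; the diagonal is
#' set to 0.5 (non-inbred self-kinship).
#'
#' @param genotypes a \code{genotype_matrix}
#' @return kinship matrix with attribute \code{n_truncated}
#' @export
kinship_matrix <- function(genotypes) {
  g <- genotypes$geno
  n <- nrow(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) {
    stop("no polymorphic markers to estimate kinship from", call. = FALSE)
  }
  if (sum(poly) < 50L) {
    warning("fewer than 50 polymorphic markers; kinship estimates ",
            "will be noisy")
  }
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  n_l <- colSums(!is.na(g))
  x <- sweep(g / 2, 2, p)          # centred individual allele freq
  x[is.na(x)] <- 0
  plq <- p * (1 - p)
  num <- tcrossprod(x) + sum(plq / pmax(n_l - 1L, 1L))
  K <- num / sum(plq)
  n_trunc <- sum(K[upper.tri(K)] < 0)
  K[K < 0] <- 0
  diag(K) <- 0.5
  dimnames(K) <- list(genotypes$individuals, genotypes$individuals)
  attr(K, "n_truncated") <- n_trunc
  K
}

#' Maximum-likelihood admixture proportions by EM
#'
#' Binomial admixture model without linkage: genotype dosage g_il ~
#' Binomial(2, sum_k q_ik p_kl). Standard EM updates for ancestry
#' fractions Q and ancestral allele frequencies P, run from several seeded
#' random starts keeping the best log-likelihood. K = 1 reduces to the
#' plain allele-frequency model.
#'
#' @param genotypes a \code{genotype_matrix}
#' @param K number of ancestral subpopulations (1..12)
#' @param n_restarts random restarts (default 20)
#' @param max_iter EM iterations per start
#' @param tol convergence tolerance on the log-likelihood
#' @param seed RNG seed
#' @return list: \code{Q} (n x K, rows sum to 1), \code{P} (K x L),
#'   \code{loglik}, \code{converged}
#' @export
admixture_q <- function(genotypes, K, n_restarts = 20L, max_iter = 1000L,
                        tol = 1e-3, seed = 1L) {
  stopifnot(K >= 1L, K <= 12L)
  g <- genotypes$geno
  keep <- site_maf(genotypes) > 0
  g <- g[, keep, drop = FALSE]
  n <- nrow(g); L <- ncol(g)
  gA <- g; gA[is.na(gA)] <- 0L          # alt-allele counts
  gR <- 2L - g; gR[is.na(gR)] <- 0L     # ref-allele counts
  loglik_of <- function(Q, P) {
    mu <- Q %*% P
    mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    sum(gA * log(mu) + gR * log(1 - mu))
  }
  if (K == 1L) {
    P <- matrix(colSums(gA) / pmax(colSums(gA + gR), 1L), 1L, L)
    Q <- matrix(1, n, 1L)
    return(list(Q = Q, P = P, loglik = loglik_of(Q, P), converged = TRUE))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(n_restarts, 1L))) {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mu <- Q %*% P
      mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
      # expected allele assignments to ancestry k
      A_num <- gA / mu        # n x L
      R_num <- gR / (1 - mu)
      EA <- array(0, c(n, K))
      ER <- array(0, c(n, K))
      PA <- matrix(0, K, L)
      PR <- matrix(0, K, L)
      for (k in seq_len(K)) {
        ak <- (Q[, k] %o% P[k, ]) * A_num
        rk <- (Q[, k] %o% (1 - P[k, ])) * R_num
        EA[, k] <- rowSums(ak)
        ER[, k] <- rowSums(rk)
        PA[k, ] <- colSums(ak)
        PR[k, ] <- colSums(rk)
      }
      Q <- (EA + ER)
      Q <- Q / pmax(rowSums(Q), 1e-12)
      P <- PA / pmax(PA + PR, 1e-12)
      P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
      ll <- loglik_of(Q, P)
      if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
      ll_prev <- ll
    }
    ll <- loglik_of(Q, P)
    if (is.null(best) || ll > best$loglik) {
      best <- list(Q = Q, P = P, loglik = ll, converged = converged)
    }
  }
  if (!best$converged) {
    warning("admixture EM did not fully converge; returning best run")
  }
  best
}

#' Choose the number of subpopulations from a likelihood trace
#'
#' Runs \code{\link{admixture_q}} for K = 1..k_max and returns the K with
#' the largest increase in log-likelihood over K - 1 (the successive
#' change criterion); if no increase exceeds \code{min_gain} the trace is
#' flat and K = 1 is reported.
#'
#' @param genotypes a \code{genotype_matrix}
#' @param k_max largest K to try (<= 12)
#' @param min_gain plateau threshold in log-likelihood units; gains below
#'   it are treated as overfitting noise. The default (NULL) uses the
#'   AIC-flavoured heuristic L + n (each extra component adds about
#'   L + n free parameters, so a chance gain of roughly (L + n)/2 is
#'   expected under the flat model; twice that is demanded).
#' @param ... passed on to \code{\link{admixture_q}}
#' @return list: k, loglik (trace), gains, min_gain
#' @export
select_k <- function(genotypes, k_max = 6L, min_gain = NULL, ...) {
  stopifnot(k_max >= 1L, k_max <= 12L)
  ll <- vapply(seq_len(k_max), function(K) {
    admixture_q(genotypes, K, ...)$loglik
  }, numeric(1))
  if (is.null(min_gain)) {
    min_gain <- sum(site_maf(genotypes) > 0) + nrow(genotypes$geno)
  }
  if (k_max == 1L) {
    return(list(k = 1L, loglik = ll, gains = numeric(0),
                min_gain = min_gain))
  }
  gains <- diff(ll)
  k <- if (max(gains) < min_gain) 1L else which.max(gains) + 1L
  list(k = k, loglik = ll, gains = gains, min_gain = min_gain)
}

# EMMA-style restricted likelihood for lambda = sigma_g^2 / sigma_e^2 on
# the eigenbasis of the relationship matrix
reml_lambda <- function(yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  neg_restricted <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * d + 1
    w <- 1 / v
    fit <- stats::lm.wfit(Xt, yt, w)
    rss <- sum(w * fit$residuals^2)
    xtwx <- crossprod(Xt * sqrt(w))
    ldet <- determinant(xtwx, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(rss) + sum(log(v)) + as.numeric(ldet))
  }
  grid <- seq(-10, 10, by = 0.5)
  vals <- vapply(grid, neg_restricted, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  op <- stats::optimize(neg_restricted, c(lo, hi))
  lambda <- exp(op$minimum)
  if (neg_restricted(-25) <= op$objective) lambda <- 0  # boundary
  lambda
}

#' Mixed-linear-model single-marker association scan
#'
#' For each trait, fits y = mu + Q v + marker + u + e with polygenic
#' effect u ~ N(0, sigma_g^2 G), G = 2 x kinship, by REML on one spectral
#' decomposition of G. Variance components are estimated once per trait
#' under the null model and reused across markers (P3D); each marker is
#' tested by an F-test on its genotype-class factor in the
#' generalised-least-squares transform. Markers whose design is singular
#' given the covariates are reported NA.
#'
#' @param phenotypes data.frame with individual_id and trait columns
#' @param genotypes a \code{genotype_matrix} (pre-filtered to common SNPs)
#' @param Q admixture matrix (n x K) or NULL; the first column is dropped
#'   as redundant with the intercept
#' @param K kinship matrix or NULL for an unstructured (OLS) scan
#' @param traits traits to scan (default: all numeric columns)
#' @param additive test the additive dosage (1 df) instead of the
#'   genotype-class factor
#' @param exact_reml re-estimate variance components under each marker
#'   model instead of P3D
#' @return data.frame of class \code{assoc_scan}: site_id, fragment, pos,
#'   maf, trait, p, q, r2_pct, two_a, d, d_over_a, action, lambda
#' @export
mlm_scan <- function(phenotypes, genotypes, Q = NULL, K = NULL,
                     traits = NULL, additive = FALSE, exact_reml = FALSE) {
  ids <- genotypes$individuals
  stopifnot(all(ids %in% phenotypes$individual_id))
  ph <- phenotypes[match(ids, phenotypes$individual_id), , drop = FALSE]
  if (is.null(traits)) {
    traits <- setdiff(names(ph)[vapply(ph, is.numeric, TRUE)],
                      "individual_id")
  }
  n <- length(ids)
  if (!is.null(K)) {
    G <- 2 * K[ids, ids]
    eg <- eigen(G, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
  } else {
    d <- rep(0, n); U <- diag(n)
  }
  Xq <- if (!is.null(Q)) {
    qm <- as.matrix(Q)
    if (ncol(qm) > 1L) qm[, -1L, drop = FALSE] else NULL
  } else NULL
  X0 <- cbind(`(Intercept)` = rep(1, n), Xq)
  X0t <- crossprod(U, X0)

  res <- list()
  for (tr in traits) {
    y <- ph[[tr]]
    ok <- !is.na(y)
    # with missing phenotypes the eigenbasis is recomputed on the subset
    if (any(!ok)) {
      if (!is.null(K)) {
        eg2 <- eigen(2 * K[ids[ok], ids[ok]], symmetric = TRUE)
        d_t <- pmax(eg2$values, 0); U_t <- eg2$vectors
      } else { d_t <- rep(0, sum(ok)); U_t <- diag(sum(ok)) }
      X0_t <- crossprod(U_t, X0[ok, , drop = FALSE])
    } else { d_t <- d; U_t <- U; X0_t <- X0t }
    yt <- crossprod(U_t, y[ok])
    lambda <- if (!is.null(K)) reml_lambda(yt, X0_t, d_t) else 0
    w <- 1 / (lambda * d_t + 1)
    sw <- sqrt(w)
    fit0 <- stats::lm.fit(X0_t * sw, yt * sw)
    rss0 <- sum(fit0$residuals^2)
    p0 <- fit0$rank
    # total SS in the whitened model (around the GLS intercept; the
    # intercept column in the rotated basis is U'1 = X0t[, 1])
    fit_null <- stats::lm.fit(X0t[, 1, drop = FALSE] * sw, yt * sw)
    sst <- sum(fit_null$residuals^2)
    for (s in seq_len(ncol(genotypes$geno))) {
      x <- genotypes$geno[ok, s]
      xin <- !is.na(x)
      row <- marker_test(yt, X0_t, sw, x, xin, rss0, p0, sst,
                         additive = additive,
                         exact = exact_reml, d = d_t, U = U_t,
                         lambda = lambda)
      # raw genotype-class means for the gene-action decomposition
      ga <- gene_action_from_genotypes(y[ok], x)
      res[[length(res) + 1L]] <- data.frame(
        site_id = genotypes$sites$site_id[s],
        fragment = genotypes$sites$fragment[s],
        pos = genotypes$sites$pos[s],
        maf = site_maf(genotypes)[s],
        trait = tr, p = row$p, r2_pct = row$r2_pct,
        two_a = ga$two_a, d = ga$d, d_over_a = ga$d_over_a,
        action = ga$action, lambda = lambda,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  class(out) <- c("assoc_scan", "data.frame")
  out[, c("site_id", "fragment", "pos", "maf", "trait", "p", "q",
          "r2_pct", "two_a", "d", "d_over_a", "action", "lambda")]
}

# GLS F-test of one marker given the whitened null design. Individuals
# with a missing genotype at the marker keep their phenotype via mean
# imputation of the dosage (markers are pre-filtered to < 20% missing, so
# the approximation is mild); exact = TRUE re-estimates lambda under the
# marker model instead of reusing the null's (P3D off).
marker_test <- function(yt, X0t, sw, x, xin, rss0, p0, sst, additive,
                        exact, d, U, lambda) {
  classes <- sort(unique(x[xin]))
  if (length(classes) < 2L) return(list(p = NA_real_, r2_pct = NA_real_))
  x_use <- x
  if (any(!xin)) x_use[!xin] <- mean(x[xin])
  M <- if (additive) matrix(x_use, ncol = 1) else
    vapply(classes[-1], function(cl) as.numeric(x_use == cl),
           numeric(length(x_use)))
  Mt <- crossprod(U, M)
  if (exact) {
    lambda <- reml_lambda(yt, cbind(X0t, Mt), d)
    sw <- 1 / sqrt(lambda * d + 1)
    fit0 <- stats::lm.fit(X0t * sw, yt * sw)
    rss0 <- sum(fit0$residuals^2)
    p0 <- fit0$rank
    sst <- sum(stats::lm.fit(X0t[, 1, drop = FALSE] * sw,
                             yt * sw)$residuals^2)
  }
  X1 <- cbind(X0t, Mt) * sw
  fit1 <- stats::lm.fit(X1, yt * sw)
  p1 <- fit1$rank
  qdf <- p1 - p0
  if (qdf < 1L) return(list(p = NA_real_, r2_pct = NA_real_))
  rss1 <- sum(fit1$residuals^2)
  ndf <- length(yt) - p1
  f <- ((rss0 - rss1) / qdf) / (rss1 / ndf)
  list(p = stats::pf(f, qdf, ndf, lower.tail = FALSE),
       r2_pct = if (sst > 0) 100 * (rss0 - rss1) / sst else NA_real_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with monotonicity enforcement: q_(i) =
#' min_{j >= i} p_(j) m / j, capped at 1. NAs propagate.
#'
#' @param pvals numeric vector of p-values in [0, 1]
#' @return vector of Q values, same order as input
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- rep(NA_real_, length(pvals))
  q[ok][ord] <- q_sorted
  q
}

#' Gene-action decomposition from genotype-class means
#'
#' 2a = |G_BB - G_bb| (twice the additive effect), d = G_Bb -
#' 0.5 (G_BB + G_bb) (dominance deviation), d/a their signed ratio;
#' |d/a| <= 0.5 is additive, 0.5 < |d/a| < 1.25 partial-to-full dominance,
#' >= 1.25 over/underdominance. NA when a class is unobserved or 2a = 0.
#'
#' @param g_hom_ref,g_het,g_hom_alt trait means of the three genotype
#'   classes
#' @return list: two_a, d, d_over_a, action
#' @export
gene_action <- function(g_hom_ref, g_het, g_hom_alt) {
  if (any(is.na(c(g_hom_ref, g_het, g_hom_alt)))) {
    return(list(two_a = NA_real_, d = NA_real_, d_over_a = NA_real_,
                action = NA_character_))
  }
  two_a <- abs(g_hom_alt - g_hom_ref)
  d <- g_het - 0.5 * (g_hom_alt + g_hom_ref)
  if (two_a == 0) {
    return(list(two_a = two_a, d = d, d_over_a = NA_real_,
                action = NA_character_))
  }
  da <- d / (two_a / 2)
  action <- if (abs(da) <= 0.5) "additive" else
    if (abs(da) < 1.25) "partial-to-full dominance" else
      "over/underdominance"
  list(two_a = two_a, d = d, d_over_a = da, action = action)
}

gene_action_from_genotypes <- function(y, x) {
  m <- function(cl) if (any(x == cl, na.rm = TRUE))
    mean(y[which(x == cl)], na.rm = TRUE) else NA_real_
  gene_action(m(0L), m(1L), m(2L))
}

#' Fulton's condition factor
#'
#' K = 100 x body weight / standard length^3 (weight in g, length in cm),
#' a plumpness index.
#'
#' @param BWT body weight
#' @param SL standard length (> 0)
#' @return condition factor
#' @export
condition_factor <- function(BWT, SL) {
  if (any(SL <= 0, na.rm = TRUE)) {
    stop("standard length must be positive", call. = FALSE)
  }
  100 * BWT / SL^3
}

#' Pairwise trait correlations with p-values
#'
#' Pearson correlations on pairwise-complete observations with two-sided
#' t-test p-values; constant traits give NA rows.
#'
#' @param phenotypes data.frame with individual_id and numeric traits
#' @param min_n minimum complete pairs per correlation
#' @return list of matrices: r, p, n
#' @export
trait_correlations <- function(phenotypes, min_n = 3L) {
  num <- phenotypes[vapply(phenotypes, is.numeric, TRUE)]
  traits <- names(num)
  k <- length(traits)
  r <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in i:k) {
    x <- num[[i]]; y <- num[[j]]
    ok <- !is.na(x) & !is.na(y)
    nn[i, j] <- nn[j, i] <- sum(ok)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      next
    }
    rr <- stats::cor(x[ok], y[ok])
    r[i, j] <- r[j, i] <- rr
    if (i == j) { p[i, j] <- NA_real_; next }
    df <- sum(ok) - 2L
    tt <- rr * sqrt(df / (1 - rr^2))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = nn)
}
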