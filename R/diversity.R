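#' Nucleotide diversity (pi) per site
#'
#' Average number of pairwise nucleotide differences between sequences,
#' divided by the number of sites considered. \code{haps} holds only the
#' segregating sites of the region; \code{L} is the region's total length
#' and may be fractional for codon-derived site classes.
#'
#' @param haps binary matrix, sequences x segregating sites
#' @param L total sites in the region (> 0; fractional allowed)
#' @return pi per site; NA when L is 0
#' @export
nuc_diversity <- function(haps, L) {
  n <- nrow(haps)
  stopifnot(n >= 2)
  if (is.na(L) || L <= 0) return(NA_real_)
  mean_pairwise_diff(haps) / L
}

# mean number of pairwise differences k-hat (absolute, not per site);
# per-site identity: a site with c carriers contributes c(n-c) differing
# pairs out of C(n,2)
mean_pairwise_diff <- function(haps) {
  n <- nrow(haps)
  if (ncol(haps) == 0L) return(0)
  cnt <- colSums(haps)
  sum(cnt * (n - cnt)) / choose(n, 2)
}

#' Watterson's theta per site
#'
#' theta_w = S / (a_n L) with a_n the (n-1)th harmonic number: the expected
#' number of segregating sites per site under neutrality.
#'
#' @param S segregating-site count
#' @param n number of sequences (>= 2)
#' @param L region length in sites (> 0)
#' @return theta_w per site
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, n >= 2, L > 0)
  S / (harmonic_a(n) * L)
}

#' Tajima's D
#'
#' Normalised difference between the pairwise-difference estimator (k-hat)
#' and the segregating-sites estimator (S/a1) of theta, using the standard
#' 1989 constants. NA when S = 0 or the variance term vanishes.
#'
#' @param haps binary matrix, sequences x sites
#' @return D statistic
#' @export
tajimas_d <- function(haps) {
  n <- nrow(haps)
  stopifnot(n >= 2)
  seg <- colSums(haps) %% n != 0L
  S <- sum(seg)
  if (S < 1L) return(NA_real_)
  k_hat <- mean_pairwise_diff(haps)
  cst <- tajima_constants(n)
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (k_hat - S / cst$a1) / denom
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Log unsigned Stirling numbers of the first kind, one row
#'
#' Returns log |s(n, k)| for k = 0..n via the recurrence
#' |s(n,k)| = |s(n-1,k-1)| + (n-1) |s(n-1,k)| evaluated in log space, so
#' rows up to n of several hundred do not overflow.
#'
#' @param n row index
#' @return numeric vector of length n + 1 (k = 0..n), -Inf where s = 0
#' @export
log_stirling_first <- function(n) {
  row <- c(0)                       # n = 0: s(0,0) = 1
  if (n == 0L) return(row)
  for (m in seq_len(n)) {
    prev <- c(-Inf, row)            # shifted: |s(m-1, k-1)|
    carry <- c(row, -Inf) + log(m - 1)  # (m-1) |s(m-1, k)|
    hi <- pmax(prev, carry)
    row <- ifelse(is.infinite(hi) & hi < 0, -Inf,
                  hi + log1p(exp(pmin(prev, carry) - hi)))
    row[is.nan(row)] <- -Inf
  }
  row
}

#' Ewens distribution of the number of distinct alleles
#'
#' log Pr(K = k | theta, n) = log|s(n,k)| + k log theta - log theta^(n)
#' (rising factorial), for k = 1..n.
#'
#' @param n sample size
#' @param theta scaled mutation rate (> 0)
#' @return numeric vector of log probabilities, k = 1..n
#' @export
ewens_log_pk <- function(n, theta) {
  stopifnot(theta > 0)
  ls <- log_stirling_first(n)[-1]   # k = 1..n
  ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's Fs statistic with a coalescent p-value
#'
#' theta is estimated by the mean pairwise difference k-hat; S' is the
#' Ewens probability of observing at least the sampled number of distinct
#' haplotypes, and Fs = ln(S'/(1 - S')). Strongly negative Fs indicates an
#' excess of haplotypes relative to neutrality (e.g. population growth).
#' The p-value is the proportion of neutral coalescent replicates (at the
#' same theta estimate) with Fs at or below the observed value.
#'
#' @param haps binary matrix, sequences x segregating sites
#' @param n_reps coalescent replicates for the p-value (0 to skip)
#' @param seed RNG seed for the replicates
#' @return list: fs, p, k_obs (distinct haplotypes), theta_hat
#' @export
fus_fs <- function(haps, n_reps = 1000L, seed = 1L) {
  n <- nrow(haps)
  stopifnot(n >= 2)
  obs <- fs_statistic(haps)
  if (is.na(obs$fs)) {
    return(list(fs = NA_real_, p = NA_real_, k_obs = obs$k_obs,
                theta_hat = obs$theta_hat))
  }
  p <- NA_real_
  if (n_reps > 0L) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    fs_null <- vapply(seq_len(n_reps), function(i) {
      sim <- sim_coalescent(n, obs$theta_hat)
      fs_statistic(sim)$fs
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    p <- mean(fs_null <= obs$fs, na.rm = TRUE)
  }
  list(fs = obs$fs, p = p, k_obs = obs$k_obs, theta_hat = obs$theta_hat)
}

fs_statistic <- function(haps) {
  n <- nrow(haps)
  k_obs <- nrow(unique(haps))
  theta_hat <- mean_pairwise_diff(haps)
  list(fs = fs_statistic_from(n, k_obs, theta_hat), k_obs = k_obs,
       theta_hat = theta_hat)
}

# Fs = log(S'/(1-S')) computed as log S' - log(1 - S') in log space
fs_statistic_from <- function(n, k_obs, theta_hat) {
  if (theta_hat <= 0 || k_obs <= 1L) return(NA_real_)
  lp <- ewens_log_pk(n, theta_hat)
  log_sp <- logsumexp(lp[k_obs:n])
  log_below <- logsumexp(lp[seq_len(k_obs - 1L)])
  if (!is.finite(log_below)) return(NA_real_)
  log_sp - log_below
}

#' Nei-Gojobori synonymous / non-synonymous divergence
#'
#' Pathway counting over all pairs of aligned coding sequences: per codon,
#' the synonymous site count is the fraction of the three possible changes
#' at each position that preserve the amino acid (changes to stop codons
#' count as non-synonymous, so N + S = 3 x codons); codons differing at
#' several positions average the synonymous/non-synonymous step counts over
#' all shortest pathways. Proportions are Jukes-Cantor corrected,
#' d = -(3/4) ln(1 - (4/3) p), undefined for p >= 0.75.
#'
#' @param seqs character vector of aligned CDS strings (equal length,
#'   divisible by 3, no internal stop codons)
#' @param weights optional multiplicities per sequence (collapsed unique
#'   haplotypes); pairwise proportions are then averaged over all
#'   \code{choose(sum(weights), 2)} sequence pairs, identical pairs
#'   contributing zero differences
#' @return list: dn, ds, dn_ds, n_sites, s_sites, pn, ps
#' @export
nei_gojobori <- function(seqs, weights = NULL) {
  stopifnot(length(seqs) >= 2 || (!is.null(weights) && sum(weights) >= 2))
  len <- unique(nchar(seqs))
  if (length(len) != 1L || len %% 3L != 0L) {
    stop("sequences must be aligned with length divisible by 3",
         call. = FALSE)
  }
  codons <- lapply(seqs, function(s) {
    substring(s, seq(1, len, 3), seq(3, len, 3))
  })
  code <- Biostrings::GENETIC_CODE
  if (any(vapply(codons, function(cs)
    any(code[cs[-length(cs)]] == "*"), TRUE))) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  st <- syn_table()
  syn_sites <- vapply(codons, function(cs) sum(st[cs]), numeric(1))
  n_cod <- len / 3
  w <- weights %||% rep(1, length(seqs))
  if (length(seqs) == 1L) {
    return(list(dn = 0, ds = 0, dn_ds = NA_real_,
                n_sites = 3 * n_cod - syn_sites[1],
                s_sites = syn_sites[1], pn = 0, ps = 0))
  }
  pairs <- utils::combn(length(seqs), 2)
  pn_sum <- ps_sum <- 0
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    s_bar <- (syn_sites[i] + syn_sites[j]) / 2
    n_bar <- 3 * n_cod - s_bar
    sd_nd <- codon_pair_diffs(codons[[i]], codons[[j]])
    ps_sum <- ps_sum + w[i] * w[j] * sd_nd["sd"] / s_bar
    pn_sum <- pn_sum + w[i] * w[j] * sd_nd["nd"] / n_bar
  }
  tot_pairs <- choose(sum(w), 2)
  pn <- unname(pn_sum / tot_pairs)
  ps <- unname(ps_sum / tot_pairs)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dn <- jc(pn); ds <- jc(ps)
  list(dn = dn, ds = ds,
       dn_ds = if (!is.na(ds) && ds > 0) dn / ds else NA_real_,
       n_sites = 3 * n_cod - stats::weighted.mean(syn_sites, w),
       s_sites = stats::weighted.mean(syn_sites, w), pn = pn, ps = ps)
}

# fraction of possible single-nucleotide changes in a codon that are
# synonymous, summed over the three positions (each position contributes
# (# synonymous among 3 alternatives)/3); memoised over the 64 codons
.syn_cache <- new.env(parent = emptyenv())
syn_table <- function() {
  if (is.null(.syn_cache$tab)) {
    code <- Biostrings::GENETIC_CODE
    nucs <- c("A", "C", "G", "T")
    tab <- vapply(names(code), function(cod) {
      aa <- code[[cod]]
      chars <- strsplit(cod, "")[[1]]
      s <- 0
      for (p in 1:3) {
        for (nu in setdiff(nucs, chars[p])) {
          mut <- chars; mut[p] <- nu
          if (code[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .syn_cache$tab <- tab
  }
  .syn_cache$tab
}

codon_syn_sites <- function(codon) syn_table()[[codon]]

# synonymous (sd) and non-synonymous (nd) difference counts between two
# codon vectors, averaging multi-difference codons over all pathways
codon_pair_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  sd <- nd <- 0
  diff_idx <- which(c1 != c2)
  for (k in diff_idx) {
    a <- strsplit(c1[k], "")[[1]]
    b <- strsplit(c2[k], "")[[1]]
    pos <- which(a != b)
    perms <- if (length(pos) == 1L) list(pos) else
      if (length(pos) == 2L) list(pos, rev(pos)) else
        lapply(seq_len(6), function(i)
          pos[rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                    c(3,1,2), c(3,2,1))[i, ]])
    sd_k <- nd_k <- 0
    for (path in perms) {
      cur <- a
      for (p in path) {
        nxt <- cur; nxt[p] <- b[p]
        if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) sd_k <- sd_k + 1
        else nd_k <- nd_k + 1
        cur <- nxt
      }
    }
    sd <- sd + sd_k / length(perms)
    nd <- nd + nd_k / length(perms)
  }
  c(sd = sd, nd = nd)
}

#' Codon-bootstrap Z-test of H0: dN = dS
#'
#' Variances of dN and dS are obtained by resampling codon columns with
#' replacement; Z = (dN - dS)/sqrt(Var dN + Var dS) with a two-sided
#' normal p-value.
#'
#' @param seqs aligned CDS strings (see \code{\link{nei_gojobori}})
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param weights optional sequence multiplicities
#' @return list: z, p, dn, ds, var_dn, var_ds
#' @export
dn_ds_test <- function(seqs, n_boot = 1000L, seed = 1L, weights = NULL) {
  base <- nei_gojobori(seqs, weights)
  len <- nchar(seqs[1])
  n_cod <- len / 3
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_cod, n_cod, replace = TRUE)
    keep <- sort(idx)
    res <- tryCatch(nei_gojobori(vapply(seqs, function(s) {
      paste(substring(s, 3 * keep - 2, 3 * keep), collapse = "")
    }, ""), weights), error = function(e) NULL)
    if (!is.null(res)) reps[b, ] <- c(res$dn, res$ds)
  }
  v <- apply(reps, 2, stats::var, na.rm = TRUE)
  zt <- z_test_dn_ds(base$dn, base$ds, v[1], v[2])
  c(zt, list(dn = base$dn, ds = base$ds, var_dn = v[1], var_ds = v[2]))
}

#' Z statistic for the dN = dS null
#' @param dn,ds corrected substitution rates
#' @param var_dn,var_ds their (bootstrap) variances
#' @return list: z, p (two-sided normal); NA when the variance is zero
#' @export
z_test_dn_ds <- function(dn, ds, var_dn, var_ds) {
  if (is.na(dn) || is.na(ds)) return(list(z = NA_real_, p = NA_real_))
  v <- var_dn + var_ds
  if (!isTRUE(v > 0)) {
    if (dn == ds) return(list(z = 0, p = 1))
    return(list(z = NA_real_, p = NA_real_))
  }
  z <- (dn - ds) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
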