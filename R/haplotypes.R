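# enumerate ordered diplotype pairs (h1, h2) compatible with one
# individual's window genotypes; haplotypes are bit codes, site 1 = highest
# bit; NA genotypes leave both alleles free
compatible_pairs <- function(g) {
  pairs <- matrix(0L, 1, 2)
  for (s in seq_along(g)) {
    add <- switch(as.character(g[s]),
                  `0` = matrix(c(0L, 0L), 1),
                  `1` = matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE),
                  `2` = matrix(c(1L, 1L), 1),
                  matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), 4,
                         byrow = TRUE))
    pairs <- cbind(pairs[rep(seq_len(nrow(pairs)), each = nrow(add)), ,
                         drop = FALSE] * 2L,
                   0L)[, 1:2, drop = FALSE] +
      add[rep(seq_len(nrow(add)), nrow(pairs)), , drop = FALSE]
  }
  pairs
}

#' EM estimate of window haplotype frequencies
#'
#' Expectation-maximisation over all diplotype expansions compatible with
#' the observed (possibly missing) genotypes of a marker window, as used
#' for haplotype-based association. Converges when the largest frequency
#' change drops below \code{tol} (or at \code{max_iter}); several seeded
#' restarts keep the best log-likelihood, with ties resolved
#' deterministically by restart order.
#'
#' @param geno integer matrix (individuals x window sites, codes 0/1/2/NA);
#'   at most 8 sites
#' @param tol convergence tolerance on max frequency change
#' @param max_iter iteration cap per restart
#' @param n_restarts random restarts in addition to the uniform start
#' @param seed RNG seed for restart initialisation
#' @return object of class \code{haplotype_table}: \code{haplotypes}
#'   (binary strings), \code{freq}, \code{dosage} (individuals x
#'   haplotypes, rows sum to 2), \code{loglik}
#' @export
em_haplotype_frequencies <- function(geno, tol = 1e-6, max_iter = 500L,
                                     n_restarts = 3L, seed = 1L) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  stopifnot(k >= 1L, k <= 8L)
  n <- nrow(geno)
  H <- 2L^k
  # collapse individuals sharing a genotype pattern: the EM only depends
  # on pattern counts
  key <- apply(geno, 1, paste, collapse = "/")
  upat <- unique(key)
  pat_of <- match(key, upat)
  wgt <- tabulate(pat_of, length(upat))
  plist <- lapply(upat, function(kk) {
    compatible_pairs(geno[match(kk, key), ])
  })
  n_eff <- n
  run_em <- function(f) {
    for (it in seq_len(max_iter)) {
      counts <- numeric(H)
      for (u in seq_along(plist)) {
        pp <- plist[[u]]
        w <- f[pp[, 1] + 1L] * f[pp[, 2] + 1L]
        tw <- sum(w)
        if (tw <= 0) w <- rep(1 / nrow(pp), nrow(pp)) else w <- w / tw
        wu <- w * wgt[u]
        # accumulate with duplicate-safe aggregation (indices repeat)
        agg <- rowsum(c(wu, wu), c(pp[, 1], pp[, 2]) + 1L)
        ai <- as.integer(rownames(agg))
        counts[ai] <- counts[ai] + agg[, 1]
      }
      f_new <- counts / (2 * n_eff)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    list(f = f, loglik = em_loglik(f, plist, wgt))
  }
  starts <- list(rep(1 / H, H))
  if (n_restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      g <- stats::rgamma(H, 1)
      starts[[r + 1L]] <- g / sum(g)
    }
  }
  best <- NULL
  for (st in starts) {
    res <- run_em(st)
    if (is.null(best) || res$loglik > best$loglik + 1e-9) best <- res
  }
  f <- best$f
  # posterior dosages per pattern, expanded to individuals
  dos_pat <- matrix(0, length(plist), H)
  for (u in seq_along(plist)) {
    pp <- plist[[u]]
    w <- f[pp[, 1] + 1L] * f[pp[, 2] + 1L]
    if (sum(w) <= 0) w <- rep(1, nrow(pp))
    w <- w / sum(w)
    agg <- rowsum(c(w, w), c(pp[, 1], pp[, 2]) + 1L)
    dos_pat[u, as.integer(rownames(agg))] <- agg[, 1]
  }
  dosage <- dos_pat[pat_of, , drop = FALSE]
  labels <- vapply(0:(H - 1L), function(h) {
    paste(as.integer(bitwAnd(bitwShiftR(h, (k - 1L):0), 1L)),
          collapse = "")
  }, "")
  keep <- f > 0 | colSums(dosage) > 0
  structure(list(haplotypes = labels[keep], freq = f[keep],
                 dosage = dosage[, keep, drop = FALSE],
                 loglik = best$loglik, n_sites = k),
            class = "haplotype_table")
}

em_loglik <- function(f, plist, wgt = rep(1, length(plist))) {
  sum(wgt * vapply(plist, function(pp) {
    log(max(sum(f[pp[, 1] + 1L] * f[pp[, 2] + 1L]), 1e-300))
  }, numeric(1)))
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d-site window, %d haplotypes (loglik %.2f)\n",
              x$n_sites, length(x$haplotypes), x$loglik))
  ord <- order(-x$freq)
  print(data.frame(haplotype = x$haplotypes[ord],
                   freq = round(x$freq[ord], 4)))
  invisible(x)
}

#' Overlapping sliding windows of k sites
#'
#' All contiguous k-site windows within each fragment (step 1 by default);
#' windows never span fragments. Fragments with fewer than k sites yield
#' no windows.
#'
#' @param sites site data.frame (fragment, pos) as in a
#'   \code{genotype_matrix}
#' @param k window size in markers (default 4)
#' @param step offset between window starts
#' @return data.frame: window id, fragment, first/last site index (into
#'   \code{sites}), span_bp
#' @export
sliding_windows <- function(sites, k = 4L, step = 1L) {
  out <- list()
  for (fr in unique(sites$fragment)) {
    idx <- which(sites$fragment == fr)
    idx <- idx[order(sites$pos[idx])]
    if (length(idx) < k) next
    starts <- seq(1L, length(idx) - k + 1L, by = step)
    out[[fr]] <- data.frame(
      fragment = fr,
      first = idx[starts], last = idx[starts + k - 1L],
      span_bp = sites$pos[idx[starts + k - 1L]] - sites$pos[idx[starts]] + 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(window = character(0), fragment = character(0),
                      first = integer(0), last = integer(0),
                      span_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cbind(window = sprintf("%s:w%03d", res$fragment,
                         stats::ave(seq_len(nrow(res)), res$fragment,
                                    FUN = seq_along)),
        res)
}

#' Impute missing genotypes and assemble phased haplotypes
#'
#' Sites are chunked per fragment into consecutive windows (overlapping by
#' one site), each chunk is phased by \code{\link{em_haplotype_frequencies}},
#' missing genotypes are replaced by the posterior-mode diplotype, and
#' chunk phases are chained through the shared site (orientation kept when
#' the shared site is homozygous, which leaves phase locally ambiguous but
#' deterministic). Observed genotypes are never altered.
#'
#' @param genotypes a \code{genotype_matrix}
#' @param k chunk size in sites (2..8)
#' @param seed RNG seed passed to the EM restarts
#' @param refine refine imputed genotypes with a fragment-wide haplotype
#'   library pass (see Details)
#' @details After the chunked EM pass, a second pass collects the
#'   assembled fragment haplotypes into a frequency-weighted library and
#'   re-imputes each missing genotype from the posterior over library
#'   haplotype pairs compatible with the individual's observed genotypes
#'   across the whole fragment. This recovers long-range context the
#'   8-site enumeration bound discards (a PHASE-like copying shortcut),
#'   which matters when individuals are mosaics of a modest founder pool.
#' @return list: \code{genotypes} (completed matrix), \code{haplotypes}
#'   (per-fragment binary matrices, 2 rows per individual)
#' @export
impute_missing <- function(genotypes, k = 7L, overlap = 3L, seed = 1L,
                           refine = TRUE) {
  stopifnot(k >= 2L, k <= 8L, overlap >= 1L, overlap < k)
  gm <- genotypes
  haps <- list()
  for (fr in unique(gm$sites$fragment)) {
    idx <- which(gm$sites$fragment == fr)
    idx <- idx[order(gm$sites$pos[idx])]
    n <- nrow(gm$geno)
    ph <- matrix(NA_integer_, 2L * n, length(idx))
    rows1 <- seq(1L, 2L * n, 2L); rows2 <- rows1 + 1L
    chunk_start <- 1L
    n_shared <- 0L
    repeat {
      chunk <- chunk_start:min(chunk_start + k - 1L, length(idx))
      sub <- gm$geno[, idx[chunk], drop = FALSE]
      ht <- em_haplotype_frequencies(sub, n_restarts = 0L, seed = seed)
      mode <- diplotype_mode(ht, sub)
      # fill missing genotypes from the mode diplotype
      fill <- is.na(sub)
      sub[fill] <- (mode$h1 + mode$h2)[fill]
      gm$geno[, idx[chunk]] <- sub
      # chain orientation through the shared overlap: flip when the new
      # chunk's phase disagrees with the previous assembly at more
      # shared sites than the flipped orientation does (all-homozygous
      # overlaps tie and keep the current orientation)
      h1 <- mode$h1; h2 <- mode$h2
      if (n_shared > 0L) {
        ov <- seq_len(n_shared)
        prev1 <- ph[rows1, chunk[ov], drop = FALSE]
        mis_keep <- rowSums(h1[, ov, drop = FALSE] != prev1)
        mis_flip <- rowSums(h2[, ov, drop = FALSE] != prev1)
        flip <- mis_flip < mis_keep
        tmp <- h1[flip, , drop = FALSE]
        h1[flip, ] <- h2[flip, , drop = FALSE]
        h2[flip, ] <- tmp
      }
      new_cols <- if (n_shared > 0L) chunk[-seq_len(n_shared)] else chunk
      sel <- (n_shared + 1L):ncol(h1)
      ph[rows1, new_cols] <- h1[, sel, drop = FALSE]
      ph[rows2, new_cols] <- h2[, sel, drop = FALSE]
      if (chunk[length(chunk)] == length(idx)) break
      n_shared <- min(overlap, length(chunk) - 1L)
      chunk_start <- chunk[length(chunk)] - n_shared + 1L
    }
    rownames(ph) <- paste0(rep(gm$individuals, each = 2L), "_",
                           rep(1:2, n))
    haps[[fr]] <- ph
    if (refine && anyNA(genotypes$geno[, idx])) {
      for (pass in 1:2) {   # second pass benefits from the cleaner library
        upd <- refine_from_library(genotypes$geno[, idx, drop = FALSE],
                                   ph)
        gm$geno[, idx] <- upd$geno
        if (!length(upd$changed)) break
        for (i in upd$changed) {
          ph[2L * i - 1L, ] <- upd$h1[i, ]
          ph[2L * i, ] <- upd$h2[i, ]
        }
        haps[[fr]] <- ph
      }
    }
  }
  list(genotypes = gm, haplotypes = haps)
}

# second-pass imputation: posterior over pairs of library haplotypes
# (assembled fragment haplotypes weighted by frequency) compatible with
# the observed genotypes; falls back to the chunked fill when no pair is
# compatible
refine_from_library <- function(obs, ph) {
  n <- nrow(obs)
  lib <- unique(ph)
  cnt <- integer(nrow(lib))
  keys_all <- apply(ph, 1, paste, collapse = "")
  keys_lib <- apply(lib, 1, paste, collapse = "")
  cnt <- as.integer(table(factor(keys_all, levels = keys_lib)))
  freq <- cnt / sum(cnt)
  H <- nrow(lib)
  geno_out <- ph[seq(1, 2 * n - 1, 2), , drop = FALSE] +
    ph[seq(2, 2 * n, 2), , drop = FALSE]
  h1 <- ph[seq(1, 2 * n - 1, 2), , drop = FALSE]
  h2 <- ph[seq(2, 2 * n, 2), , drop = FALSE]
  changed <- integer(0)
  for (i in seq_len(n)) {
    mis <- is.na(obs[i, ])
    if (!any(mis)) next
    g_obs <- obs[i, !mis]
    sub <- lib[, !mis, drop = FALSE]
    best_w <- -1; best <- NULL
    post <- matrix(0, 3, sum(mis))      # genotype posterior at missing sites
    for (a in seq_len(H)) {
      # pair must reproduce every observed genotype
      need <- g_obs - sub[a, ]
      if (any(need < 0L | need > 1L)) next
      ok_b <- which(colSums(abs(t(sub) - need)) == 0)
      for (b in ok_b) {
        w <- freq[a] * freq[b]
        gmis <- lib[a, mis] + lib[b, mis]
        post[cbind(gmis + 1L, seq_len(sum(mis)))] <-
          post[cbind(gmis + 1L, seq_len(sum(mis)))] + w
        if (w > best_w) { best_w <- w; best <- c(a, b) }
      }
    }
    if (is.null(best)) next
    # fill each missing genotype with its marginal posterior mode; phase
    # from the best-weight pair (both agree at unambiguous sites)
    geno_out[i, mis] <- apply(post, 2, which.max) - 1L
    h1[i, ] <- lib[best[1], ]; h2[i, ] <- lib[best[2], ]
    changed <- c(changed, i)
  }
  list(geno = geno_out, h1 = h1, h2 = h2, changed = changed)
}

# posterior-mode diplotype per individual (ties broken by lowest h1, h2)
diplotype_mode <- function(ht, geno) {
  k <- ht$n_sites
  n <- nrow(geno)
  f <- stats::setNames(ht$freq, ht$haplotypes)
  h1 <- matrix(0L, n, k); h2 <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    pp <- compatible_pairs(geno[i, ])
    lab1 <- bits_of(pp[, 1], k); lab2 <- bits_of(pp[, 2], k)
    key1 <- apply(lab1, 1, paste, collapse = "")
    key2 <- apply(lab2, 1, paste, collapse = "")
    w <- unname(f[key1]) * unname(f[key2])
    w[is.na(w)] <- 0
    # canonical order: h1 <= h2 numerically; tie-break lexicographic
    swap <- pp[, 1] > pp[, 2]
    hh <- pp
    hh[swap, ] <- pp[swap, 2:1]
    ord <- order(-w, hh[, 1], hh[, 2])
    bsel <- ord[1]
    h1[i, ] <- bits_of(hh[bsel, 1], k)
    h2[i, ] <- bits_of(hh[bsel, 2], k)
  }
  list(h1 = h1, h2 = h2)
}

bits_of <- function(h, k) {
  m <- vapply((k - 1L):0, function(b) bitwAnd(bitwShiftR(h, b), 1L),
              integer(length(h)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

#' Haplotype trend regression with permutation p-value
#'
#' Regresses a trait on the posterior dosages of the window's common
#' haplotypes (frequency > \code{rare_threshold}; rarer haplotypes are
#' pooled into one column, and the most frequent haplotype is dropped as
#' the baseline for identifiability). Significance of the overall F
#' statistic is assessed by permuting trait values, with the add-one
#' correction p = (1 + #{F* >= F}) / (1 + n_perm).
#'
#' @param haps a \code{haplotype_table}
#' @param trait numeric trait vector aligned with the dosage rows
#' @param n_perm permutations (default 1000)
#' @param rare_threshold frequency below which haplotypes are pooled
#' @param seed RNG seed for the permutations
#' @return list: f, p, r2, df, common haplotypes used; NA result when
#'   fewer than two common haplotypes exist
#' @export
htr_test <- function(haps, trait, n_perm = 1000L, rare_threshold = 0.01,
                     seed = 1L) {
  stopifnot(length(trait) == nrow(haps$dosage))
  keep_ind <- !is.na(trait)
  y <- trait[keep_ind]
  D <- haps$dosage[keep_ind, , drop = FALSE]
  common <- haps$freq > rare_threshold
  if (sum(common) < 2L) {
    return(list(f = NA_real_, p = NA_real_, r2 = NA_real_,
                df = c(NA, NA), common = haps$haplotypes[common]))
  }
  Dc <- D[, common, drop = FALSE]
  if (any(!common)) {
    Dc <- cbind(Dc, pooled_rare = rowSums(D[, !common, drop = FALSE]))
  }
  base <- which.max(haps$freq[common])
  X <- cbind(1, Dc[, -base, drop = FALSE])
  qx <- qr(X)
  q1 <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  n <- length(y)
  p1 <- qx$rank
  q_df <- p1 - 1L
  rss <- function(yy) {
    tot <- sum((yy - mean(yy))^2)
    r1 <- max(sum(yy^2) - colSums(crossprod(q1, matrix(yy))^2), 0)
    c(tot, r1)
  }
  f_stat <- function(yy) {
    r <- rss(yy)
    num <- max(r[1] - r[2], 0) / q_df
    den <- r[2] / (n - p1)
    if (den <= num * 1e-12) Inf else num / den
  }
  f_obs <- f_stat(y)
  r <- rss(y)
  r2 <- 1 - r[2] / r[1]
  set.seed(seed)
  # all permutations at once: RSS via projections on the design's Q basis
  Yp <- vapply(seq_len(n_perm), function(b) sample(y), numeric(n))
  tot_p <- colSums(sweep(Yp, 2, colMeans(Yp))^2)
  r1_p <- pmax(colSums(Yp^2) - colSums(crossprod(q1, Yp)^2), 0)
  num_p <- pmax(tot_p - r1_p, 0) / q_df
  den_p <- r1_p / (n - p1)
  perm_f <- ifelse(den_p <= num_p * 1e-12, Inf, num_p / den_p)
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_perm)
  list(f = f_obs, p = p, r2 = r2, df = c(q_df, n - p1),
       common = haps$haplotypes[common],
       common_freq = haps$freq[common])
}
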