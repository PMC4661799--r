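#' Pairwise r-squared within fragments
#'
#' Squared allele-frequency correlation between pairs of sites on the same
#' fragment, r2 = D^2 / (pA (1-pA) pB (1-pB)), computed from haplotype
#' frequencies. Input is either a phased haplotype set (binary matrix per
#' fragment) or a \code{genotype_matrix}, in which case two-site haplotype
#' frequencies are estimated by an EM over the nine genotype combinations
#' (the double heterozygote being the only ambiguous one).
#'
#' @param x named list of binary haplotype matrices (sequences x sites,
#'   one per fragment, columns ordered by position) or a
#'   \code{genotype_matrix}
#' @param positions list of site positions per fragment (required for the
#'   haplotype-list input; taken from metadata for a genotype matrix)
#' @param maf_min sites with folded frequency <= maf_min are excluded
#'   (strict >, default 0.1)
#' @return data.frame: fragment, site_a, site_b, dist (bp), r2
#' @export
pairwise_r2 <- function(x, positions = NULL, maf_min = 0.1) {
  if (inherits(x, "genotype_matrix")) {
    frs <- unique(x$sites$fragment)
    out <- lapply(frs, function(fr) {
      idx <- which(x$sites$fragment == fr)
      geno <- x$geno[, idx, drop = FALSE]
      p <- colMeans(geno, na.rm = TRUE) / 2
      keep <- pmin(p, 1 - p) > maf_min
      r2_table(fr, geno[, keep, drop = FALSE],
               x$sites$pos[idx][keep], phased = FALSE)
    })
  } else {
    stopifnot(is.list(x), !is.null(positions))
    out <- lapply(names(x), function(fr) {
      haps <- x[[fr]]
      p <- colMeans(haps)
      keep <- pmin(p, 1 - p) > maf_min
      r2_table(fr, haps[, keep, drop = FALSE],
               positions[[fr]][keep], phased = TRUE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

r2_table <- function(fr, mat, pos, phased) {
  m <- ncol(mat)
  if (m < 2L) {
    return(data.frame(fragment = character(0), site_a = integer(0),
                      site_b = integer(0), dist = numeric(0),
                      r2 = numeric(0)))
  }
  pairs <- utils::combn(m, 2)
  r2 <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    r2[q] <- if (phased) hap_r2(mat[, i], mat[, j])
             else geno_pair_r2(mat[, i], mat[, j])
  }
  data.frame(fragment = fr, site_a = pos[pairs[1, ]],
             site_b = pos[pairs[2, ]],
             dist = abs(pos[pairs[2, ]] - pos[pairs[1, ]]), r2 = r2,
             stringsAsFactors = FALSE)
}

# r2 from phased haplotypes
hap_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  pa <- mean(a); pb <- mean(b)
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) return(NA_real_)
  D <- mean(a * b) - pa * pb
  D^2 / den
}

# two-site EM from unphased genotypes (Haploview-style): only the double
# heterozygote is phase-ambiguous; iterate expected haplotype counts
geno_pair_r2 <- function(ga, gb, tol = 1e-10, max_iter = 200) {
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  n2 <- 2 * length(ga)
  if (n2 == 0) return(NA_real_)
  # h = freq of the (1,1) haplotype; individuals that are not doubly
  # heterozygous have a determined phase and contribute fixed counts
  n_dh <- sum(ga == 1L & gb == 1L)
  det <- !(ga == 1L & gb == 1L)
  a_d <- ga[det]; b_d <- gb[det]
  n11 <- sum(vapply(seq_along(a_d), function(i) {
    x <- a_d[i]; y <- b_d[i]
    if (x == 2 && y == 2) return(2)
    if (x == 2) return(y)       # y in {0,1}: y copies of (1,1)
    if (y == 2) return(x)
    0                            # one or both hom-ref with <=1 het
  }, numeric(1)))
  pa <- sum(ga) / n2; pb <- sum(gb) / n2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  h <- pa * pb
  for (it in seq_len(max_iter)) {
    # double het: P(coupling 11/00) vs repulsion 10/01
    p11 <- h; p00 <- 1 - pa - pb + h
    p10 <- pa - h; p01 <- pb - h
    num <- p11 * p00
    den <- p11 * p00 + p10 * p01
    w <- if (den > 0) num / den else 0.5
    h_new <- (n11 + n_dh * w) / n2
    h_new <- min(max(h_new, max(0, pa + pb - 1)), min(pa, pb))
    if (abs(h_new - h) < tol) { h <- h_new; break }
    h <- h_new
  }
  D <- h - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Expected r-squared under the mutation-recombination drift model
#'
#' E(r2) = [(10 + C)/((2 + C)(11 + C))] x
#' [1 + ((1 + C)(12 + 12C + C^2))/(n (2 + C)(11 + C))], where C is the
#' scaled recombination parameter for the pair's distance and n the sample
#' size; decreasing in C, approaching (10+C)/((2+C)(11+C)) as n grows.
#'
#' @param C scaled recombination rate (>= 0); vectorised
#' @param n sample size (>= 2)
#' @return expected r2
#' @export
expected_r2 <- function(C, n) {
  stopifnot(all(C >= 0), n >= 2)
  t1 <- (10 + C) / ((2 + C) * (11 + C))
  t2 <- 1 + ((1 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C))
  t1 * t2
}

#' Fit the LD-decay curve
#'
#' Least-squares estimate of the single per-bp recombination coefficient
#' C_hat with C(d) = C_hat x d, minimising the squared deviation of the
#' observed pairwise r2 values from \code{\link{expected_r2}}. Optimised on
#' a log grid then refined by Brent; a boundary solution C_hat = 0 is
#' reported as such.
#'
#' @param pairs data.frame from \code{\link{pairwise_r2}} (uses dist, r2)
#' @param n sample size behind the r2 estimates
#' @return object of class \code{ld_decay_fit}: c_hat, n, rss, fitted
#'   function, half_length (bp; see \code{\link{ld_half_length}})
#' @export
fit_ld_decay <- function(pairs, n) {
  pairs <- pairs[is.finite(pairs$r2) & pairs$dist > 0, , drop = FALSE]
  if (nrow(pairs) < 10L) {
    stop("need at least 10 site pairs to fit the decay curve",
         call. = FALSE)
  }
  obj <- function(c_hat) {
    sum((pairs$r2 - expected_r2(c_hat * pairs$dist, n))^2)
  }
  # bracket on a log grid, then refine
  grid <- c(0, 10^seq(-8, 1, by = 0.25))
  vals <- vapply(grid, obj, numeric(1))
  best <- which.min(vals)
  if (best == 1L) {
    # boundary: compare against a tiny interior refinement
    op <- stats::optimize(obj, c(0, grid[2]))
    c_hat <- if (op$objective < vals[1]) op$minimum else 0
  } else {
    lo <- grid[max(best - 1L, 1L)]
    hi <- grid[min(best + 1L, length(grid))]
    op <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
    c_hat <- op$minimum
  }
  fit <- structure(list(c_hat = c_hat, n = n, rss = obj(c_hat),
                        n_pairs = nrow(pairs),
                        curve = function(d) expected_r2(c_hat * d, n)),
                   class = "ld_decay_fit")
  fit$half_length <- ld_half_length(fit)
  fit
}

#' Distance at which the fitted r2 curve halves
#'
#' Solves E(r2)(d) = 0.5 x E(r2)(d = 1) by bisection on the fitted decay
#' curve (baseline at 1 bp, i.e. the curve's short-range value). NA when
#' the curve is flat (C_hat = 0).
#'
#' @param fit an \code{ld_decay_fit}
#' @param d_max upper search bound in bp
#' @return half-length in bp
#' @export
ld_half_length <- function(fit, d_max = 1e7) {
  if (fit$c_hat <= 0) return(NA_real_)
  target <- fit$curve(1) / 2
  f <- function(d) fit$curve(d) - target
  lo <- 1; hi <- 2
  while (f(hi) > 0 && hi < d_max) hi <- hi * 2
  if (f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf(
    "LD decay fit: C_hat = %.3g per bp (n = %d, %d pairs); half-length = %.0f bp\n",
    x$c_hat, x$n, x$n_pairs,
    if (is.na(x$half_length)) NA else x$half_length))
  invisible(x)
}
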