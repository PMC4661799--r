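#' Neutral coalescent sample under the infinite-sites model
#'
#' Simulates one standard (constant-size, no recombination) coalescent
#' genealogy of \code{n} sequences and sprinkles mutations at rate
#' \code{theta}/2 per lineage per unit of coalescent time; each mutation
#' creates one segregating site carried by the descendants of the lineage
#' it hits. Used to obtain the null distribution of Fu's Fs and as an
#' independent neutral-world oracle in the test suite.
#'
#' @param n number of sequences (>= 2)
#' @param theta population mutation rate (per locus)
#' @param growth optional exponential growth rate in coalescent units;
#'   positive values shorten ancient coalescent intervals, producing
#'   star-like genealogies (excess rare variants, negative Fs)
#' @return binary matrix (n x S) of derived-allele indicators
#' @export
sim_coalescent <- function(n, theta, growth = 0) {
  stopifnot(n >= 2, theta >= 0)
  lineages <- as.list(seq_len(n))
  carrier_stages <- vector("list", n - 1L)
  t_now <- 0
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    if (growth > 0) {
      # time change for exponential growth: solve for waiting time
      u <- stats::runif(1)
      dt <- log(1 - growth * exp(-growth * t_now) * log(u) / rate) / growth
    } else {
      dt <- stats::rexp(1, rate)
    }
    m <- stats::rpois(1L, k * theta / 2 * dt)
    if (m > 0L) {
      hit <- sample.int(k, m, replace = TRUE)
      carrier_stages[[k - 1L]] <- lineages[hit]
    }
    pair <- sample.int(k, 2L)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    t_now <- t_now + dt
    k <- k - 1L
  }
  carriers <- do.call(c, carrier_stages[!vapply(carrier_stages, is.null,
                                                TRUE)])
  if (is.null(carriers)) carriers <- list()
  # drop sites fixed in the sample (mutation on the root lineage)
  carriers <- carriers[lengths(carriers) < n]
  S <- length(carriers)
  haps <- matrix(0L, n, S)
  for (s in seq_len(S)) haps[carriers[[s]], s] <- 1L
  haps
}
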