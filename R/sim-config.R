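#' Configuration for the mass-cross amplicon simulator
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe a
#' grouper-style mass cross: 12 dams and 29 sires spawning together to give
#' 159 genotyped offspring, four candidate-gene amplicons of 4.3--5.6 kbp,
#' low nucleotide diversity (theta around 0.003 per site), linkage
#' disequilibrium that halves within roughly 2 kbp, two latent founder
#' subpopulations, and amplicon read depth with a fragment-effect variance
#' about 2.6 times the individual-effect variance.
#'
#' @param n_dams,n_sires,n_offspring pedigree counts.
#' @param fragments data.frame with columns \code{name} and \code{length}
#'   (bp). Defaults to the four candidate fragments (4756, 4852, 5550,
#'   4280 bp).
#' @param theta_per_site scaled mutation rate used to draw the number of
#'   segregating sites per fragment (Watterson expectation
#'   \code{theta * L * a_n}).
#' @param mix_rate per-bp rate at which the carrier-set permutation is
#'   shuffled along the sequence; controls how fast r-squared decays with
#'   distance (larger = faster decay).
#' @param count_cor probability that a site's derived-allele count is
#'   copied from the previous site instead of drawn fresh from the
#'   neutral spectrum; creates the block-like local haplotype structure
#'   (few common window haplotypes) seen in real amplicon data while
#'   leaving the marginal site-frequency spectrum neutral.
#' @param div_prop fraction of sites whose carriers are drawn from a
#'   deme-ordered (slowly within-deme-mixing) permutation, creating two
#'   divergent founder subpopulations whose marker sites are mutually
#'   correlated; \code{div_prop = 0} gives an unstructured (neutral)
#'   founder pool.
#' @param recomb_per_bp per-meiosis crossover probability per bp.
#' @param assort probability that a mating draws dam and sire from the same
#'   founder deme (assortative component creating offspring structure).
#' @param qtl list: \code{fragment} (index), \code{maf_target} (the QTL site
#'   is the segregating site with MAF closest to this), \code{a} additive
#'   effect (trait units per allele), \code{d} dominance deviation,
#'   \code{traits} character vector of affected traits (via the latent
#'   growth value).
#' @param h2_polygenic fraction of the non-QTL phenotypic variance that is
#'   polygenic (covariance proportional to pedigree kinship).
#' @param struct_shift additive mean shift (trait units) per unit of
#'   subpopulation ancestry.
#' @param sigma_env residual environmental SD (trait units of the latent
#'   growth value, cm of standard length).
#' @param n_subpops number of founder demes (only 1 or 2 supported).
#' @param depth_model list: \code{grand} mean fold depth, \code{ind_sd},
#'   \code{frag_sd}, \code{resid_sd} (log-scale effect SDs;
#'   \code{frag_sd^2/ind_sd^2} defaults to about 2.6), \code{taper_width}
#'   bp of linear ramp at each amplicon end, \code{base_cv} per-base
#'   log-normal dispersion.
#' @param missing_rate fraction of genotype calls masked to missing.
#' @param seed integer seed; fixed seed implies bit-identical output.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_dams = 12L, n_sires = 29L, n_offspring = 159L,
                       fragments = data.frame(
                         name = c("GHRH", "PRP-PACAPa", "PRP-PACAPb", "GHRHR"),
                         length = c(4756L, 4852L, 5550L, 4280L),
                         stringsAsFactors = FALSE),
                       theta_per_site = 0.003,
                       mix_rate = 0.005,
                       count_cor = 0.7,
                       div_prop = 0.15,
                       recomb_per_bp = 1e-6,
                       assort = 0.9,
                       qtl = list(fragment = 1L, maf_target = 0.25,
                                  a = 1.0, d = 0.4,
                                  traits = c("SL", "BWT", "TL", "MBD", "CPD")),
                       h2_polygenic = 0.30,
                       struct_shift = 0.5,
                       sigma_env = 1.5,
                       n_subpops = 2L,
                       depth_model = list(grand = 110, ind_sd = 0.35,
                                          frag_sd = 0.565, resid_sd = 0.25,
                                          taper_width = 150L, base_cv = 0.5),
                       missing_rate = 0.02,
                       seed = 20151102L) {
  cfg <- list(n_dams = check_count(n_dams, "n_dams"),
              n_sires = check_count(n_sires, "n_sires"),
              n_offspring = check_count(n_offspring, "n_offspring",
                                        zero_ok = TRUE),
              fragments = fragments, theta_per_site = theta_per_site,
              mix_rate = mix_rate, count_cor = count_cor,
              div_prop = div_prop,
              recomb_per_bp = recomb_per_bp,
              assort = assort, qtl = qtl, h2_polygenic = h2_polygenic,
              struct_shift = struct_shift, sigma_env = sigma_env,
              n_subpops = as.integer(n_subpops), depth_model = depth_model,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$fragments),
            all(c("name", "length") %in% names(cfg$fragments)))
  if (any(cfg$fragments$length <= 0)) {
    stop("fragment lengths must be positive", call. = FALSE)
  }
  if (cfg$theta_per_site < 0) stop("theta_per_site must be >= 0", call. = FALSE)
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic >= 1) {
    stop("h2_polygenic must be in [0, 1)", call. = FALSE)
  }
  if (cfg$recomb_per_bp < 0 || cfg$mix_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  dm <- cfg$depth_model
  if (any(unlist(dm[c("ind_sd", "frag_sd", "resid_sd", "base_cv")]) < 0)) {
    stop("depth-model SDs must be non-negative", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (!cfg$n_subpops %in% c(1L, 2L)) {
    stop("n_subpops must be 1 or 2", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Mass-cross simulation configuration\n")
  cat(sprintf("  founders: %d dams x %d sires; offspring: %d\n",
              x$n_dams, x$n_sires, x$n_offspring))
  cat(sprintf("  fragments: %s\n",
              paste(sprintf("%s (%d bp)", x$fragments$name,
                            x$fragments$length), collapse = ", ")))
  cat(sprintf("  theta/site: %g; mix rate: %g/bp; subpops: %d; seed: %d\n",
              x$theta_per_site, x$mix_rate, x$n_subpops, x$seed))
  invisible(x)
}
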