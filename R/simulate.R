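#' Simulate founder haplotypes for the mass-cross generator
#'
#' Draws, for each fragment, a Poisson number of segregating sites with
#' Watterson expectation \code{theta * L * a_n} (n = 2 x number of founders)
#' and places them uniformly (infinite-sites). Derived-allele counts are
#' drawn from the neutral frequency spectrum P(i) proportional to 1/i, so the
#' marginal site-frequency spectrum of the pool is neutral by construction.
#' Which haplotypes carry the derived allele is decided by a carrier-set
#' permutation that is reshuffled at rate \code{mix_rate} per bp along the
#' fragment: nearby sites share carrier sets (high r-squared) while distant
#' sites decorrelate, giving distance-dependent LD without a coalescent.
#' A fraction \code{div_prop} of sites instead draws carriers with a
#' deme-biased weight, creating two divergent founder subpopulations.
#'
#' @param config a \code{\link{sim_config}}
#' @return object of class \code{founder_pool}: per-fragment haplotype
#'   matrices (2 x founders rows, segregating sites columns), site tables,
#'   founder ids and deme labels.
#' @export
simulate_founder_haplotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_f <- config$n_dams + config$n_sires
  n_h <- 2L * n_f
  founder_ids <- c(sprintf("D%02d", seq_len(config$n_dams)),
                   sprintf("S%02d", seq_len(config$n_sires)))
  # deme label per founder individual; both haplotypes share it
  deme <- if (config$n_subpops == 2L) {
    rep_len(c(1L, 2L), n_f)[sample.int(n_f)]
  } else rep(1L, n_f)
  hap_deme <- rep(deme, each = 2L)
  a_n <- harmonic_a(n_h)
  sfs_p <- (1 / seq_len(n_h - 1L))
  sfs_p <- sfs_p / sum(sfs_p)
  nucs <- c("A", "C", "G", "T")

  frags <- vector("list", nrow(config$fragments))
  names(frags) <- config$fragments$name
  for (j in seq_len(nrow(config$fragments))) {
    L <- config$fragments$length[j]
    if (L <= 0) stop("zero-length fragment", call. = FALSE)
    S <- stats::rpois(1L, config$theta_per_site * L * a_n)
    S <- min(S, L)
    pos <- sort(sample.int(L, S))
    # derived-allele counts: fresh neutral-SFS draw, or copied from the
    # previous site (mutations on a shared genealogical background give
    # tightly linked sites near-identical frequencies); the marginal SFS
    # is the neutral one either way
    counts <- sample.int(n_h - 1L, S, replace = TRUE, prob = sfs_p)
    if (S > 1L && config$count_cor > 0) {
      copy <- stats::runif(S) < config$count_cor
      copy[1] <- FALSE
      for (s in which(copy)) counts[s] <- counts[s - 1L]
    }
    haps <- matrix(0L, n_h, S)
    perm <- sample.int(n_h)
    # deme-ordered permutation for structured sites: deme-1 haplotypes
    # occupy the front block, mixing only within demes, so divergent
    # sites stay correlated with each other and with local background
    perm_div <- c(sample(which(hap_deme == 1L)),
                  sample(which(hap_deme == 2L)))
    n1 <- sum(hap_deme == 1L)
    structured <- rep(FALSE, S)
    last_pos <- 0L
    for (s in seq_len(S)) {
      n_swap <- stats::rpois(1L, config$mix_rate * (pos[s] - last_pos))
      for (k in seq_len(n_swap)) {
        ij <- sample.int(n_h, 2L)
        perm[ij] <- perm[rev(ij)]
        blk <- if (stats::runif(1) < n1 / n_h) seq_len(n1)
               else (n1 + 1L):n_h
        if (length(blk) >= 2L) {
          uv <- sample(blk, 2L)
          perm_div[uv] <- perm_div[rev(uv)]
        }
      }
      last_pos <- pos[s]
      if (config$div_prop > 0 && stats::runif(1) < config$div_prop) {
        structured[s] <- TRUE
        c_s <- counts[s]
        carriers <- if (stats::runif(1) < 0.5) perm_div[seq_len(c_s)]
                    else perm_div[(n_h - c_s + 1L):n_h]
      } else {
        carriers <- perm[seq_len(counts[s])]
      }
      haps[carriers, s] <- 1L
    }
    ref <- sample(nucs, S, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L), "")
    rownames(haps) <- paste0(rep(founder_ids, each = 2L), "_",
                             rep(1:2, n_f))
    frags[[j]] <- list(name = config$fragments$name[j], length = L,
                       pos = pos, ref = ref, alt = unname(alt),
                       structured = structured, haps = haps)
  }
  structure(list(fragments = frags, founder_ids = founder_ids,
                 deme = stats::setNames(deme, founder_ids),
                 n_dams = config$n_dams, n_sires = config$n_sires),
            class = "founder_pool")
}

# one recombinant gamete from a founder's two haplotypes (0/1 vectors over
# the fragment's segregating sites); crossovers: Poisson count, uniform
# placement, no interference
recombine_gamete <- function(h1, h2, pos, L, recomb_per_bp) {
  n_x <- stats::rpois(1L, recomb_per_bp * L)
  cur <- sample(1:2, 1L)
  if (n_x == 0L || length(pos) == 0L) {
    return(list(g = if (cur == 1L) h1 else h2, n_crossovers = n_x))
  }
  breaks <- sort(stats::runif(n_x, 0, L))
  # phase index at each site = start phase + number of breaks before it
  phase <- (cur - 1L + findInterval(pos, breaks)) %% 2L + 1L
  g <- ifelse(phase == 1L, h1, h2)
  list(g = g, n_crossovers = n_x)
}

#' Drop gametes through the mass cross
#'
#' Each offspring draws a dam and a sire (with probability \code{assort}
#' both come from the same founder deme) and receives one recombinant
#' gamete per parent. Genotype codes count the derived (alt) allele.
#'
#' @param founders a \code{founder_pool}
#' @param config the \code{\link{sim_config}} used to create it
#' @return list with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{pedigree} (offspring, dam, sire), \code{haplotypes} (phased truth,
#'   2n x S matrix per fragment) and \code{ancestry} (mean parental deme-2
#'   fraction per offspring).
#' @export
simulate_mass_cross <- function(founders, config) {
  set.seed(config$seed + 1L)
  n_off <- config$n_offspring
  dams <- founders$founder_ids[seq_len(founders$n_dams)]
  sires <- founders$founder_ids[founders$n_dams + seq_len(founders$n_sires)]
  deme <- founders$deme
  off_ids <- sprintf("O%03d", seq_len(n_off))

  ped <- data.frame(offspring = off_ids,
                    dam = character(n_off), sire = character(n_off),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_off)) {
    if (config$n_subpops == 2L && stats::runif(1) < config$assort) {
      dm <- sample(1:2, 1L)
      d_pool <- dams[deme[dams] == dm]
      s_pool <- sires[deme[sires] == dm]
      if (!length(d_pool)) d_pool <- dams
      if (!length(s_pool)) s_pool <- sires
    } else {
      d_pool <- dams; s_pool <- sires
    }
    ped$dam[i] <- d_pool[sample.int(length(d_pool), 1L)]
    ped$sire[i] <- s_pool[sample.int(length(s_pool), 1L)]
  }

  hap_list <- list()
  geno_blocks <- list()
  site_blocks <- list()
  for (fr in founders$fragments) {
    S <- length(fr$pos)
    gam <- matrix(0L, 2L * n_off, max(S, 0L))
    for (i in seq_len(n_off)) {
      for (p in 1:2) {
        par <- if (p == 1L) ped$dam[i] else ped$sire[i]
        h1 <- fr$haps[paste0(par, "_1"), ]
        h2 <- fr$haps[paste0(par, "_2"), ]
        gam[2L * (i - 1L) + p, ] <-
          recombine_gamete(h1, h2, fr$pos, fr$length, config$recomb_per_bp)$g
      }
    }
    rownames(gam) <- if (n_off > 0L)
      paste0(rep(off_ids, each = 2L), "_", rep(1:2, n_off)) else NULL
    hap_list[[fr$name]] <- gam
    geno_blocks[[fr$name]] <-
      gam[2L * seq_len(n_off) - 1L, , drop = FALSE] +
      gam[2L * seq_len(n_off), , drop = FALSE]
    site_blocks[[fr$name]] <- data.frame(fragment = fr$name, pos = fr$pos,
                                         ref = fr$ref, alt = fr$alt,
                                         stringsAsFactors = FALSE)
  }
  geno <- do.call(cbind, geno_blocks)
  sites <- do.call(rbind, site_blocks)
  gm <- genotype_matrix(geno, sites, off_ids)
  ancestry <- (as.numeric(deme[ped$dam] == 2L) +
               as.numeric(deme[ped$sire] == 2L)) / 2
  list(genotypes = gm, pedigree = ped, haplotypes = hap_list,
       ancestry = stats::setNames(ancestry, off_ids))
}

#' Expected (pedigree) kinship of the simulated cohort
#'
#' Founders are treated as unrelated and non-inbred, so offspring kinship is
#' 0.25 for full sibs, 0.125 for half sibs, 0 otherwise; the diagonal is 0.5.
#' The result is symmetric positive semidefinite.
#'
#' @param pedigree data.frame with offspring, dam, sire
#' @return n x n kinship matrix
#' @export
pedigree_kinship <- function(pedigree) {
  n <- nrow(pedigree)
  same_dam <- outer(pedigree$dam, pedigree$dam, "==")
  same_sire <- outer(pedigree$sire, pedigree$sire, "==")
  K <- 0.125 * (same_dam + same_sire)
  diag(K) <- 0.5
  dimnames(K) <- list(pedigree$offspring, pedigree$offspring)
  K
}

#' Simulate the 12-trait phenotype table
#'
#' A latent growth value y0 = a (x - 1) + d [x = 1] + polygenic + ancestry
#' shift + environmental noise (x = QTL genotype code) drives standard
#' length; the remaining morphometrics are allometric functions of SL with
#' trait-specific noise, body weight scales as SL^2.8 (so condition factor
#' K = 100 BWT / SL^3 correlates negatively with SL), and K is computed,
#' not drawn.
#'
#' @param genotypes \code{genotype_matrix} of the offspring
#' @param kinship truth kinship (e.g. \code{\link{pedigree_kinship}})
#' @param config a \code{\link{sim_config}}
#' @param ancestry optional per-individual deme-2 fraction for the
#'   structured mean shift
#' @param exclude_sites site indices ineligible as the QTL (used to keep
#'   the QTL off pure deme-marker sites)
#' @return list: \code{phenotypes} data.frame (individual_id + 12 traits),
#'   \code{truth} (QTL site, effects, realized marker R^2 on SL, latent
#'   components)
#' @export
simulate_phenotypes <- function(genotypes, kinship, config, ancestry = NULL,
                                exclude_sites = NULL) {
  set.seed(config$seed + 2L)
  n <- nrow(genotypes$geno)
  qtl <- config$qtl
  frag_names <- unique(genotypes$sites$fragment)
  frag <- frag_names[min(qtl$fragment, length(frag_names))]
  idx_frag <- which(genotypes$sites$fragment == frag)
  # the QTL segregates within demes: deme-marker sites are not eligible
  if (!is.null(exclude_sites)) {
    idx_keep <- setdiff(idx_frag, exclude_sites)
    if (length(idx_keep)) idx_frag <- idx_keep
  }
  if (!length(idx_frag)) stop("QTL fragment has no sites", call. = FALSE)
  maf <- site_maf(genotypes)[idx_frag]
  qtl_idx <- idx_frag[which.min(abs(maf - qtl$maf_target))]
  x <- genotypes$geno[, qtl_idx]
  x[is.na(x)] <- round(mean(x, na.rm = TRUE))
  if (stats::var(x) == 0) {
    warning("QTL site is monomorphic; phenotype carries no marker signal")
  }
  qtl_term <- qtl$a * (x - 1) + qtl$d * (x == 1)

  # polygenic: var h2/(1-h2) * sigma_env^2, covariance 2 * kinship
  sig_e2 <- config$sigma_env^2
  sig_g2 <- config$h2_polygenic / (1 - config$h2_polygenic) * sig_e2
  u <- if (sig_g2 > 0) {
    Kc <- 2 * kinship + diag(1e-8, n)
    drop(crossprod(chol(Kc), stats::rnorm(n)) * sqrt(sig_g2))
  } else rep(0, n)
  shift <- if (is.null(ancestry)) 0 else config$struct_shift * ancestry
  e <- stats::rnorm(n, 0, config$sigma_env)
  y0 <- qtl_term + u + shift + e

  SL <- 17 + y0
  rn <- function(sd) stats::rnorm(n, 0, sd)
  TL  <- 1.18 * SL + rn(0.20)
  HL  <- 0.30 * SL + rn(0.10)
  MBD <- 0.33 * SL + rn(0.12)
  BW  <- 0.16 * SL + rn(0.06)
  CPL <- 0.18 * SL + rn(0.06)
  CPD <- 0.12 * SL + rn(0.04)
  SNL <- 0.07 * SL + rn(0.02)
  ED  <- 0.05 * SL + rn(0.012)
  ID  <- 0.06 * SL + rn(0.02)
  BWT <- 0.04 * SL^2.8 * exp(rn(0.05))
  K   <- condition_factor(BWT, SL)
  ph <- data.frame(individual_id = genotypes$individuals,
                   BWT = BWT, MBD = MBD, TL = TL, SL = SL, HL = HL, BW = BW,
                   CPL = CPL, CPD = CPD, SNL = SNL, ED = ED, ID = ID, K = K,
                   stringsAsFactors = FALSE)
  realized_r2 <- stats::var(qtl_term) / stats::var(SL)
  list(phenotypes = ph,
       truth = list(qtl_site = genotypes$sites$site_id[qtl_idx],
                    qtl_index = qtl_idx, a = qtl$a, d = qtl$d,
                    realized_r2 = realized_r2,
                    polygenic = u, latent = y0))
}

#' Simulate per-base amplicon depth profiles
#'
#' Per amplicon (individual x fragment) the mean fold depth is log-normal:
#' log depth = log(grand) + b_i + c_j + eps with independent normal effects
#' (individual, fragment, residual). Per-base depth is the amplicon mean
#' scaled by a linear taper ramp of \code{taper_width} bp at each end
#' (normalised so the across-positions mean equals the amplicon mean) times
#' a per-base log-normal factor with SD \code{base_cv}, rounded to integer.
#'
#' @param config a \code{\link{sim_config}}
#' @param individuals ids (defaults to the offspring ids implied by config)
#' @return object of class \code{depth_profile}: list with \code{depths}
#'   (per-fragment integer matrices, individuals x positions) and
#'   \code{means} (individuals x fragments amplicon mean depth)
#' @export
simulate_depth_profiles <- function(config, individuals = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  dm <- config$depth_model
  if (is.null(individuals)) {
    individuals <- sprintf("O%03d", seq_len(config$n_offspring))
  }
  n <- length(individuals)
  J <- nrow(config$fragments)
  b <- stats::rnorm(n, 0, dm$ind_sd)
  cc <- stats::rnorm(J, 0, dm$frag_sd)
  eps <- matrix(stats::rnorm(n * J, 0, dm$resid_sd), n, J)
  means <- exp(log(dm$grand) + outer(b, cc, "+") + eps)
  dimnames(means) <- list(individuals, config$fragments$name)

  depths <- vector("list", J)
  names(depths) <- config$fragments$name
  for (j in seq_len(J)) {
    L <- config$fragments$length[j]
    tap <- taper_profile(L, dm$taper_width)
    mat <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      mu <- means[i, j] * tap
      d <- if (dm$base_cv > 0) mu * exp(stats::rnorm(L, 0, dm$base_cv)) else mu
      mat[i, ] <- as.integer(round(d))
    }
    rownames(mat) <- individuals
    depths[[j]] <- mat
  }
  structure(list(depths = depths, means = means,
                 fragments = config$fragments),
            class = "depth_profile")
}

# linear ramp of width w at each end, normalised to mean 1 over the fragment
taper_profile <- function(L, w) {
  pos <- seq_len(L)
  t <- if (w > 0) pmin(1, pos / w, (L + 1 - pos) / w) else rep(1, L)
  t / mean(t)
}

#' Simulate a complete mass-cross dataset
#'
#' Runs founders -> gene drop -> phenotypes -> depths, injects missing
#' genotypes uniformly at \code{missing_rate}, builds reference sequences
#' and a small exon/intron gene model per fragment, and packs the truth
#' needed by downstream tests (QTL effects, pedigree kinship, subpopulation
#' labels, phased haplotypes).
#'
#' @param config a \code{\link{sim_config}}
#' @return object of class \code{sim_dataset}
#' @export
simulate_dataset <- function(config = sim_config()) {
  founders <- simulate_founder_haplotypes(config)
  cross <- simulate_mass_cross(founders, config)
  K <- pedigree_kinship(cross$pedigree)
  structured_sites <- which(unlist(lapply(founders$fragments,
                                          function(f) f$structured)))
  ph <- simulate_phenotypes(cross$genotypes, K, config, cross$ancestry,
                            exclude_sites = structured_sites)
  depths <- simulate_depth_profiles(config)

  set.seed(config$seed + 4L)
  site_pos <- lapply(founders$fragments, function(f) f$pos)
  refmod <- simulate_reference(config, site_pos)
  gm <- cross$genotypes
  # relabel ref/alt from the emitted reference sequence so VCF, FASTA and
  # gene model are mutually consistent (codes are allele counts either way)
  gm$sites$ref <- refmod$site_alleles$ref
  gm$sites$alt <- refmod$site_alleles$alt
  if (config$missing_rate > 0 && length(gm$geno)) {
    mask <- stats::runif(length(gm$geno)) < config$missing_rate
    gm$geno[matrix(mask, nrow(gm$geno))] <- NA_integer_
  }
  structure(list(
    genotypes = gm, phenotypes = ph$phenotypes, depths = depths,
    pedigree = cross$pedigree, reference = refmod$reference,
    gene_model = refmod$gene_model, config = config,
    truth = list(qtl = ph$truth, kinship = K,
                 subpop = founders$deme, ancestry = cross$ancestry,
                 structured_sites = structured_sites,
                 haplotypes = cross$haplotypes,
                 founder_haplotypes = lapply(founders$fragments,
                                             function(f) f$haps),
                 complete_genotypes = cross$genotypes)),
    class = "sim_dataset")
}

# reference nucleotide sequence per fragment plus a simple plus-strand gene
# model (3 exons; CDS length divisible by 3; no internal stop codons in the
# reference frame). Ref alleles are read off the sequence; alt alleles are
# chosen so that no exonic SNP creates a stop codon (keeps the Nei-Gojobori
# precondition satisfiable on simulated haplotypes).
simulate_reference <- function(config, site_pos) {
  nucs <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nucs, nucs, nucs, stringsAsFactors = FALSE),
                  1L, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  ok_codons <- setdiff(codons, stops)
  refs <- list(); rows <- list(); allele_rows <- list()
  for (j in seq_len(nrow(config$fragments))) {
    nm <- config$fragments$name[j]
    L <- config$fragments$length[j]
    pos <- site_pos[[nm]]
    seq_ <- sample(nucs, L, replace = TRUE)
    ex_len <- c(90L, 150L, 120L)
    gap <- max(50L, (L - 400L - sum(ex_len)) %/% 3L)
    starts <- cumsum(c(200L, ex_len[1] + gap, ex_len[2] + gap))
    ends <- starts + ex_len - 1L
    cds_pos <- unlist(Map(seq, starts, ends))
    cod <- sample(ok_codons, length(cds_pos) %/% 3L, replace = TRUE)
    cod[1] <- "ATG"
    seq_[cds_pos] <- unlist(strsplit(cod, ""))
    ref <- seq_[pos]
    alt <- character(length(pos))
    cds_index <- match(pos, cds_pos)          # NA for non-exonic sites
    for (s in seq_along(pos)) {
      choices <- setdiff(nucs, ref[s])
      if (!is.na(cds_index[s])) {
        ci <- cds_index[s]
        cod_id <- (ci - 1L) %/% 3L
        cpos <- cds_pos[cod_id * 3L + 1:3]
        off <- ci - cod_id * 3L
        ok <- vapply(choices, function(a) {
          trip <- seq_[cpos]; trip[off] <- a
          !(paste(trip, collapse = "") %in% stops)
        }, TRUE)
        if (any(ok)) choices <- choices[ok]
      }
      alt[s] <- sample(choices, 1L)
    }
    refs[[nm]] <- paste(seq_, collapse = "")
    rows[[nm]] <- data.frame(fragment = nm, feature = "CDS",
                             start = starts, end = ends, strand = "+",
                             stringsAsFactors = FALSE)
    allele_rows[[nm]] <- data.frame(fragment = nm, pos = pos,
                                    ref = ref, alt = alt,
                                    stringsAsFactors = FALSE)
  }
  list(reference = unlist(refs), gene_model = do.call(rbind, rows),
       site_alleles = do.call(rbind, allele_rows))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated mass-cross dataset\n")
  print(x$genotypes)
  cat(sprintf("  phenotypes: %d individuals x %d traits; QTL %s (a=%g, d=%g, realized R2=%.3f)\n",
              nrow(x$phenotypes), ncol(x$phenotypes) - 1L,
              x$truth$qtl$qtl_site, x$truth$qtl$a, x$truth$qtl$d,
              x$truth$qtl$realized_r2))
  invisible(x)
}
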