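#' Per-amplicon coverage statistics
#'
#' Mean fold depth over all fragment positions and sensitivity (physical
#' coverage): the fraction of positions sequenced to at least
#' \code{min_depth}-fold. Positions absent from the profile count as depth
#' zero.
#'
#' @param depths a \code{depth_profile}
#' @param min_depth effective-site threshold in fold coverage (default 10)
#' @return data.frame: individual, fragment, mean_depth, sensitivity
#' @export
compute_amplicon_stats <- function(depths, min_depth = 10) {
  out <- lapply(names(depths$depths), function(fr) {
    m <- depths$depths[[fr]]
    L <- ncol(m)
    if (L == 0L) stop("fragment '", fr, "' has zero length", call. = FALSE)
    data.frame(individual = rownames(m), fragment = fr,
               mean_depth = rowMeans(m),
               sensitivity = rowMeans(m >= min_depth),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call a genotype from the variant-supporting read fraction
#'
#' A variant/total read ratio within [0.10, 0.90] is a heterozygote; above
#' 0.90 a homozygous variant; below 0.10 homozygous reference. The interval
#' is closed at both ends.
#'
#' @param variant_depth reads supporting the variant allele
#' @param total_depth total reads at the site (>= 1)
#' @return integer vector of genotype codes (0, 1, 2)
#' @export
classify_genotype <- function(variant_depth, total_depth) {
  if (any(total_depth < 1)) stop("total depth must be >= 1", call. = FALSE)
  if (any(variant_depth > total_depth)) {
    stop("variant depth exceeds total depth", call. = FALSE)
  }
  if (any(variant_depth < 0)) stop("negative variant depth", call. = FALSE)
  ratio <- variant_depth / total_depth
  ifelse(ratio > 0.90, 2L, ifelse(ratio >= 0.10, 1L, 0L))
}

#' Default SNP-quality thresholds
#'
#' Phred base quality >= 20, map quality >= 20, per-genotype depth >= 10,
#' variant (site) quality >= 20, indels excluded.
#' @return named list of thresholds
#' @export
qc_thresholds <- function(min_base_q = 20, min_map_q = 20, min_depth = 10,
                          min_var_q = 20, drop_indels = TRUE) {
  list(min_base_q = min_base_q, min_map_q = min_map_q,
       min_depth = min_depth, min_var_q = min_var_q,
       drop_indels = drop_indels)
}

#' Filter variant records to the high-quality SNP set
#'
#' Site-level criteria (base quality, map quality, variant quality, indel
#' exclusion) reject a whole record; the depth criterion is applied per
#' individual genotype, setting calls below \code{min_depth} to missing.
#' A site is retained when at least one individual still carries a
#' high-quality variant (non-reference) genotype. Genotypes are re-called
#' from the variant-read fraction where allele depths are available.
#'
#' @param vcf result of \code{\link{read_vcf_genotypes}} (or a compatible
#'   list with genotypes, records, dp, ad_alt)
#' @param thresholds see \code{\link{qc_thresholds}}
#' @return list: \code{genotypes} filtered \code{genotype_matrix},
#'   \code{n_dropped_sites}, \code{n_masked_genotypes}, \code{log}
#'   per-site rejection reason
#' @export
filter_variants <- function(vcf, thresholds = qc_thresholds()) {
  rec <- vcf$records
  gm <- vcf$genotypes
  th <- thresholds
  reason <- rep(NA_character_, nrow(rec))
  ok <- rep(TRUE, nrow(rec))
  fail <- function(which, why) {
    newly <- which & ok
    reason[newly] <<- why
    ok <<- ok & !which
  }
  if (th$drop_indels) fail(rec$is_indel %in% TRUE, "indel")
  fail(!is.na(rec$bq) & rec$bq < th$min_base_q, "base_quality")
  fail(!is.na(rec$mq) & rec$mq < th$min_map_q, "map_quality")
  fail(!is.na(rec$qual) & rec$qual < th$min_var_q, "variant_quality")

  geno <- gm$geno
  # per-genotype depth: below threshold -> missing
  masked <- 0L
  if (!is.null(vcf$dp)) {
    low <- !is.na(vcf$dp) & vcf$dp < th$min_depth & !is.na(geno)
    masked <- sum(low)
    geno[low] <- NA_integer_
    # re-call genotypes from allele balance where read support is present
    if (!is.null(vcf$ad_alt)) {
      has <- !is.na(geno) & !is.na(vcf$dp) & vcf$dp >= 1 &
        !is.na(vcf$ad_alt)
      geno[has] <- classify_genotype(vcf$ad_alt[has], vcf$dp[has])
    }
  }
  # retention: >= 1 passing variant genotype
  any_var <- colSums(geno > 0L, na.rm = TRUE) > 0L
  fail(!any_var, "no_passing_variant")

  out <- genotype_matrix(geno[, ok, drop = FALSE],
                         gm$sites[ok, , drop = FALSE], gm$individuals)
  list(genotypes = out,
       n_dropped_sites = sum(!ok), n_masked_genotypes = masked,
       log = data.frame(site_id = gm$sites$site_id, kept = ok,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Extract common SNPs for association analysis
#'
#' Retains biallelic sites with MAF strictly greater than \code{maf_min}
#' and missing-data fraction strictly below \code{max_missing}; site order
#' is preserved. An empty result is legitimate.
#'
#' @param genotypes a \code{genotype_matrix}
#' @param maf_min minor-allele-frequency threshold (strict >, default 0.05)
#' @param max_missing missing-fraction threshold (strict <, default 0.20)
#' @return filtered \code{genotype_matrix}
#' @export
extract_common_snps <- function(genotypes, maf_min = 0.05,
                                max_missing = 0.20) {
  if (ncol(genotypes$geno) == 0L) return(genotypes)
  keep <- site_maf(genotypes) > maf_min &
    site_missing(genotypes) < max_missing
  keep[is.na(keep)] <- FALSE
  subset_sites(genotypes, keep)
}

#' Annotate sites by codon consequence
#'
#' Exonic SNPs are classified synonymous / non-synonymous by substituting
#' the alternate allele into the reference codon (standard genetic code);
#' everything outside CDS is silent (intron/UTR/intergenic). Minus-strand
#' CDS are handled by complementing. The gene model must have per-fragment
#' CDS lengths divisible by 3.
#'
#' @param genotypes a \code{genotype_matrix}
#' @param gene_model data.frame (fragment, feature, start, end, strand) or
#'   path to a GFF3 file
#' @param reference named character vector of fragment sequences or path to
#'   a FASTA file
#' @return the genotype matrix with \code{sites$class} filled in
#' @export
annotate_sites <- function(genotypes, gene_model, reference) {
  if (is.character(gene_model) && length(gene_model) == 1L) {
    gene_model <- read_gff3(gene_model)
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  gene_model <- gene_model[gene_model$feature == "CDS", , drop = FALSE]
  sites <- genotypes$sites
  cls <- rep("silent", nrow(sites))
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (fr in unique(sites$fragment)) {
    gmod <- gene_model[gene_model$fragment == fr, , drop = FALSE]
    if (!nrow(gmod)) next
    gmod <- gmod[order(gmod$start), ]
    minus <- all(gmod$strand == "-")
    cds_pos <- unlist(Map(seq, gmod$start, gmod$end))
    if (length(cds_pos) %% 3L != 0L) {
      stop("CDS length for fragment '", fr,
           "' is not divisible by 3; rejecting gene model", call. = FALSE)
    }
    if (minus) cds_pos <- rev(cds_pos)
    seq_ <- strsplit(reference[[fr]], "")[[1]]
    idx <- which(sites$fragment == fr)
    for (s in idx) {
      ci <- match(sites$pos[s], cds_pos)
      if (is.na(ci)) next
      cod_id <- (ci - 1L) %/% 3L
      trip_pos <- cds_pos[cod_id * 3L + 1:3]
      trip <- seq_[trip_pos]
      alt <- sites$alt[s]
      if (minus) { trip <- comp[trip]; alt <- comp[[alt]] }
      ref_cod <- paste(trip, collapse = "")
      trip[ci - cod_id * 3L] <- alt
      alt_cod <- paste(trip, collapse = "")
      cls[s] <- if (code[[ref_cod]] == code[[alt_cod]]) "synonymous"
                else "non-synonymous"
    }
  }
  genotypes$sites$class <- cls
  genotypes
}
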