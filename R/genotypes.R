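#' Genotype matrix container
#'
#' Individuals-by-sites matrix of biallelic genotype codes (0 = hom ref,
#' 1 = het, 2 = hom alt, NA = missing) plus per-site metadata. This is the
#' central exchange object between the QC, diversity, LD, haplotype and
#' association stages.
#'
#' @param geno integer matrix, individuals in rows, sites in columns.
#' @param sites data.frame with one row per column of \code{geno}; must
#'   contain \code{fragment}, \code{pos} (1-based), \code{ref}, \code{alt};
#'   optional \code{class} annotation (synonymous / non-synonymous /
#'   silent / intergenic).
#' @param individuals character vector of individual ids (defaults to
#'   rownames of \code{geno}).
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(geno, sites, individuals = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(individuals)) individuals <- sprintf("I%03d", seq_len(nrow(geno)))
  stopifnot(nrow(sites) == ncol(geno),
            all(c("fragment", "pos", "ref", "alt") %in% names(sites)))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(sites$class)) sites$class <- NA_character_
  if (is.null(sites$site_id)) {
    sites$site_id <- paste0(sites$fragment, ":", sites$pos)
  }
  rownames(geno) <- individuals
  colnames(geno) <- sites$site_id
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites, individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%d fragments)\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$sites$fragment))))
  mf <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.2f%%; MAF range: %s\n", 100 * mf,
              if (ncol(x$geno)) paste(signif(range(site_maf(x)), 3),
                                      collapse = " - ") else "NA"))
  invisible(x)
}

#' Per-site minor allele frequency
#'
#' Computed from non-missing genotype codes; always folded into [0, 0.5].
#' @param gm a \code{genotype_matrix}
#' @return numeric vector, one MAF per site
#' @export
site_maf <- function(gm) {
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-site missing-data fraction
#' @param gm a \code{genotype_matrix}
#' @return numeric vector in [0, 1]
#' @export
site_missing <- function(gm) colMeans(is.na(gm$geno))

# subset sites (logical or integer index), keeping metadata in step
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$geno[, keep, drop = FALSE],
                  gm$sites[keep, , drop = FALSE], gm$individuals)
}
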