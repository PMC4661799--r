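#' Write a simulated dataset to disk
#'
#' Emits the on-disk formats the analysis stages consume: a VCF 4.2 with
#' GT:DP:AD genotypes (positions 1-based, sorted within contig), a phenotype
#' TSV (individual_id + 12 traits), a long per-base depth TSV, the reference
#' FASTA, a GFF3 gene model and a truth JSON carrying the seed and the
#' planted QTL so a run can be reproduced and checked.
#'
#' @param dataset a \code{\link{simulate_dataset}} result
#' @param dir output directory (created if absent)
#' @param depth logical; write the (large) per-base depth table
#' @return invisibly, the named vector of file paths written
#' @export
write_dataset <- function(dataset, dir, depth = TRUE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             pheno = file.path(dir, "phenotypes.tsv"),
             depth = file.path(dir, "depth.tsv"),
             fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))

  write_vcf(dataset$genotypes, paths["vcf"], depths = dataset$depths)
  data.table::fwrite(dataset$phenotypes, paths["pheno"], sep = "\t")
  if (depth) {
    dt <- data.table::rbindlist(lapply(names(dataset$depths$depths),
      function(fr) {
        m <- dataset$depths$depths[[fr]]
        data.table::data.table(individual = rep(rownames(m), ncol(m)),
                               fragment = fr,
                               pos = rep(seq_len(ncol(m)), each = nrow(m)),
                               depth = as.vector(m))
      }))
    data.table::fwrite(dt, paths["depth"], sep = "\t")
  }
  writeLines(unlist(lapply(names(dataset$reference), function(nm) {
    c(paste0(">", nm),
      substring(dataset$reference[[nm]],
                seq(1, nchar(dataset$reference[[nm]]), 70),
                pmin(seq(1, nchar(dataset$reference[[nm]]), 70) + 69,
                     nchar(dataset$reference[[nm]]))))
  })), paths["fasta"])
  write_gff3(dataset$gene_model, paths["gff"])
  truth <- list(seed = dataset$config$seed,
                qtl_site = dataset$truth$qtl$qtl_site,
                qtl_a = dataset$truth$qtl$a, qtl_d = dataset$truth$qtl$d,
                realized_r2 = dataset$truth$qtl$realized_r2,
                subpop = as.list(dataset$truth$subpop),
                pedigree = dataset$pedigree)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# VCF 4.2 text emission; per-genotype DP taken from the depth profile at the
# site position when available, AD consistent with the genotype call
write_vcf <- function(gm, path, depths = NULL) {
  sites <- gm$sites
  n <- nrow(gm$geno)
  frag_len <- tapply(sites$pos, sites$fragment, max)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(frag_len),
                   as.integer(frag_len) + 10L),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- character(nrow(sites))
  ord <- order(match(sites$fragment, unique(sites$fragment)), sites$pos)
  for (k in seq_along(ord)) {
    s <- ord[k]
    g <- gm$geno[, s]
    dp <- if (!is.null(depths) &&
              sites$fragment[s] %in% names(depths$depths)) {
      depths$depths[[sites$fragment[s]]][, sites$pos[s]]
    } else rep(100L, n)
    ratio <- ifelse(is.na(g), 0, c(0.02, 0.5, 0.98)[g + 1L])
    ad_alt <- as.integer(round(dp * ratio))
    ad_ref <- pmax(dp - ad_alt, 0L)
    gt <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    lines[k] <- paste(c(sites$fragment[s], sites$pos[s], sites$site_id[s],
                        sites$ref[s], sites$alt[s], "60", "PASS",
                        "MQ=60;BQ=30", "GT:DP:AD",
                        paste0(gt, ":", dp, ":", ad_ref, ",", ad_alt)),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
}

write_gff3 <- function(gene_model, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tamplipop\t%s\t%d\t%d\t.\t%s\t%d\tID=%s",
                     gene_model$fragment, gene_model$feature,
                     gene_model$start, gene_model$end, gene_model$strand,
                     gff3_phase(gene_model),
                     paste0(gene_model$fragment, "_cds",
                            stats::ave(gene_model$start, gene_model$fragment,
                                       FUN = seq_along))))
  writeLines(lines, path)
}

# phase column: offset to the next codon start given cumulative CDS length
gff3_phase <- function(gene_model) {
  unlist(lapply(split(gene_model, gene_model$fragment), function(g) {
    g <- g[order(g$start), ]
    cum <- cumsum(c(0L, g$end - g$start + 1L))[seq_len(nrow(g))]
    (3L - cum %% 3L) %% 3L
  })[unique(gene_model$fragment)])
}

#' Read a VCF into a genotype matrix plus per-record QC fields
#'
#' Thin wrapper over \code{VariantAnnotation::readVcf} for VCFs carrying
#' GT, DP and AD genotype fields and MQ / BQ INFO tags (as written by
#' \code{\link{write_dataset}} or by a variant caller configured to emit
#' them). Multiallelic records are split by ALT allele; only SNP alleles are
#' retained as candidate records, with indels flagged for the filter.
#'
#' @param path VCF file
#' @return list: \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{records} data.frame of site-level QC fields (qual, mq, bq,
#'   is_indel), \code{dp}/\code{ad_alt} integer matrices (individuals x
#'   sites)
#' @export
read_vcf_genotypes <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt_list <- VariantAnnotation::alt(v)
  if (any(lengths(alt_list) != 1L)) {
    keep <- lengths(alt_list) == 1L
    v <- v[keep]; rr <- rr[keep]; alt_list <- alt_list[keep]
  }
  ref <- as.character(VariantAnnotation::ref(v))
  alt <- as.character(unlist(alt_list))
  gt <- VariantAnnotation::geno(v)$GT
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  dp <- VariantAnnotation::geno(v)$DP
  ad <- VariantAnnotation::geno(v)$AD
  ad_alt <- matrix(vapply(ad, function(x) {
    if (length(x) >= 2L && !all(is.na(x))) x[2L] else NA_integer_
  }, integer(1)), nrow(ad), ncol(ad), dimnames = dimnames(ad))
  info <- VariantAnnotation::info(v)
  sites <- data.frame(
    fragment = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr), ref = ref, alt = alt,
    stringsAsFactors = FALSE)
  records <- cbind(sites, data.frame(
    qual = as.numeric(rr$QUAL),
    mq = if (!is.null(info$MQ)) as.numeric(info$MQ) else NA_real_,
    bq = if (!is.null(info$BQ)) as.numeric(info$BQ) else NA_real_,
    is_indel = nchar(ref) != 1L | nchar(alt) != 1L))
  gm <- genotype_matrix(t(code), sites, colnames(gt))
  list(genotypes = gm, records = records,
       dp = t(dp), ad_alt = t(ad_alt))
}

#' Read a per-base depth TSV into a depth profile
#'
#' Expects columns individual, fragment, pos (1-based), depth. Positions
#' absent from the table count as depth 0 up to the declared fragment
#' length (defaults to the maximum observed position per fragment).
#'
#' @param path TSV file
#' @param fragment_lengths optional named vector of fragment lengths
#' @return a \code{depth_profile}
#' @export
read_depth_tsv <- function(path, fragment_lengths = NULL) {
  dt <- data.table::fread(path)
  stopifnot(all(c("individual", "fragment", "pos", "depth") %in% names(dt)))
  frs <- unique(dt$fragment)
  inds <- unique(dt$individual)
  depths <- list()
  for (fr in frs) {
    sub <- dt[dt$fragment == fr, ]
    L <- if (!is.null(fragment_lengths)) fragment_lengths[[fr]] else
      max(sub$pos)
    m <- matrix(0L, length(inds), L, dimnames = list(inds, NULL))
    m[cbind(match(sub$individual, inds), sub$pos)] <- as.integer(sub$depth)
    depths[[fr]] <- m
  }
  means <- vapply(depths, rowMeans, numeric(length(inds)))
  structure(list(depths = depths, means = means,
                 fragments = data.frame(name = frs,
                                        length = vapply(depths, ncol, 0L))),
            class = "depth_profile")
}

#' Read a gene model GFF3 (CDS features) into the internal table
#' @param path GFF3 file
#' @return data.frame fragment / feature / start / end / strand
#' @export
read_gff3 <- function(path) {
  dt <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("seqid", "source", "type", "start",
                                        "end", "score", "strand", "phase",
                                        "attributes"))
  data.frame(fragment = dt$seqid, feature = dt$type, start = dt$start,
             end = dt$end, strand = dt$strand, stringsAsFactors = FALSE)
}

#' Read a reference FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Read a dataset directory written by \code{\link{write_dataset}}
#' @param dir directory
#' @return list with genotypes, records, phenotypes, depths, gene_model,
#'   reference and truth
#' @export
read_dataset <- function(dir) {
  vcf <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  ph <- as.data.frame(data.table::fread(file.path(dir, "phenotypes.tsv")))
  depth_path <- file.path(dir, "depth.tsv")
  depths <- if (file.exists(depth_path)) read_depth_tsv(depth_path) else NULL
  list(genotypes = vcf$genotypes, records = vcf$records,
       dp = vcf$dp, ad_alt = vcf$ad_alt,
       phenotypes = ph, depths = depths,
       gene_model = read_gff3(file.path(dir, "genes.gff3")),
       reference = read_reference_fasta(file.path(dir, "reference.fa")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
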