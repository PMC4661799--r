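#' Pipeline stage parameters
#'
#' All analysis thresholds in one validated list; defaults are the
#' published criteria (base/map/variant quality 20, genotype depth 10,
#' MAF > 0.05 with < 20% missing for association, MAF > 0.1 for LD,
#' 4-marker sliding windows, 1000 permutations, FDR 0.05).
#'
#' @param qc see \code{\link{qc_thresholds}}
#' @param maf_min,max_missing common-SNP extraction thresholds
#' @param ld_maf MAF threshold for LD pairs
#' @param window_k sliding-window size in markers
#' @param n_perm HTR permutations
#' @param fs_reps coalescent replicates behind Fu's Fs p-values
#' @param boot_reps codon-bootstrap replicates for the dN/dS Z-test
#' @param k_max largest admixture K tried
#' @param fdr Q-value significance threshold echoed in the report
#' @param min_depth fold-depth threshold defining an effective site
#' @return named list of class \code{pipeline_params}
#' @export
pipeline_params <- function(qc = qc_thresholds(), maf_min = 0.05,
                            max_missing = 0.20, ld_maf = 0.1,
                            window_k = 4L, n_perm = 1000L,
                            fs_reps = 1000L, boot_reps = 1000L,
                            k_max = 4L, fdr = 0.05, min_depth = 10) {
  structure(list(qc = qc, maf_min = maf_min, max_missing = max_missing,
                 ld_maf = ld_maf, window_k = window_k, n_perm = n_perm,
                 fs_reps = fs_reps, boot_reps = boot_reps, k_max = k_max,
                 fdr = fdr, min_depth = min_depth),
            class = "pipeline_params")
}

#' Run the full candidate-gene analysis pipeline
#'
#' Orchestrates simulate -> qc -> coverage -> diversity -> ld ->
#' haplotypes -> association on a synthetic mass-cross dataset (or on a
#' dataset directory produced by \code{\link{write_dataset}}), writing
#' per-stage outputs and a JSON run report with the seed, thresholds and
#' stage status. A stage failure aborts the stages downstream of it and is
#' recorded in the report.
#'
#' @param config a \code{\link{sim_config}} (ignored when \code{data_dir}
#'   is given)
#' @param out_dir output directory
#' @param data_dir optional directory of an existing dataset
#' @param stages character vector of stages to run, in dependency order
#' @param params a \code{\link{pipeline_params}}
#' @return invisibly, the run report (also written to report.json)
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         data_dir = NULL,
                         stages = c("simulate", "qc", "coverage",
                                    "diversity", "ld", "haplotypes",
                                    "association"),
                         params = pipeline_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(
                   utils::packageVersion("amplipop")),
                 seed = config$seed, params = params,
                 started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stages = list())
  state <- new.env()
  aborted <- FALSE
  run_stage <- function(name, fun) {
    if (aborted || !(name %in% stages)) {
      report$stages[[name]] <<- list(status = if (aborted) "aborted"
                                     else "skipped")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) paste("failed:",
                                              conditionMessage(e)))
    report$stages[[name]] <<- list(
      status = res,
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    if (!identical(res, "ok")) aborted <<- TRUE
  }

  run_stage("simulate", function() {
    if (is.null(data_dir)) {
      state$ds <- simulate_dataset(config)
      sim_dir <- file.path(out_dir, "sim")
      write_dataset(state$ds, sim_dir, depth = FALSE)
      state$genotypes <- state$ds$genotypes
      state$depths <- state$ds$depths
      state$phenotypes <- state$ds$phenotypes
      state$reference <- state$ds$reference
      state$gene_model <- state$ds$gene_model
    } else {
      dd <- read_dataset(data_dir)
      state$read <- dd
      state$genotypes <- dd$genotypes
      state$depths <- dd$depths
      state$phenotypes <- dd$phenotypes
      state$reference <- dd$reference
      state$gene_model <- dd$gene_model
    }
  })

  run_stage("qc", function() {
    qdir <- file.path(out_dir, "qc"); dir.create(qdir, showWarnings = FALSE)
    gm <- annotate_sites(state$genotypes, state$gene_model,
                         state$reference)
    state$genotypes <- gm
    data.table::fwrite(gm$sites, file.path(qdir, "site_annotation.tsv"),
                       sep = "\t")
    state$common <- extract_common_snps(gm, params$maf_min,
                                        params$max_missing)
    data.table::fwrite(state$common$sites,
                       file.path(qdir, "common_snps.tsv"), sep = "\t")
  })

  run_stage("coverage", function() {
    cdir <- file.path(out_dir, "coverage")
    dir.create(cdir, showWarnings = FALSE)
    st <- compute_amplicon_stats(state$depths, params$min_depth)
    data.table::fwrite(st, file.path(cdir, "amplicon_stats.tsv"),
                       sep = "\t")
    for (resp in c("mean_depth", "sensitivity")) {
      an <- two_way_anova(st, resp)
      data.table::fwrite(an, file.path(cdir, paste0("anova_", resp,
                                                    ".tsv")), sep = "\t")
    }
    bf <- fit_boltzmann(st$mean_depth, st$sensitivity)
    jsonlite::write_json(list(x0 = bf$x0, dx = bf$dx,
                              se = as.list(bf$se), r2 = bf$r2),
                         file.path(cdir, "boltzmann.json"),
                         auto_unbox = TRUE, digits = NA)
    state$boltzmann <- bf
  })

  run_stage("diversity", function() {
    ddir <- file.path(out_dir, "diversity")
    dir.create(ddir, showWarnings = FALSE)
    imp <- impute_missing(state$genotypes, seed = config$seed)
    state$phased <- imp$haplotypes
    state$imputed <- imp$genotypes
    tabs <- lapply(unique(state$genotypes$sites$fragment), function(fr) {
      fragment_diversity(fr, state$phased[[fr]],
                         state$genotypes$sites, state$reference[[fr]],
                         state$gene_model, fs_reps = params$fs_reps,
                         boot_reps = params$boot_reps,
                         seed = config$seed)
    })
    data.table::fwrite(do.call(rbind, tabs),
                       file.path(ddir, "diversity.tsv"), sep = "\t")
  })

  run_stage("ld", function() {
    ldir <- file.path(out_dir, "ld"); dir.create(ldir, showWarnings = FALSE)
    pos <- split(state$genotypes$sites$pos, state$genotypes$sites$fragment)
    pairs <- pairwise_r2(state$phased, pos, maf_min = params$ld_maf)
    data.table::fwrite(pairs, file.path(ldir, "ld_pairs.tsv"), sep = "\t")
    n <- length(state$genotypes$individuals)
    fits <- list()
    for (fr in unique(pairs$fragment)) {
      sub <- pairs[pairs$fragment == fr, ]
      if (nrow(sub) < 10L) next
      ft <- fit_ld_decay(sub, n)
      fits[[fr]] <- list(c_hat = ft$c_hat, half_length = ft$half_length,
                         n_pairs = ft$n_pairs)
    }
    if (nrow(pairs) >= 10L) {
      ft <- fit_ld_decay(pairs, n)
      fits[["combined"]] <- list(c_hat = ft$c_hat,
                                 half_length = ft$half_length,
                                 n_pairs = ft$n_pairs)
    }
    jsonlite::write_json(fits, file.path(ldir, "ld_decay.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("haplotypes", function() {
    hdir <- file.path(out_dir, "haplo")
    dir.create(hdir, showWarnings = FALSE)
    com <- state$common
    wins <- sliding_windows(com$sites, k = params$window_k)
    traits <- setdiff(names(state$phenotypes), "individual_id")
    rows <- list()
    for (wi in seq_len(nrow(wins))) {
      idx <- wins$first[wi]:wins$last[wi]
      ht <- em_haplotype_frequencies(com$geno[, idx, drop = FALSE],
                                     seed = config$seed)
      for (tr in traits) {
        res <- htr_test(ht, state$phenotypes[[tr]],
                        n_perm = params$n_perm, seed = config$seed)
        rows[[length(rows) + 1L]] <- data.frame(
          window = wins$window[wi], fragment = wins$fragment[wi],
          span_bp = wins$span_bp[wi], trait = tr, f = res$f, p = res$p,
          r2 = res$r2,
          haplotypes = paste(res$common, collapse = ","),
          frequencies = paste(signif(res$common_freq, 3), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$best_window <- FALSE
    if (any(is.finite(out$p))) {
      out$best_window[which.min(out$p)] <- TRUE
    }
    data.table::fwrite(out, file.path(hdir, "htr.tsv"), sep = "\t")
  })

  run_stage("association", function() {
    adir <- file.path(out_dir, "assoc")
    dir.create(adir, showWarnings = FALSE)
    com <- state$common
    K <- kinship_matrix(com)
    sel <- select_k(com, k_max = params$k_max, n_restarts = 5L,
                    seed = config$seed)
    Q <- admixture_q(com, sel$k, seed = config$seed)$Q
    scan <- mlm_scan(state$phenotypes, com, Q = Q, K = K)
    data.table::fwrite(scan, file.path(adir, "association.tsv"),
                       sep = "\t")
    jsonlite::write_json(list(k_selected = sel$k,
                              loglik_trace = sel$loglik,
                              n_significant = sum(scan$q < params$fdr,
                                                  na.rm = TRUE)),
                         file.path(adir, "structure.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  report$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  report$completed <- !aborted
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Diversity and neutrality summary for one fragment
#'
#' Computes, per site class (synonymous, silent, non-synonymous, total),
#' the segregating-site count, pi, Watterson's theta and Tajima's D from
#' phased haplotypes, plus gene-level Fu's Fs (coalescent p) and the
#' Nei-Gojobori dN/dS with a codon-bootstrap Z-test. Class site totals use
#' fractional synonymous/non-synonymous site counts from the reference
#' CDS; silent = non-coding + synonymous.
#'
#' @param fragment fragment name
#' @param phased binary haplotype matrix (2n x segregating sites)
#' @param sites full site table (uses rows of this fragment; needs
#'   \code{class} from \code{\link{annotate_sites}})
#' @param ref_seq reference sequence string of the fragment
#' @param gene_model CDS table
#' @param fs_reps,boot_reps,seed simulation controls
#' @return one data.frame in Table-2 layout (rows = site classes)
#' @export
fragment_diversity <- function(fragment, phased, sites, ref_seq,
                               gene_model, fs_reps = 1000L,
                               boot_reps = 1000L, seed = 1L) {
  idx <- which(sites$fragment == fragment)
  cls <- sites$class[idx]
  pos <- sites$pos[idx]
  gmod <- gene_model[gene_model$fragment == fragment &
                       gene_model$feature == "CDS", , drop = FALSE]
  L <- nchar(ref_seq)
  cds_pos <- if (nrow(gmod)) unlist(Map(seq, gmod$start, gmod$end))
             else integer(0)
  ref_cds <- paste(strsplit(ref_seq, "")[[1]][cds_pos], collapse = "")
  ng_ref <- if (nchar(ref_cds)) nei_gojobori(c(ref_cds, ref_cds))
            else NULL
  syn_len <- if (!is.null(ng_ref)) ng_ref$s_sites else 0
  nonsyn_len <- if (!is.null(ng_ref)) ng_ref$n_sites else 0
  lens <- c(synonymous = syn_len,
            silent = L - length(cds_pos) + syn_len,
            `non-synonymous` = nonsyn_len,
            total = L)
  sel <- list(synonymous = cls == "synonymous",
              silent = cls %in% c("synonymous", "silent"),
              `non-synonymous` = cls == "non-synonymous",
              total = rep(TRUE, length(cls)))
  rows <- lapply(names(sel), function(cl) {
    h <- phased[, sel[[cl]], drop = FALSE]
    segc <- colSums(h) %% nrow(h) != 0
    S <- sum(segc)
    data.frame(fragment = fragment, region = cl,
               n_bp = round(lens[[cl]], 2), n_segregating = S,
               pi = nuc_diversity(h, lens[[cl]]),
               theta_w = if (lens[[cl]] > 0)
                 watterson_theta(S, nrow(h), lens[[cl]]) else NA_real_,
               tajimas_d = tajimas_d(h),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fs <- fus_fs(phased, n_reps = fs_reps, seed = seed)
  tab$fs <- NA_real_; tab$fs_p <- NA_real_
  tab$fs[tab$region == "total"] <- fs$fs
  tab$fs_p[tab$region == "total"] <- fs$p
  tab$dn_ds <- NA_real_; tab$z <- NA_real_; tab$z_p <- NA_real_
  if (nchar(ref_cds) && any(!is.na(cds_index <- match(pos, cds_pos)))) {
    seqs <- haplotype_cds(phased, pos, sites$alt[idx], ref_seq, cds_pos)
    uu <- !duplicated(seqs)
    wts <- as.numeric(table(factor(seqs, levels = seqs[uu])))
    if (sum(uu) >= 2) {
      zt <- dn_ds_test(seqs[uu], n_boot = boot_reps, seed = seed,
                       weights = wts)
      tab$dn_ds[tab$region == "total"] <- if (is.na(zt$ds) ||
                                              zt$ds == 0) {
        if (!is.na(zt$dn) && zt$dn == 0) 0 else NA_real_
      } else zt$dn / zt$ds
      tab$z[tab$region == "total"] <- zt$z
      tab$z_p[tab$region == "total"] <- zt$p
    }
  }
  tab
}

# substitute alt alleles into the reference CDS for each haplotype row
haplotype_cds <- function(phased, pos, alt, ref_seq, cds_pos) {
  base <- strsplit(ref_seq, "")[[1]]
  in_cds <- match(pos, cds_pos)
  vapply(seq_len(nrow(phased)), function(i) {
    s <- base
    carr <- phased[i, ] == 1L
    s[pos[carr]] <- alt[carr]
    paste(s[cds_pos], collapse = "")
  }, "")
}
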