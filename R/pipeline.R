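#' Run the full parallel-adaptation analysis pipeline
#'
#' Orchestrates simulate (or load) -> ascertain -> AFD scan -> core-SNP
#' detection -> polarity and asymmetry tests -> synthetic-genotype
#' similarity, NJ tree and ordination -> sweep statistics -> ancestral
#' sub-sample concordance, honouring a single master seed throughout.
#' Every intermediate table can be written under \code{out_dir}; the
#' return value is the JSON-serialisable summary.
#'
#' @param config a \code{\link{cohort_config}} describing the simulated
#'   cohort, or a list with elements \code{matrix} (a
#'   \code{\link{snp_matrix}}) and optional \code{truth} for pre-built data.
#' @param out_dir optional output directory; created if missing.
#' @param core_threshold integrated-AFD threshold for core regions
#'   (default 0.70).
#' @param core_gap region-independence distance in bp (default 50 kb).
#' @param scan_maf MAF floor across the global freshwater pool for the
#'   divergence scan (default 0.2, strict).
#' @param n_boot bootstrap iterations for CIs (default 10000).
#' @param n_perm permutation iterations (default 9999).
#' @return (invisibly) a named list: the summary statistics plus the main
#'   intermediate objects (\code{matrix}, \code{scan_ba}, \code{regions},
#'   \code{polarized_core}, \code{sweep_core}, ...).
#' @export
run_pipeline <- function(config, out_dir = NULL, core_threshold = 0.70,
                         core_gap = 50000, scan_maf = 0.2,
                         n_boot = 10000, n_perm = 9999) {
  if (inherits(config, "cohort_config")) {
    seed <- config$seed
    cohort <- simulate_cohort(config)
    m0 <- cohort$matrix
    truth <- cohort$truth
  } else {
    m0 <- config$matrix
    truth <- config$truth
    seed <- if (!is.null(config$seed)) config$seed else 1L
  }
  snps0 <- m0$snps
  marine_subs <- habitat_pops(m0, "marine")
  if (length(marine_subs) > 1) {
    m0 <- combine_populations(m0, marine_subs, "MAR", keep_members = TRUE)
    marine <- "MAR"
  } else {
    marine <- marine_subs
    marine_subs <- character(0)
  }
  fresh <- m0$populations$name[m0$populations$habitat %in% c("basic", "acidic")]

  # --- ascertainment on the global freshwater pool ---------------------
  m <- filter_coverage(m0, scope = fresh, min_total = 150, max_total = 2800)
  m <- filter_maf(m, scope = fresh, min_maf = 0.05)
  m <- filter_spacing(m, min_gap = 12)
  truth0 <- truth
  if (!is.null(truth)) {
    truth <- truth[match(paste(m$snps$chrom, m$snps$pos),
                         paste(snps0$chrom, snps0$pos)), , drop = FALSE]
  }

  # --- divergence scan -------------------------------------------------
  m_scan <- filter_maf(m, scope = fresh, min_maf = scan_maf)
  tab <- pairwise_scan(m_scan, min_depth_per_pop = 50)
  scan_ba <- integrate_category(tab, "BA", 18L)
  scan_bb <- integrate_category(tab, "BB", 8L)
  scan_aa <- integrate_category(tab, "AA", 8L)
  regions <- detect_core_snps(scan_ba, threshold = core_threshold,
                              max_gap = core_gap)
  core <- data.frame(chrom = regions$chrom, pos = regions$core_pos)

  # --- phylogeny-SNP ascertainment (neutral structure check) ----------
  tab_mf <- mf_scan(m, marine = marine, min_depth_per_pop = 50)
  scan_mf_full <- integrate_category(tab_mf, "MF", 8L)
  tab_ba_full <- pairwise_scan(m, min_depth_per_pop = 50)
  scan_ba_full <- integrate_category(tab_ba_full, "BA", 18L)
  m_phylo <- select_phylogeny_snps(m, scan_ba_full, scan_mf_full,
                                   min_pool_cov = 40, max_afd = 0.5,
                                   tip_window = 5e6)

  # --- polarity and asymmetry -----------------------------------------
  summary <- list()
  res <- list(matrix = m, scan_ba = scan_ba, scan_bb = scan_bb,
              scan_aa = scan_aa, regions = regions, truth = truth,
              n_phylogeny_snps = n_snps(m_phylo))
  summary$n_snps_ascertained <- n_snps(m)
  summary$n_snps_scanned <- sum(!is.na(scan_ba$mean_afd))
  summary$core_region_count <- nrow(regions)
  if (nrow(regions) >= 3) {
    pol <- polarize(m, core, marine = marine,
                    marine_subsamples = if (length(marine_subs)) marine_subs)
    mm <- marine_minor_count(pol)
    bt <- sign_binomial_test(mm$k, mm$n)
    ctrl_idx <- select_random_controls(scan_ba, n = nrow(pol),
                                       tolerance = 0.005, seed =
                                         substream_seed(seed, "controls"))
    ctrl <- data.frame(chrom = scan_ba$chrom[ctrl_idx],
                       pos = scan_ba$pos[ctrl_idx])
    pol_ctrl <- polarize(m, ctrl, marine = marine)
    perm <- median_permutation_test(pol$marine_acidic_freq,
                                    pol_ctrl$marine_acidic_freq,
                                    n_iter = n_perm,
                                    seed = substream_seed(seed, "median_perm"))

    # --- similarity, tree, ordination ---------------------------------
    d_core <- binary_similarity(m, core,
                                seed = substream_seed(seed, "bin_core"))
    d_ctrl <- binary_similarity(m, ctrl,
                                seed = substream_seed(seed, "bin_ctrl"))
    drop_subs <- function(d) {
      keep <- setdiff(rownames(d), marine_subs)
      d[keep, keep]
    }
    tree_core <- nj_tree(drop_subs(d_core))
    tree_ctrl <- nj_tree(drop_subs(d_ctrl))
    ord_core <- ordinate(drop_subs(d_core), n_dims = 1,
                         seed = substream_seed(seed, "ord_core"))
    ord_ctrl <- ordinate(drop_subs(d_ctrl), n_dims = 1,
                         seed = substream_seed(seed, "ord_ctrl"))

    # --- sweeps --------------------------------------------------------
    sw_core <- sweep_contrasts(m, pol)
    sw_ctrl <- sweep_contrasts(m, pol_ctrl)
    cor_core <- correlate_bootstrap(sw_core, n_boot = n_boot,
                                    seed = substream_seed(seed, "boot_core"))
    cor_ctrl <- correlate_bootstrap(sw_ctrl, n_boot = n_boot,
                                    seed = substream_seed(seed, "boot_ctrl"))
    hd <- habitat_diversity_test(m, data.frame(chrom = ctrl$chrom,
                                               center = ctrl$pos),
                                 basic_pops = habitat_pops(m, "basic"),
                                 acidic_pops = habitat_pops(m, "acidic"),
                                 width = 1e6, n_iter = n_perm,
                                 seed = substream_seed(seed, "habitat_perm"))

    summary$marine_minor_k <- mm$k
    summary$marine_minor_n <- mm$n
    summary$binomial_p <- bt$p_value
    summary$median_perm_p <- perm$p_value
    summary$median_marine_acidic_core <- median(pol$marine_acidic_freq)
    summary$median_marine_acidic_control <- median(pol_ctrl$marine_acidic_freq)
    summary$sweep_r_core <- cor_core$r
    summary$sweep_r_core_ci <- c(cor_core$ci_low, cor_core$ci_high)
    summary$sweep_r_control <- cor_ctrl$r
    summary$sweep_r_control_ci <- c(cor_ctrl$ci_low, cor_ctrl$ci_high)
    summary$habitat_diversity_p <- hd$p_value
    res <- c(res, list(polarized_core = pol, polarized_control = pol_ctrl,
                       control_idx = ctrl_idx, sweep_core = sw_core,
                       sweep_control = sw_ctrl, tree_core = tree_core,
                       tree_control = tree_ctrl, ord_core = ord_core,
                       ord_control = ord_ctrl, dist_core = d_core,
                       dist_control = d_ctrl))

    # --- concordance between marine sub-samples -----------------------
    if (length(marine_subs) >= 2) {
      xs <- pol[[paste0("marine_acidic_freq_", marine_subs[1])]]
      ys <- pol[[paste0("marine_acidic_freq_", marine_subs[2])]]
      maf_fit <- major_axis_fit(xs, ys, n_boot = n_boot,
                                seed = substream_seed(seed, "ma_boot"))
      summary$ma_slope <- maf_fit$slope
      summary$ma_slope_ci <- c(maf_fit$ci_low, maf_fit$ci_high)
      res$ma_fit <- maf_fit
    }
  }

  # --- recovery against the truth table -------------------------------
  if (!is.null(truth0) && nrow(regions) > 0) {
    planted <- which(truth0$class == "selected_core")
    p_chrom <- snps0$chrom[planted]
    p_pos <- snps0$pos[planted]
    # a planted locus within the chaining distance of a region counts as
    # recovered: had its own SNP passed the pair-depth rule it would have
    # been chained into that region
    in_region <- vapply(seq_along(planted), function(i) {
      any(regions$chrom == p_chrom[i] &
            regions$start - core_gap <= p_pos[i] &
            regions$end + core_gap >= p_pos[i])
    }, NA)
    hit_region <- vapply(seq_len(nrow(regions)), function(r) {
      any(p_chrom == regions$chrom[r] &
            p_pos >= regions$start[r] - core_gap &
            p_pos <= regions$end[r] + core_gap)
    }, NA)
    summary$planted_loci <- length(planted)
    summary$planted_recovered <- sum(in_region)
    summary$recovery_rate <- mean(in_region)
    summary$false_region_fraction <-
      if (nrow(regions)) mean(!hit_region) else 0
  }
  res$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_snp_matrix(m, file.path(out_dir, "snp_matrix_ascertained.tsv"))
    scan_out <- data.frame(scan_ba[, c("chrom", "pos")],
                           mean_afd_ba = scan_ba$mean_afd,
                           n_pairs_ba = scan_ba$n_pairs,
                           mean_afd_bb = scan_bb$mean_afd,
                           mean_afd_aa = scan_aa$mean_afd)
    write.table(scan_out, file.path(out_dir, "category_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(regions)) {
      write_regions_bed(regions, file.path(out_dir, "core_regions.bed"))
      write.table(regions, file.path(out_dir, "core_regions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$polarized_core)) {
      write.table(res$polarized_core, file.path(out_dir, "polarized_core.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$sweep_core, file.path(out_dir, "sweep_core.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(tree_newick(res$tree_core),
                 file.path(out_dir, "nj_core.nwk"))
      writeLines(tree_newick(res$tree_control),
                 file.path(out_dir, "nj_control.nwk"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
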