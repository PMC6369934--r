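#' Configuration for the synthetic Pool-seq cohort
#'
#' Defines the simulated study design: an ancestral marine population and
#' independently founded basic and acidic lake populations that diverge by
#' drift, habitat-directed selection on standing variation, and selective
#' sweep footprints on linked sites, observed through pooled read sampling.
#'
#' Defaults emulate the study conditions: 5 basic + 5 acidic lake pools of
#' 30 diploids at ~63x depth plus a marine ancestor-proxy sequenced as two
#' sub-samples (20 + 10 diploids) at a combined ~133x; neutral SNPs at
#' long-segregating (uniform) ancestral frequencies and selected loci whose
#' acidic-favoured allele is rare in the ancestor.
#'
#' @param layout genome layout; default 21 chromosomes of 2.5 Mb. At the
#'   default SNP count this gives about 1 SNP per kb, a deliberately dense
#'   scaled-down design: with 20 selected loci (roughly half the number of
#'   regions a full-size study yields), the denser markers keep the
#'   windowed sweep statistics comparably informative per locus.
#' @param n_basic,n_acidic numbers of derived lake populations.
#' @param pool_size diploid individuals per lake pool.
#' @param marine_pools named integer vector of marine sub-sample pool sizes;
#'   set to a single entry for a pre-combined marine pool.
#' @param Ne effective diploid size per lake during post-founding drift.
#' @param founder_size diploid size of the founding propagule (bottleneck).
#' @param generations Wright-Fisher generations of drift since colonisation.
#' @param n_neutral_snps,n_selected_loci SNP counts by class.
#' @param selected_target_freq post-selection frequency of the locally
#'   favoured allele in its habitat.
#' @param ancestral_acidic_freq_range interval from which the acidic-favoured
#'   allele's ancestral (marine) frequency is drawn.
#' @param depth_mean_lake,depth_mean_marine mean pooled read depths.
#' @param depth_dispersion negative-binomial size parameter for depth
#'   over-dispersion (smaller = more over-dispersed).
#' @param rad_locus_spacing bp per RAD locus used to assign locus identifiers.
#' @param lambda0 base length scale (bp) of the sweep footprint.
#' @param ld_scale decay scale (bp) of ancestral haplotype association: a
#'   linked SNP at distance \code{d} from a selected site is a perfect
#'   marker of the selected standing variant (same ancestral frequency,
#'   riding the swept haplotype) with probability \code{exp(-d/ld_scale)};
#'   otherwise it is at linkage equilibrium with it in the ancestor.
#' @param seed master seed; mandatory for reproducibility.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(layout = NULL,
                          n_basic = 5L, n_acidic = 5L, pool_size = 30L,
                          marine_pools = c(OBSM = 20L, ARDH = 10L),
                          Ne = 500L, founder_size = 50L, generations = 100L,
                          n_neutral_snps = 50000L, n_selected_loci = 20L,
                          selected_target_freq = 0.95,
                          ancestral_acidic_freq_range = c(0.05, 0.45),
                          depth_mean_lake = 63, depth_mean_marine = 133,
                          depth_dispersion = 100,
                          rad_locus_spacing = 2000L,
                          lambda0 = 15000L,
                          ld_scale = 5000L,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  if (is.null(layout)) {
    roman <- c("I","II","III","IV","V","VI","VII","VIII","IX","X","XI","XII",
               "XIII","XIV","XV","XVI","XVII","XVIII","XIX","XX","XXI")
    layout <- genome_layout(paste0("chr", roman), rep(2.5e6, 21))
  }
  stopifnot(n_basic >= 1, n_acidic >= 1, pool_size >= 1, Ne >= 1,
            founder_size >= 1, generations >= 0, n_neutral_snps >= 1,
            n_selected_loci >= 0,
            selected_target_freq > 0, selected_target_freq < 1,
            all(ancestral_acidic_freq_range > 0),
            all(ancestral_acidic_freq_range < 1),
            diff(ancestral_acidic_freq_range) >= 0,
            depth_mean_lake > 0, depth_mean_marine > 0, depth_dispersion > 0,
            lambda0 > 0, length(marine_pools) >= 1)
  structure(list(layout = layout, n_basic = as.integer(n_basic),
                 n_acidic = as.integer(n_acidic),
                 pool_size = as.integer(pool_size),
                 marine_pools = marine_pools,
                 Ne = as.integer(Ne), founder_size = as.integer(founder_size),
                 generations = as.integer(generations),
                 n_neutral_snps = as.integer(n_neutral_snps),
                 n_selected_loci = as.integer(n_selected_loci),
                 selected_target_freq = selected_target_freq,
                 ancestral_acidic_freq_range = ancestral_acidic_freq_range,
                 depth_mean_lake = depth_mean_lake,
                 depth_mean_marine = depth_mean_marine,
                 depth_dispersion = depth_dispersion,
                 rad_locus_spacing = as.integer(rad_locus_spacing),
                 lambda0 = as.numeric(lambda0),
                 ld_scale = as.numeric(ld_scale),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

cohort_populations <- function(config) {
  pops <- population_spec(
    name = c(paste0("B", seq_len(config$n_basic)),
             paste0("A", seq_len(config$n_acidic)),
             names(config$marine_pools)),
    habitat = c(rep("basic", config$n_basic), rep("acidic", config$n_acidic),
                rep("marine", length(config$marine_pools))),
    pool_size = c(rep(config$pool_size, config$n_basic + config$n_acidic),
                  as.integer(config$marine_pools)))
  pops$group_tag[pops$habitat == "marine"] <- names(config$marine_pools)
  pops
}

#' Sweep footprint coupling
#'
#' Fraction \code{h} of a derived population's lineages at distance \code{d}
#' from a selected site that descend from the single founding swept
#' haplotype. The functional form is \code{h = exp(-d / lambda(p0))} with
#' \code{lambda(p0) = lambda0 * log(1/p0) / log(4)}, so the footprint scale
#' equals \code{lambda0} when the favoured allele started at frequency 0.25
#' and widens as the allele starts rarer (stronger sweeps from rarer
#' standing variants).
#'
#' @param d distance in bp (>= 0).
#' @param p0 ancestral frequency of the locally favoured allele, in (0, 1).
#' @param lambda0 base footprint length scale in bp.
#' @return coupling value(s) in [0, 1].
#' @export
sweep_coupling <- function(d, p0, lambda0) {
  stopifnot(all(d >= 0), all(p0 > 0), all(p0 < 1))
  lambda <- lambda0 * log(1 / p0) / log(4)
  exp(-d / lambda)
}

#' Simulate ancestral allele frequencies and the truth table
#'
#' Lays SNPs out on RAD loci across the genome, draws neutral ancestral
#' reference-allele frequencies uniform on [0.05, 0.95] (the long-term
#' neutral expectation for long-segregating polymorphisms), places selected
#' loci whose acidic-favoured allele's ancestral frequency is drawn from
#' \code{config$ancestral_acidic_freq_range}, and classifies every SNP
#' within \code{5 * lambda0} of a selected locus as linked to it.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{snps} (record table), \code{p_anc} (ancestral
#'   reference-allele frequency per SNP) and \code{truth} (per-SNP class
#'   \code{neutral}/\code{selected_core}/\code{linked}, owning selected
#'   locus id, distance \code{d}, ancestral acidic-allele frequency
#'   \code{p0_acidic}, and which allele is the acidic one).
#' @export
simulate_ancestral_frequencies <- function(config) {
  with_seed(substream_seed(config$seed, "ancestral"), {
    lay <- config$layout
    n_total <- config$n_neutral_snps + config$n_selected_loci
    # SNP positions allocated to chromosomes proportional to length
    n_per <- round_half_up(lay$length / sum(lay$length) * n_total)
    while (sum(n_per) != n_total) {
      i <- which.max(lay$length - n_per)  # adjust on the emptiest chromosome
      n_per[i] <- n_per[i] + sign(n_total - sum(n_per))
    }
    if (any(n_per > lay$length)) stop("more SNPs than representable positions")
    chrom <- rep(lay$chrom, n_per)
    pos <- unlist(lapply(seq_len(nrow(lay)), function(i) {
      sort(sample.int(lay$length[i], n_per[i]))
    }))
    n <- length(pos)
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, n, replace = TRUE)
    # alt drawn uniformly among the three non-ref nucleotides, vectorised
    alt <- nts[(match(ref, nts) - 1L + sample(3L, n, replace = TRUE)) %% 4L + 1L]
    locus_id <- paste0(chrom, "_L", (pos - 1L) %/% config$rad_locus_spacing)
    snps <- data.frame(chrom = chrom, pos = pos, locus_id = locus_id,
                       ref = ref, alt = alt, stringsAsFactors = FALSE)

    p_anc <- runif(n, 0.05, 0.95)
    truth <- data.frame(class = rep("neutral", n), sel_id = NA_integer_,
                        d = NA_real_, p0_acidic = NA_real_,
                        acidic_is_ref = NA, block = FALSE,
                        stringsAsFactors = FALSE)

    k <- config$n_selected_loci
    if (k > 0) {
      # spread selected loci over chromosomes, away from ends and from each
      # other, so 1 Mb sweep-analysis windows do not overlap
      min_sep <- 2.5e6
      sel_idx <- integer(0)
      chr_cycle <- rep_len(seq_len(nrow(lay)), k)
      for (ci in chr_cycle) {
        cand <- which(snps$chrom == lay$chrom[ci] &
                      pos > 0.12 * lay$length[ci] &
                      pos < 0.88 * lay$length[ci])
        cand <- setdiff(cand, sel_idx)
        ok <- cand[vapply(cand, function(j) {
          same <- sel_idx[snps$chrom[sel_idx] == snps$chrom[j]]
          !length(same) || min(abs(pos[same] - pos[j])) >= min_sep
        }, NA)]
        if (!length(ok)) stop("cannot place selected loci with required spacing")
        sel_idx <- c(sel_idx, sample(ok, 1L))
      }
      r <- config$ancestral_acidic_freq_range
      p0 <- runif(k, r[1], r[2])
      acidic_is_ref <- runif(k) < 0.5
      truth$class[sel_idx] <- "selected_core"
      truth$sel_id[sel_idx] <- seq_len(k)
      truth$d[sel_idx] <- 0
      truth$p0_acidic[sel_idx] <- p0
      truth$acidic_is_ref[sel_idx] <- acidic_is_ref
      p_anc[sel_idx] <- ifelse(acidic_is_ref, p0, 1 - p0)

      # linked sites inherit the owning locus' sweep parameters; those in
      # the ancestral haplotype block are perfect markers of the standing
      # variant (their own ancestral frequency mirrors p0)
      radius <- 5 * config$lambda0
      for (s in seq_len(k)) {
        j <- sel_idx[s]
        near <- which(snps$chrom == snps$chrom[j] &
                      abs(pos - pos[j]) <= radius &
                      truth$class == "neutral")
        d_near <- abs(pos[near] - pos[j])
        in_block <- runif(length(near)) < exp(-d_near / config$ld_scale)
        blk_ref <- runif(length(near)) < 0.5  # acidic allele is ref?
        truth$class[near] <- "linked"
        truth$sel_id[near] <- s
        truth$d[near] <- d_near
        truth$p0_acidic[near] <- p0[s]
        truth$acidic_is_ref[near] <- ifelse(in_block, blk_ref, acidic_is_ref[s])
        truth$block[near] <- in_block
        bi <- near[in_block]
        p_anc[bi] <- ifelse(blk_ref[in_block], p0[s], 1 - p0[s])
      }
    }
    list(snps = snps, p_anc = p_anc, truth = truth)
  })
}

#' Simulate true allele frequencies in the derived populations
#'
#' Each derived lake population evolves independently from the ancestor:
#' a founder bottleneck, then Wright-Fisher binomial drift for
#' \code{generations} rounds at effective size \code{Ne}; at selected loci
#' the habitat-favoured allele (the acidic allele in acidic lakes, its
#' alternative in basic lakes) is set to \code{selected_target_freq}; at
#' linked SNPs the post-sweep frequency is
#' \code{p' = (1 - h) * p_drift + h * x}, where \code{h} is the
#' \code{\link{sweep_coupling}} at the SNP's distance given the favoured
#' allele's ancestral starting frequency in that habitat, and \code{x} is
#' the allele carried by the founding swept haplotype. Because parallel
#' adaptation draws on the same standing variant, the swept haplotype is
#' shared by all populations of a habitat: \code{x} is drawn once per
#' linked SNP and habitat (with the ancestral frequency), which produces
#' the characteristic blocks of SNPs near-fixed for alternative alleles
#' between habitats around selected sites. The marine population keeps
#' the ancestral frequencies unchanged (ancestor-proxy assumption).
#'
#' @param ancestral output of \code{\link{simulate_ancestral_frequencies}}.
#' @param truth the truth table (taken from \code{ancestral} if missing).
#' @param config a \code{\link{cohort_config}}.
#' @return numeric matrix of true reference-allele frequencies,
#'   SNPs x populations (columns named as in \code{cohort_populations}).
#' @export
simulate_derived_populations <- function(ancestral, truth = ancestral$truth,
                                         config) {
  p_anc <- ancestral$p_anc
  n <- length(p_anc)
  pops <- cohort_populations(config)
  freqs <- matrix(NA_real_, n, nrow(pops), dimnames = list(NULL, pops$name))
  target <- config$selected_target_freq
  sel <- truth$class == "selected_core"
  lnk <- truth$class == "linked"

  # founding swept-haplotype allele at linked SNPs, shared within habitat:
  # block members ride the selected haplotype (acidic allele in the acidic
  # sweep, its alternative in the basic sweep); linkage-equilibrium sites
  # get an independent draw per habitat at the ancestral frequency
  x_hab <- with_seed(substream_seed(config$seed, "swept_haplotypes"), {
    blk <- truth$block[lnk]
    acid_ref <- as.numeric(truth$acidic_is_ref[lnk])
    xa <- as.numeric(runif(sum(lnk)) < p_anc[lnk])
    xb <- as.numeric(runif(sum(lnk)) < p_anc[lnk])
    xa[blk] <- acid_ref[blk]
    xb[blk] <- 1 - acid_ref[blk]
    list(acidic = xa, basic = xb)
  })

  for (j in seq_len(nrow(pops))) {
    hab <- pops$habitat[j]
    if (hab == "marine") {
      freqs[, j] <- p_anc
      next
    }
    with_seed(substream_seed(config$seed, paste0("pop_", pops$name[j])), {
      p <- rbinom(n, 2L * config$founder_size, p_anc) / (2 * config$founder_size)
      two_ne <- 2L * config$Ne
      for (g in seq_len(config$generations)) {
        p <- rbinom(n, two_ne, p) / two_ne
      }
      if (any(sel)) {
        # favoured-allele ancestral start frequency, per habitat
        fav_is_ref <- if (hab == "acidic") truth$acidic_is_ref else !truth$acidic_is_ref
        p0_fav <- if (hab == "acidic") truth$p0_acidic else 1 - truth$p0_acidic
        p[sel] <- ifelse(fav_is_ref[sel], target, 1 - target)
        if (any(lnk)) {
          h <- sweep_coupling(truth$d[lnk], p0_fav[lnk], config$lambda0)
          p[lnk] <- (1 - h) * p[lnk] + h * x_hab[[hab]]
        }
      }
      freqs[, j] <- p
    })
  }
  freqs
}

#' Sample pooled reads over true allele frequencies
#'
#' Per SNP and population, depth is negative-binomial with the configured
#' habitat mean and dispersion (floored at 1 read) and the reference read
#' count is binomial(depth, true frequency).
#'
#' @param true_freqs SNPs x populations matrix of true reference-allele
#'   frequencies.
#' @param config a \code{\link{cohort_config}}.
#' @param snps SNP record table (defaults to regenerating the ancestral
#'   layout is not possible here, so pass \code{ancestral$snps}).
#' @return a \code{\link{snp_matrix}}.
#' @export
simulate_pooled_reads <- function(true_freqs, config, snps) {
  stopifnot(all(true_freqs >= 0 & true_freqs <= 1))
  pops <- cohort_populations(config)
  n <- nrow(true_freqs)
  ref <- matrix(0, n, nrow(pops))
  alt <- matrix(0, n, nrow(pops))
  # the marine depth target is for the combined ancestor-proxy pool, so
  # sub-samples are sequenced in proportion to their pool sizes
  marine_total <- sum(pops$pool_size[pops$habitat == "marine"])
  for (j in seq_len(nrow(pops))) {
    mu <- if (pops$habitat[j] == "marine") {
      config$depth_mean_marine * pops$pool_size[j] / marine_total
    } else config$depth_mean_lake
    with_seed(substream_seed(config$seed, paste0("reads_", pops$name[j])), {
      depth <- pmax(1L, rnbinom(n, size = config$depth_dispersion, mu = mu))
      ref[, j] <- rbinom(n, depth, true_freqs[, j])
      alt[, j] <- depth - ref[, j]
    })
  }
  snp_matrix(snps, ref, alt, pops, config$layout)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining \code{\link{simulate_ancestral_frequencies}},
#' \code{\link{simulate_derived_populations}} and
#' \code{\link{simulate_pooled_reads}}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{matrix} (the observed \code{snp_matrix}),
#'   \code{truth}, \code{true_freqs} and \code{p_anc}.
#' @export
simulate_cohort <- function(config) {
  anc <- simulate_ancestral_frequencies(config)
  tf <- simulate_derived_populations(anc, anc$truth, config)
  m <- simulate_pooled_reads(tf, config, anc$snps)
  list(matrix = m, truth = anc$truth, true_freqs = tf, p_anc = anc$p_anc)
}

#' Write a truth table as TSV
#' @param cohort output of \code{\link{simulate_cohort}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_table <- function(cohort, path) {
  df <- cbind(cohort$matrix$snps[, c("chrom", "pos")], cohort$truth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
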