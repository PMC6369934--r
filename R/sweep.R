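# Windowed genetic-diversity statistics around focal SNPs: the relative
# high-MAF SNP-density sweep metric, habitat contrasts, bootstrap
# correlation, pooled nucleotide diversity, and the genome-wide habitat
# diversity permutation test.

window_rows <- function(m, chrom, center, width) {
  len <- m$layout$length[match(chrom, m$layout$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  lo <- max(1, center - width / 2)
  hi <- min(len, center + width / 2)
  which(m$snps$chrom == chrom & m$snps$pos >= lo & m$snps$pos <= hi)
}

#' Count high-MAF SNPs in a window for one population
#'
#' Counts SNPs whose per-population MAF strictly exceeds
#' \code{maf_threshold} within the inclusive window
#' \code{[center - width/2, center + width/2]}, clipped to the chromosome.
#' SNPs with zero depth in the population are missing and not counted.
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param population population name.
#' @param chrom,center,width window specification (bp).
#' @param maf_threshold strict MAF bound (default 0.3).
#' @return integer count.
#' @export
high_maf_count <- function(m, population, chrom, center, width,
                           maf_threshold = 0.3) {
  rows <- window_rows(m, chrom, center, width)
  if (!length(rows)) return(0L)
  j <- pop_index(m, population)
  f <- m$ref_counts[rows, j] / (m$ref_counts[rows, j] + m$alt_counts[rows, j])
  maf <- pmin(f, 1 - f)
  sum(maf > maf_threshold, na.rm = TRUE)
}

#' Relative high-MAF SNP density around a focal SNP for one habitat
#'
#' Per-population high-MAF SNP counts in the small window are summed over
#' the habitat's populations and divided by the analogous sum over the
#' large window (which contains the small one). Missing (\code{NA}) when
#' the large-window sum is zero.
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param chrom,center focal SNP location.
#' @param populations habitat population names.
#' @param w_small,w_large window widths in bp (defaults 40 kb and 1 Mb).
#' @param maf_threshold strict MAF bound (default 0.3).
#' @return ratio in [0, 1], or \code{NA}.
#' @export
relative_density <- function(m, chrom, center, populations,
                             w_small = 40000, w_large = 1e6,
                             maf_threshold = 0.3) {
  if (w_small > w_large) stop("w_small must not exceed w_large")
  small <- sum(vapply(populations, function(p)
    high_maf_count(m, p, chrom, center, w_small, maf_threshold), 0L))
  large <- sum(vapply(populations, function(p)
    high_maf_count(m, p, chrom, center, w_large, maf_threshold), 0L))
  if (large == 0) NA_real_ else small / large
}

#' Sweep statistics (relative densities and B-A contrast) at focal SNPs
#'
#' One row per focal SNP: relative high-MAF SNP density per habitat,
#' their difference \code{delta = density_basic - density_acidic}, and the
#' marine acidic-allele frequency carried along for the correlation
#' analysis. Focal SNPs with an undefined density in either habitat are
#' excluded with a message.
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param focal data.frame with \code{chrom}, \code{pos} and
#'   \code{marine_acidic_freq} (e.g. a \code{\link{polarize}} result).
#' @param basic_pops,acidic_pops habitat population name vectors (defaults
#'   from the matrix habitats).
#' @param w_small,w_large,maf_threshold as in \code{\link{relative_density}}.
#' @return data.frame with \code{chrom}, \code{pos}, \code{density_basic},
#'   \code{density_acidic}, \code{delta}, \code{marine_acidic_freq}.
#' @export
sweep_contrasts <- function(m, focal, basic_pops = habitat_pops(m, "basic"),
                            acidic_pops = habitat_pops(m, "acidic"),
                            w_small = 40000, w_large = 1e6,
                            maf_threshold = 0.3) {
  db <- mapply(function(ch, p) relative_density(m, ch, p, basic_pops,
                                                w_small, w_large, maf_threshold),
               focal$chrom, focal$pos)
  da <- mapply(function(ch, p) relative_density(m, ch, p, acidic_pops,
                                                w_small, w_large, maf_threshold),
               focal$chrom, focal$pos)
  out <- data.frame(chrom = focal$chrom, pos = focal$pos,
                    density_basic = db, density_acidic = da,
                    delta = db - da,
                    marine_acidic_freq = focal$marine_acidic_freq,
                    stringsAsFactors = FALSE)
  bad <- is.na(out$delta)
  if (any(bad)) {
    message(sum(bad), " focal SNP(s) dropped: undefined density in a habitat")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation with percentile bootstrap CI
#'
#' Correlates the B-A density contrast with the marine acidic-allele
#' frequency; the 95\% CI comes from percentile bootstrap over SNP
#' resampling with replacement.
#'
#' @param stats a \code{\link{sweep_contrasts}} data.frame (or any with
#'   \code{delta} and \code{marine_acidic_freq}).
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with \code{r}, \code{ci_low}, \code{ci_high}, \code{n},
#'   \code{n_boot}, \code{seed}.
#' @export
correlate_bootstrap <- function(stats, n_boot = 10000, seed = 1,
                                conf = 0.95) {
  x <- stats$delta
  y <- stats$marine_acidic_freq
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three defined statistics")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a variable")
  r <- cor(x, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bi <- sample.int(length(x), replace = TRUE)
      suppressWarnings(cor(x[bi], y[bi]))
    }, 0)
  })
  boots <- boots[is.finite(boots)]  # degenerate resamples dropped
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(r = r, ci_low = ci[1], ci_high = ci[2], n = length(x),
       n_boot = n_boot, seed = seed)
}

#' Pooled nucleotide diversity in a window
#'
#' \code{pi = sum over SNPs of [depth / (depth - 1)] * 2 * p * (1 - p)}
#' divided by the clipped window length in bp; monomorphic positions
#' contribute zero, SNPs with depth <= 1 are skipped.
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param population population name.
#' @param chrom,center,width window specification.
#' @return per-bp diversity estimate (>= 0).
#' @export
pooled_pi <- function(m, population, chrom, center, width) {
  len <- m$layout$length[match(chrom, m$layout$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  lo <- max(1, center - width / 2)
  hi <- min(len, center + width / 2)
  rows <- which(m$snps$chrom == chrom & m$snps$pos >= lo & m$snps$pos <= hi)
  if (!length(rows)) return(0)
  j <- pop_index(m, population)
  dep <- m$ref_counts[rows, j] + m$alt_counts[rows, j]
  p <- m$ref_counts[rows, j] / dep
  keep <- dep > 1
  sum(dep[keep] / (dep[keep] - 1) * 2 * p[keep] * (1 - p[keep])) / (hi - lo + 1)
}

#' Habitat diversity permutation test on per-population medians
#'
#' Per population, the median high-MAF SNP count across the given windows;
#' the statistic is the absolute difference between the median of those
#' medians over basic pools and over acidic pools. The null permutes the
#' habitat labels over populations, either by \code{n_iter} random draws
#' (\code{p = (b + 1) / (n_iter + 1)}) or exhaustively over all label
#' assignments (\code{exact = TRUE}).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param windows data.frame with \code{chrom}, \code{center} (window
#'   centres, e.g. at random-control SNPs).
#' @param basic_pops,acidic_pops habitat population names (>= 2 each).
#' @param width window width in bp (default 1 Mb).
#' @param maf_threshold strict MAF bound (default 0.3).
#' @param n_iter random permutations (default 9999).
#' @param seed RNG seed.
#' @param exact enumerate all label assignments.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{n_iterations}, \code{seed}, \code{pop_medians}.
#' @export
habitat_diversity_test <- function(m, windows, basic_pops, acidic_pops,
                                   width = 1e6, maf_threshold = 0.3,
                                   n_iter = 9999, seed = 1, exact = FALSE) {
  if (length(basic_pops) < 2 || length(acidic_pops) < 2) {
    stop("need at least two populations per habitat")
  }
  pops <- c(basic_pops, acidic_pops)
  counts <- vapply(pops, function(p) {
    vapply(seq_len(nrow(windows)), function(i)
      high_maf_count(m, p, windows$chrom[i], windows$center[i],
                     width, maf_threshold), 0L)
  }, integer(nrow(windows)))
  med <- apply(counts, 2L, median)
  nb <- length(basic_pops)
  stat_of <- function(ib) abs(median(med[ib]) - median(med[-ib]))
  obs <- stat_of(seq_len(nb))
  if (exact) {
    idx <- combn(length(pops), nb)
    null <- apply(idx, 2L, stat_of)
    p <- sum(null >= obs) / ncol(idx)
    return(list(statistic = obs, p_value = p, method = "permutation_exact",
                n_iterations = ncol(idx), seed = NA_integer_,
                pop_medians = med))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i)
      stat_of(sample.int(length(pops), nb)), 0)
  })
  p <- (sum(null >= obs) + 1) / (n_iter + 1)
  list(statistic = obs, p_value = p, method = "permutation",
       n_iterations = n_iter, seed = seed, pop_medians = med)
}
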