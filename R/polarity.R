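#' Classify alleles at focal SNPs as basic or acidic
#'
#' At each focal SNP, the allele with unweighted across-population mean
#' frequency above 0.5 in the basic pools is the basic allele, and the
#' other allele is the acidic allele. The frequency of the acidic allele
#' in the marine ancestor-proxy is taken from the (combined) marine pool's
#' read counts, and optionally per marine sub-sample.
#'
#' When the basic-habitat mean is exactly 0.5 the acidic-habitat mean
#' breaks the tie; SNPs with both habitat means exactly 0.5 are flagged
#' unpolarizable and dropped with a warning. A warning is also raised when
#' the acidic allele's acidic-habitat mean is not above 0.5 (the polarity
#' then rests on the basic habitat alone).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param snps data.frame with \code{chrom}, \code{pos} of focal SNPs (or
#'   integer row indices into \code{m}).
#' @param marine name of the combined marine population; default the single
#'   \code{"marine"}-habitat population.
#' @param marine_subsamples optional character vector of additional marine
#'   population names whose per-sub-sample acidic-allele frequencies are
#'   reported (for concordance analysis); these columns must be present in
#'   \code{m}.
#' @return data.frame of polarized SNPs: coordinates, \code{basic_allele},
#'   \code{acidic_allele}, \code{mean_basic_freq}, \code{mean_acidic_freq}
#'   (each allele's mean within its own habitat), \code{marine_acidic_freq},
#'   and one \code{marine_acidic_freq_<tag>} column per sub-sample.
#' @export
polarize <- function(m, snps, marine = NULL, marine_subsamples = NULL) {
  if (is.numeric(snps) && is.null(dim(snps))) {
    idx <- as.integer(snps)
  } else {
    idx <- match(paste(snps$chrom, snps$pos),
                 paste(m$snps$chrom, m$snps$pos))
    if (anyNA(idx)) stop("focal SNP(s) not present in the matrix")
  }
  if (is.null(marine)) {
    mar <- habitat_pops(m, "marine")
    if (length(mar) != 1) stop("pass `marine` when the matrix has ",
                               length(mar), " marine populations")
    marine <- mar
  }
  basic <- habitat_pops(m, "basic")
  acidic <- habitat_pops(m, "acidic")
  if (!length(basic) || !length(acidic)) {
    stop("need at least one population per freshwater habitat")
  }
  f <- pop_freq(m)[idx, , drop = FALSE]
  mean_ref_basic <- rowMeans(f[, basic, drop = FALSE], na.rm = TRUE)
  mean_ref_acid <- rowMeans(f[, acidic, drop = FALSE], na.rm = TRUE)

  # ref is the basic allele when its basic-habitat mean exceeds 0.5;
  # exact ties defer to the acidic habitat
  ref_is_basic <- mean_ref_basic > 0.5
  tie <- mean_ref_basic == 0.5
  ref_is_basic[tie] <- mean_ref_acid[tie] < 0.5
  unpol <- (tie & mean_ref_acid == 0.5) | is.na(mean_ref_basic) |
    is.na(mean_ref_acid)
  if (any(unpol)) {
    warning(sum(unpol), " SNP(s) unpolarizable (habitat means exactly 0.5 ",
            "or undefined); dropped")
  }

  mf <- pooled_freq(subset_snps(m, idx), marine)  # marine ref frequency
  basic_allele <- ifelse(ref_is_basic, m$snps$ref[idx], m$snps$alt[idx])
  acidic_allele <- ifelse(ref_is_basic, m$snps$alt[idx], m$snps$ref[idx])
  out <- data.frame(
    chrom = m$snps$chrom[idx], pos = m$snps$pos[idx],
    basic_allele = basic_allele, acidic_allele = acidic_allele,
    mean_basic_freq = ifelse(ref_is_basic, mean_ref_basic, 1 - mean_ref_basic),
    mean_acidic_freq = ifelse(ref_is_basic, 1 - mean_ref_acid, mean_ref_acid),
    marine_acidic_freq = ifelse(ref_is_basic, 1 - mf, mf),
    stringsAsFactors = FALSE)
  if (!is.null(marine_subsamples)) {
    for (s in marine_subsamples) {
      sf <- pooled_freq(subset_snps(m, idx), s)
      out[[paste0("marine_acidic_freq_", s)]] <-
        ifelse(ref_is_basic, 1 - sf, sf)
    }
  }
  weak <- !unpol & out$mean_acidic_freq <= 0.5
  if (any(weak)) {
    warning(sum(weak), " SNP(s) polarized by the basic habitat alone ",
            "(acidic allele not above 0.5 in acidic pools)")
  }
  out <- out[!unpol, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count SNPs whose acidic allele is the marine minor allele
#'
#' @param polarized output of \code{\link{polarize}}.
#' @return list with \code{k} (SNPs with marine acidic-allele frequency
#'   strictly below 0.5; exactly 0.5 is not minor) and \code{n}.
#' @export
marine_minor_count <- function(polarized) {
  if (!nrow(polarized)) stop("no polarized SNPs")
  f <- polarized$marine_acidic_freq
  list(k = sum(!is.na(f) & f < 0.5), n = sum(!is.na(f)))
}

#' Exact two-tailed binomial sign test
#'
#' Tests whether \code{k} successes out of \code{n} are compatible with a
#' fair coin: \code{p = min(1, 2 * P(X >= max(k, n - k)))} under
#' Binomial(n, 1/2) — the probability of an asymmetry of the observed
#' magnitude or greater in either direction.
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials (> 0).
#' @return list with \code{statistic} (= k), \code{n}, \code{p_value},
#'   \code{method = "exact_binomial"}.
#' @export
sign_binomial_test <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  kmax <- max(k, n - k)
  p <- min(1, 2 * pbinom(kmax - 1, n, 0.5, lower.tail = FALSE))
  list(statistic = k, n = n, p_value = p, method = "exact_binomial")
}

#' Select random control SNPs matched to the median differentiation
#'
#' Samples \code{n} SNPs without replacement among those whose integrated
#' AFD lies within a tolerance of the scan's median AFD, so that controls
#' carry typical (not outlier) differentiation.
#'
#' @param scan a \code{category_scan}.
#' @param n number of controls.
#' @param tolerance half-width of the eligibility window around the median;
#'   default 0.005.
#' @param mode \code{"relative"} (window \code{median * (1 +/- tolerance)},
#'   the default) or \code{"absolute"} (\code{median +/- tolerance}).
#' @param seed RNG seed.
#' @return integer vector of row indices into the scan (and the matrix the
#'   scan was computed from).
#' @export
select_random_controls <- function(scan, n, tolerance = 0.005,
                                   mode = c("relative", "absolute"), seed) {
  mode <- match.arg(mode)
  vals <- scan$mean_afd
  med <- median(vals, na.rm = TRUE)
  win <- if (mode == "relative") c(med * (1 - tolerance), med * (1 + tolerance))
         else c(med - tolerance, med + tolerance)
  eligible <- which(!is.na(vals) & vals >= win[1] & vals <= win[2])
  if (length(eligible) < n) {
    stop("only ", length(eligible), " SNPs within the median window; ",
         n, " requested")
  }
  with_seed(seed, sort(sample(eligible, n)))
}

#' Two-tailed permutation test on the absolute median difference
#'
#' Statistic \code{|median(a) - median(b)|}; the null distribution is built
#' by random relabelings of the pooled values at the original group sizes,
#' and \code{p = (b + 1) / (n_iter + 1)} where \code{b} counts null values
#' at least as large as observed. With \code{exact = TRUE} all
#' \code{choose(n_a + n_b, n_a)} relabelings are enumerated and
#' \code{p = #\{null >= observed\} / total} (the observed labeling is one of
#' them).
#'
#' @param a,b numeric vectors (non-empty).
#' @param n_iter number of random relabelings (default 9999).
#' @param seed RNG seed (ignored for exact enumeration).
#' @param exact enumerate all relabelings instead of sampling.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{n_iterations}, \code{seed}.
#' @export
median_permutation_test <- function(a, b, n_iter = 9999, seed = 1,
                                    exact = FALSE) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(median(a) - median(b))
  if (exact) {
    idx <- combn(length(pool), na)
    null <- apply(idx, 2L, function(i) {
      abs(median(pool[i]) - median(pool[-i]))
    })
    p <- sum(null >= obs) / ncol(idx)
    return(list(statistic = obs, p_value = p, method = "permutation_exact",
                n_iterations = ncol(idx), seed = NA_integer_))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      pi <- sample.int(length(pool), na)
      abs(median(pool[pi]) - median(pool[-pi]))
    }, 0)
  })
  p <- (sum(null >= obs) + 1) / (n_iter + 1)
  list(statistic = obs, p_value = p, method = "permutation",
       n_iterations = n_iter, seed = seed)
}
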