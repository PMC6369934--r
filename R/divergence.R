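#' Absolute allele frequency difference (AFD)
#'
#' \code{|p1 - p2|}; invariant to which allele (ref or alt) is tracked,
#' since \code{|(1-p1) - (1-p2)| = |p1 - p2|}. Missing frequencies
#' propagate as \code{NA}.
#'
#' @param p1,p2 allele frequencies in [0, 1] (vectorised).
#' @return AFD value(s) in [0, 1].
#' @export
afd <- function(p1, p2) abs(p1 - p2)

#' Pairwise AFD table over freshwater population pairs
#'
#' Computes AFD for every unordered pair of basic/acidic populations at
#' every SNP where both pools have depth of at least
#' \code{min_depth_per_pop} reads. With 5 basic and 5 acidic populations
#' this enumerates the 45 pairs: 25 basic-acidic (BA), 10 basic-basic (BB)
#' and 10 acidic-acidic (AA).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param min_depth_per_pop per-population depth requirement (default 50).
#' @return an \code{afd_table}: list with \code{pairs} (pop1, pop2,
#'   category) and \code{afd} (SNPs x pairs matrix, \code{NA} = missing),
#'   plus the SNP coordinate table.
#' @export
pairwise_scan <- function(m, min_depth_per_pop = 50) {
  fresh <- m$populations$name[m$populations$habitat %in% c("basic", "acidic")]
  if (length(fresh) < 2) stop("need at least two freshwater populations")
  hab <- setNames(m$populations$habitat, m$populations$name)
  prs <- t(combn(fresh, 2))
  cat_of <- function(h1, h2) {
    ifelse(h1 != h2, "BA", ifelse(h1 == "basic", "BB", "AA"))
  }
  pairs <- data.frame(pop1 = prs[, 1], pop2 = prs[, 2],
                      category = cat_of(hab[prs[, 1]], hab[prs[, 2]]),
                      stringsAsFactors = FALSE)
  build_afd_table(m, pairs, min_depth_per_pop)
}

#' Marine-vs-freshwater AFD table
#'
#' One pair per freshwater lake against the (combined) marine population;
#' category \code{MF}. Used as a filter input for phylogeny-SNP selection.
#'
#' @param m a \code{\link{snp_matrix}} containing one marine population.
#' @param marine name of the marine population (default: the single
#'   population with habitat \code{"marine"}).
#' @param min_depth_per_pop per-population depth requirement.
#' @return an \code{afd_table}.
#' @export
mf_scan <- function(m, marine = NULL, min_depth_per_pop = 50) {
  if (is.null(marine)) {
    marine <- habitat_pops(m, "marine")
    if (length(marine) != 1) {
      stop("matrix must contain exactly one marine population ",
           "(combine sub-samples first) or pass `marine`")
    }
  }
  fresh <- m$populations$name[m$populations$habitat %in% c("basic", "acidic")]
  pairs <- data.frame(pop1 = fresh, pop2 = marine, category = "MF",
                      stringsAsFactors = FALSE)
  build_afd_table(m, pairs, min_depth_per_pop)
}

build_afd_table <- function(m, pairs, min_depth_per_pop) {
  f <- pop_freq(m)
  d <- pop_depth(m)
  f[d < min_depth_per_pop] <- NA_real_
  a <- abs(f[, pairs$pop1, drop = FALSE] - f[, pairs$pop2, drop = FALSE])
  colnames(a) <- paste(pairs$pop1, pairs$pop2, sep = "-")
  structure(list(pairs = pairs, afd = a,
                 snps = m$snps[, c("chrom", "pos")]),
            class = "afd_table")
}

#' @export
print.afd_table <- function(x, ...) {
  cat(sprintf("afd_table: %d SNPs x %d pairs (%s)\n", nrow(x$afd),
              nrow(x$pairs),
              paste(sprintf("%d %s", table(x$pairs$category),
                            names(table(x$pairs$category))), collapse = ", ")))
  invisible(x)
}

#' Integrate pairwise AFD within a comparison category
#'
#' Per SNP, the unweighted mean of the available pair AFD values in the
#' category, reported only when at least \code{min_pairs} pairs contribute
#' (defaults: 18 for BA, 8 for BB and AA, 8 otherwise).
#'
#' @param table an \code{afd_table}.
#' @param category one of \code{"BA"}, \code{"BB"}, \code{"AA"}, \code{"MF"}.
#' @param min_pairs minimum contributing pairs; \code{NULL} picks the
#'   category default.
#' @return a \code{category_scan} data.frame: \code{chrom}, \code{pos},
#'   \code{mean_afd} (\code{NA} below the pair threshold), \code{n_pairs}.
#' @export
integrate_category <- function(table, category, min_pairs = NULL) {
  cols <- which(table$pairs$category == category)
  if (!length(cols)) stop("no pairs in category ", category)
  if (is.null(min_pairs)) min_pairs <- if (category == "BA") 18L else 8L
  sub <- table$afd[, cols, drop = FALSE]
  n_ok <- rowSums(!is.na(sub))
  mean_afd <- rowMeans(sub, na.rm = TRUE)
  mean_afd[n_ok < min_pairs] <- NA_real_
  out <- data.frame(chrom = table$snps$chrom, pos = table$snps$pos,
                    mean_afd = mean_afd, n_pairs = n_ok,
                    stringsAsFactors = FALSE)
  attr(out, "category") <- category
  attr(out, "min_pairs") <- min_pairs
  class(out) <- c("category_scan", "data.frame")
  out
}

#' Standardise pair AFD values by genome-wide pair means
#'
#' Divides each pair's AFD values by that pair's genome-wide mean AFD,
#' removing between-pair differences in overall differentiation (robustness
#' variant of the integration).
#'
#' @param table an \code{afd_table}.
#' @return an \code{afd_table} of standardised values.
#' @export
standardize_pairs <- function(table) {
  mu <- colMeans(table$afd, na.rm = TRUE)
  if (any(!is.finite(mu)) || any(mu == 0)) {
    stop("each pair needs at least one valid SNP and a non-zero mean AFD")
  }
  table$afd <- sweep(table$afd, 2L, mu, "/")
  table
}

#' Detect core SNPs in independent high-differentiation regions
#'
#' SNPs whose integrated AFD strictly exceeds the threshold (or the
#' empirical type-7 quantile, when \code{quantile} is given) are chained
#' per chromosome by single linkage: two passing SNPs belong to the same
#' region when separated by less than \code{max_gap} bp, and regions are
#' independent when separated by at least \code{max_gap}. The core SNP of
#' a region is its maximal-AFD member (ties broken by smallest position).
#'
#' @param scan a \code{category_scan}.
#' @param threshold absolute AFD threshold (default 0.70).
#' @param quantile empirical quantile (e.g. 0.9995) used instead of
#'   \code{threshold} when non-\code{NULL}.
#' @param max_gap independence distance in bp (default 50 kb).
#' @return data.frame of regions: \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{core_pos}, \code{core_afd}; zero rows when no SNP
#'   passes.
#' @export
detect_core_snps <- function(scan, threshold = 0.70, quantile = NULL,
                             max_gap = 50000) {
  vals <- scan$mean_afd
  if (!is.null(quantile)) {
    threshold <- stats::quantile(vals, probs = quantile, na.rm = TRUE,
                                 type = 7, names = FALSE)
  }
  pass <- which(!is.na(vals) & vals > threshold)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      core_pos = numeric(), core_afd = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(pass)) return(empty)
  df <- data.frame(chrom = scan$chrom[pass], pos = scan$pos[pass],
                   afd = vals[pass], stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, unique(scan$chrom)), df$pos), ]
  n <- nrow(df)
  new_region <- c(TRUE, df$chrom[-1] != df$chrom[-n] |
                        (df$pos[-1] - df$pos[-n]) >= max_gap)
  rid <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(df, factor(rid, levels = unique(rid))),
                               function(g) {
    core <- which(g$afd == max(g$afd))
    core <- core[which.min(g$pos[core])]
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_snps = nrow(g), core_pos = g$pos[core],
               core_afd = g$afd[core], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Hudson-style F_ST from pooled allele frequencies
#'
#' Estimator with sample-size correction,
#' \code{Fst = [ (p1-p2)^2 - p1(1-p1)/(d1-1) - p2(1-p2)/(d2-1) ] /
#' [ p1(1-p2) + p2(1-p1) ]}, clamped to [0, 1]; 0 by convention for a
#' monomorphic pair. Reported alongside AFD for parity with standard
#' pairwise-differentiation summaries; the read depths stand in for sample
#' sizes as usual in Pool-seq.
#'
#' @param p1,p2 allele frequencies (vectorised).
#' @param depth1,depth2 read depths (> 1).
#' @return F_ST value(s) in [0, 1].
#' @export
fst <- function(p1, p2, depth1, depth2) {
  if (any(depth1 <= 1 | depth2 <= 1, na.rm = TRUE)) {
    stop("depths must exceed 1 for the sample-size correction")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (depth1 - 1) - p2 * (1 - p2) / (depth2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- ifelse(den == 0, 0, pmin(1, pmax(0, num / den)))
  out
}
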