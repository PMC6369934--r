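# SNP ascertainment filters. All filters take and return a snp_matrix,
# preserve sort order, and are idempotent.

#' Filter SNPs by total read coverage over a population scope
#'
#' Keeps SNPs whose summed depth over the scope lies in
#' \code{[min_total, max_total]}; the upper bound guards against collapsed
#' repeats. The defaults are the global-freshwater-pool ascertainment
#' bounds (150, 2800).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param scope population names the depths are summed over; default all.
#' @param min_total,max_total inclusive depth bounds.
#' @return a filtered \code{snp_matrix}.
#' @export
filter_coverage <- function(m, scope = m$populations$name,
                            min_total = 150, max_total = 2800) {
  if (!length(scope)) stop("scope must be non-empty")
  if (min_total > max_total) stop("min_total > max_total")
  idx <- pop_index(m, scope)
  tot <- rowSums(pop_depth(m)[, idx, drop = FALSE])
  subset_snps(m, tot >= min_total & tot <= max_total)
}

#' Filter SNPs by pooled minor allele frequency
#'
#' Keeps SNPs whose MAF across the pooled scope (depth-weighted) is
#' strictly greater than \code{min_maf} ("superior to" the threshold).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param scope population names pooled for the MAF.
#' @param min_maf strict lower MAF bound in [0, 0.5).
#' @return a filtered \code{snp_matrix}.
#' @export
filter_maf <- function(m, scope = m$populations$name, min_maf = 0.05) {
  if (!length(scope)) stop("scope must be non-empty")
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must be in [0, 0.5)")
  maf <- pooled_maf(m, scope)
  keep <- !is.na(maf) & maf > min_maf
  subset_snps(m, keep)
}

#' Filter SNPs by distance to the nearest polymorphism
#'
#' Removes every SNP whose nearest neighbour on the same chromosome is
#' closer than \code{min_gap} bp (a microindel-stutter guard). Both members
#' of a too-close pair are removed: symmetric removal is the only
#' order-independent reading of a per-SNP nearest-neighbour rule.
#'
#' @param m a sorted \code{\link{snp_matrix}}.
#' @param min_gap minimum tolerated distance in bp (a gap equal to
#'   \code{min_gap} is kept: "at least").
#' @return a filtered \code{snp_matrix}.
#' @export
filter_spacing <- function(m, min_gap = 12) {
  pos <- m$snps$pos
  chrom <- m$snps$chrom
  n <- length(pos)
  if (n <= 1) return(m)
  same_next <- chrom[-n] == chrom[-1]
  gap_next <- c(ifelse(same_next, pos[-1] - pos[-n], Inf), Inf)
  gap_prev <- c(Inf, gap_next[-n])
  subset_snps(m, pmin(gap_next, gap_prev) >= min_gap)
}

#' Keep SNPs occurring alone on their RAD locus ("loner" SNPs)
#'
#' @param m a \code{\link{snp_matrix}} with populated locus identifiers.
#' @return a filtered \code{snp_matrix}.
#' @export
select_loner_snps <- function(m) {
  ids <- m$snps$locus_id
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("locus_id must be populated for loner-SNP selection")
  }
  counts <- table(ids)
  subset_snps(m, counts[ids] == 1L)
}

#' Select putatively neutral SNPs for phylogenies and ordination
#'
#' Keeps loner SNPs with per-population depth of at least
#' \code{min_pool_cov} in every pool, not strongly differentiated (AFD
#' above \code{max_afd}) in \emph{both} the basic-acidic and the
#' marine-freshwater integrated scans, and located within
#' \code{tip_window} bp of a chromosome end (high-recombination
#' peripheries).
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param scan_ba,scan_mf integrated \code{\link{integrate_category}} scans
#'   row-aligned with \code{m}.
#' @param min_pool_cov minimum per-pool depth (default 40).
#' @param max_afd differentiation ceiling (default 0.5); a SNP is dropped
#'   only when its mean AFD exceeds this in both scans.
#' @param tip_window distance from the nearest chromosome tip (default 5 Mb).
#' @return a filtered \code{snp_matrix}.
#' @export
select_phylogeny_snps <- function(m, scan_ba, scan_mf, min_pool_cov = 40,
                                  max_afd = 0.5, tip_window = 5e6) {
  if (nrow(scan_ba) != n_snps(m) || nrow(scan_mf) != n_snps(m)) {
    stop("scans must be row-aligned with the matrix")
  }
  if (is.null(m$layout)) stop("genome layout required for the tip filter")
  ids <- m$snps$locus_id
  loner <- table(ids)[ids] == 1L
  cov_ok <- rowSums(pop_depth(m) < min_pool_cov) == 0
  hi_ba <- !is.na(scan_ba$mean_afd) & scan_ba$mean_afd > max_afd
  hi_mf <- !is.na(scan_mf$mean_afd) & scan_mf$mean_afd > max_afd
  len <- m$layout$length[match(m$snps$chrom, m$layout$chrom)]
  tip_dist <- pmin(m$snps$pos, len - m$snps$pos + 1)
  subset_snps(m, loner & cov_ok & !(hi_ba & hi_mf) & tip_dist <= tip_window)
}

#' Thin SNPs to a minimum pairwise spacing (greedy)
#'
#' Left-to-right greedy retention per chromosome: a SNP is kept iff it lies
#' at least \code{min_gap} bp from the last kept SNP on that chromosome.
#'
#' @param m a sorted \code{\link{snp_matrix}}.
#' @param min_gap minimum spacing in bp (default 1 Mb).
#' @return a thinned \code{snp_matrix}.
#' @export
thin_by_distance <- function(m, min_gap = 1e6) {
  keep <- logical(n_snps(m))
  last_pos <- -Inf
  last_chrom <- ""
  pos <- m$snps$pos
  chrom <- m$snps$chrom
  for (i in seq_along(pos)) {
    if (chrom[i] != last_chrom || pos[i] - last_pos >= min_gap) {
      keep[i] <- TRUE
      last_pos <- pos[i]
      last_chrom <- chrom[i]
    }
  }
  subset_snps(m, keep)
}
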