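#' Population specification table
#'
#' Describes the sequenced population pools: a short unique name, the habitat
#' label used throughout the pipeline (\code{"basic"}, \code{"acidic"} or
#' \code{"marine"}), the number of diploid individuals in the pool, and an
#' optional group tag (e.g. a marine sub-sample label).
#'
#' @param name character vector of unique population names.
#' @param habitat character vector in \code{c("basic","acidic","marine")},
#'   recycled to \code{length(name)}.
#' @param pool_size integer vector of diploid pool sizes (>= 1), recycled.
#' @param group_tag optional character vector of sub-sample tags.
#' @return A \code{data.frame} with columns \code{name}, \code{habitat},
#'   \code{pool_size}, \code{group_tag}.
#' @export
population_spec <- function(name, habitat, pool_size, group_tag = NA_character_) {
  stopifnot(length(name) >= 1)
  if (anyDuplicated(name)) stop("population names must be unique")
  habitat <- rep_len(as.character(habitat), length(name))
  bad <- setdiff(unique(habitat), c("basic", "acidic", "marine"))
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  pool_size <- rep_len(as.integer(pool_size), length(name))
  if (any(pool_size < 1L)) stop("pool_size must be >= 1")
  data.frame(name = as.character(name), habitat = habitat,
             pool_size = pool_size,
             group_tag = rep_len(as.character(group_tag), length(name)),
             stringsAsFactors = FALSE)
}

#' Genome layout
#'
#' Ordered chromosome names and lengths. The layout fixes the chromosome
#' ordering used when sorting SNP records and bounds window clipping and
#' the chromosome-tip distance filter.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A \code{data.frame} with columns \code{chrom}, \code{length}.
#' @export
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  data.frame(chrom = as.character(chrom), length = length,
             stringsAsFactors = FALSE)
}

#' Construct a SNP count matrix
#'
#' The universal substrate of the pipeline: per-SNP, per-population biallelic
#' read counts with genome coordinates and RAD-locus identifiers. Records are
#' stored sorted by (chromosome in layout order, position); positions are
#' 1-based inclusive.
#'
#' @param snps data.frame with columns \code{chrom}, \code{pos},
#'   \code{locus_id}, \code{ref}, \code{alt}. Alleles must be distinct
#'   nucleotides in A/C/G/T.
#' @param ref_counts,alt_counts numeric matrices (SNPs x populations) of
#'   non-negative read counts; columns in population order.
#' @param populations a \code{\link{population_spec}} table.
#' @param layout a \code{\link{genome_layout}} table covering all SNP
#'   chromosomes.
#' @return An object of class \code{snp_matrix}.
#' @export
snp_matrix <- function(snps, ref_counts, alt_counts, populations, layout) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "locus_id", "ref", "alt")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns: ", paste(need, collapse = ", "))
  }
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  n <- nrow(snps)
  npop <- nrow(populations)
  if (nrow(ref_counts) != n || nrow(alt_counts) != n ||
      ncol(ref_counts) != npop || ncol(alt_counts) != npop) {
    stop("count matrices must be n_snps x n_populations")
  }
  if (any(ref_counts < 0) || any(alt_counts < 0)) stop("negative read counts")
  if (!all(snps$chrom %in% layout$chrom)) {
    stop("SNP chromosome(s) absent from layout")
  }
  maxlen <- layout$length[match(snps$chrom, layout$chrom)]
  if (any(snps$pos < 1 | snps$pos > maxlen)) {
    stop("SNP position outside chromosome bounds")
  }
  ok_nt <- c("A", "C", "G", "T")
  if (!all(snps$ref %in% ok_nt) || !all(snps$alt %in% ok_nt)) {
    stop("alleles must be nucleotides A/C/G/T")
  }
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  ord <- order(match(snps$chrom, layout$chrom), snps$pos)
  snps <- snps[ord, , drop = FALSE]
  ref_counts <- ref_counts[ord, , drop = FALSE]
  alt_counts <- alt_counts[ord, , drop = FALSE]
  if (anyDuplicated(snps[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) records")
  }
  rownames(snps) <- NULL
  dimnames(ref_counts) <- list(NULL, populations$name)
  dimnames(alt_counts) <- list(NULL, populations$name)
  structure(list(populations = populations, layout = layout, snps = snps,
                 ref_counts = ref_counts, alt_counts = alt_counts),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d SNPs x %d populations (%s)\n",
              nrow(x$snps), nrow(x$populations),
              paste(sprintf("%d %s", table(x$populations$habitat),
                            names(table(x$populations$habitat))),
                    collapse = ", ")))
  cat(sprintf("layout: %d chromosome(s), %.1f Mb total\n",
              nrow(x$layout), sum(x$layout$length) / 1e6))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) c(nrow(x$snps), nrow(x$populations))

#' Number of SNP records
#' @param m a \code{snp_matrix}.
#' @return integer count.
#' @export
n_snps <- function(m) nrow(m$snps)

#' Per-population read depth and reference-allele frequency
#'
#' \code{pop_depth} returns the SNPs x populations matrix of total read
#' depths; \code{pop_freq} the corresponding reference-allele frequencies,
#' \code{NA} wherever depth is zero (missing data, never coerced to 0).
#'
#' @param m a \code{snp_matrix}.
#' @return numeric matrix, SNPs x populations.
#' @export
pop_depth <- function(m) m$ref_counts + m$alt_counts

#' @rdname pop_depth
#' @export
pop_freq <- function(m) {
  d <- pop_depth(m)
  f <- m$ref_counts / d
  f[d == 0] <- NA_real_
  f
}

pop_index <- function(m, names) {
  idx <- match(names, m$populations$name)
  if (anyNA(idx)) {
    stop("unknown population(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Pooled allele frequency and minor allele frequency over a population set
#'
#' Frequencies are computed from summed read counts over the scope
#' (depth-weighted pooling). \code{pooled_maf} is \code{pmin(f, 1 - f)}.
#'
#' @param m a \code{snp_matrix}.
#' @param scope character vector of population names; default all.
#' @return numeric vector, one value per SNP (\code{NA} at zero pooled depth).
#' @export
pooled_freq <- function(m, scope = m$populations$name) {
  idx <- pop_index(m, scope)
  r <- rowSums(m$ref_counts[, idx, drop = FALSE])
  d <- r + rowSums(m$alt_counts[, idx, drop = FALSE])
  f <- r / d
  f[d == 0] <- NA_real_
  f
}

#' @rdname pooled_freq
#' @export
pooled_maf <- function(m, scope = m$populations$name) {
  f <- pooled_freq(m, scope)
  pmin(f, 1 - f)
}

#' Subset SNP records by row index
#'
#' @param m a \code{snp_matrix}.
#' @param idx integer or logical index into the SNP rows.
#' @return a \code{snp_matrix} with the selected records (order preserved).
#' @export
subset_snps <- function(m, idx) {
  m$snps <- m$snps[idx, , drop = FALSE]
  rownames(m$snps) <- NULL
  m$ref_counts <- m$ref_counts[idx, , drop = FALSE]
  m$alt_counts <- m$alt_counts[idx, , drop = FALSE]
  m
}

#' Combine populations by summing read counts
#'
#' Merges the named populations into a single population whose per-SNP
#' counts are the sums of the members' counts (depth-weighted pooling) and
#' whose pool size is the sum of the member pool sizes. The merged
#' population replaces the members at the position of the first; this is
#' how two marine sub-samples are combined into the single ancestral proxy.
#'
#' @param m a \code{snp_matrix}.
#' @param names character vector (length >= 2, distinct) of populations to merge.
#' @param new_name name for the merged population.
#' @param keep_members if \code{TRUE}, the member populations are retained
#'   and the combined population is appended instead of replacing them
#'   (useful when sub-sample and combined frequencies are both needed).
#' @return a \code{snp_matrix}.
#' @export
combine_populations <- function(m, names, new_name, keep_members = FALSE) {
  if (length(names) < 2 || anyDuplicated(names)) {
    stop("need at least two distinct population names to combine")
  }
  idx <- pop_index(m, names)
  if (new_name %in% setdiff(m$populations$name, names)) {
    stop("new_name collides with an existing population")
  }
  ref_new <- rowSums(m$ref_counts[, idx, drop = FALSE])
  alt_new <- rowSums(m$alt_counts[, idx, drop = FALSE])
  if (keep_members) {
    newpop <- m$populations[idx[1], , drop = FALSE]
    newpop$name <- new_name
    newpop$pool_size <- sum(m$populations$pool_size[idx])
    newpop$group_tag <- NA_character_
    m$populations <- rbind(m$populations, newpop)
    rownames(m$populations) <- NULL
    m$ref_counts <- cbind(m$ref_counts, ref_new)
    m$alt_counts <- cbind(m$alt_counts, alt_new)
    colnames(m$ref_counts) <- colnames(m$alt_counts) <- m$populations$name
    return(m)
  }
  keep <- setdiff(seq_len(nrow(m$populations)), idx[-1])
  at <- which(keep == idx[1])
  pops <- m$populations[keep, , drop = FALSE]
  pops$name[at] <- new_name
  pops$pool_size[at] <- sum(m$populations$pool_size[idx])
  pops$group_tag[at] <- NA_character_
  rownames(pops) <- NULL
  ref <- m$ref_counts[, keep, drop = FALSE]
  alt <- m$alt_counts[, keep, drop = FALSE]
  ref[, at] <- ref_new
  alt[, at] <- alt_new
  colnames(ref) <- colnames(alt) <- pops$name
  m$populations <- pops
  m$ref_counts <- ref
  m$alt_counts <- alt
  m
}

#' Population names belonging to a habitat
#' @param m a \code{snp_matrix}.
#' @param habitat one of \code{"basic"}, \code{"acidic"}, \code{"marine"}.
#' @return character vector of population names.
#' @export
habitat_pops <- function(m, habitat) {
  m$populations$name[m$populations$habitat == habitat]
}
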