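# Individual-like inputs from pooled frequencies: synthetic diploid IUPAC
# genotypes, binary similarity matrices for ordination, NJ trees.

iupac_code <- function(a1, a2) {
  codes <- c(AA = "A", CC = "C", GG = "G", TT = "T",
             AG = "R", GA = "R", CT = "Y", TC = "Y",
             CG = "S", GC = "S", AT = "W", TA = "W",
             GT = "K", TG = "K", AC = "M", CA = "M")
  out <- codes[paste0(a1, a2)]
  if (anyNA(out)) stop("invalid nucleotide pair for IUPAC encoding")
  unname(out)
}

#' Synthesize diploid genotypes from population pools
#'
#' Per population, each SNP's discrete allele pool of size
#' \code{2 * pool_size} is reconstructed by rounding the reference-allele
#' frequency times \code{2 * pool_size} to the nearest integer (ties up).
#' Two alleles per individual are then drawn at random \emph{without
#' replacement} from that pool — the draws for all individuals at one SNP
#' share the pool, so at most \code{pool_size} individuals can be
#' synthesized. Homozygotes are encoded as the base, heterozygotes as the
#' two-base IUPAC ambiguity code, and characters are concatenated in SNP
#' order.
#'
#' @param m a \code{\link{snp_matrix}} (every focal SNP must have depth > 0
#'   in every population).
#' @param snps focal SNP row indices or a data.frame with \code{chrom},
#'   \code{pos}.
#' @param n_individuals synthetic individuals per population.
#' @param seed RNG seed.
#' @return data.frame with \code{population}, \code{individual},
#'   \code{sequence} (one IUPAC character per SNP).
#' @export
synthesize_genotypes <- function(m, snps = seq_len(n_snps(m)),
                                 n_individuals = 10, seed) {
  idx <- resolve_snp_index(m, snps)
  sub <- subset_snps(m, idx)
  f <- pop_freq(sub)
  if (anyNA(f)) stop("every focal SNP needs depth > 0 in every population")
  nsnp <- nrow(f)
  out <- vector("list", nrow(sub$populations))
  with_seed(seed, {
    for (j in seq_len(nrow(sub$populations))) {
      two_n <- 2L * sub$populations$pool_size[j]
      if (2L * n_individuals > two_n) {
        stop("pool exhausted: 2 * n_individuals exceeds the ",
             sub$populations$name[j], " allele pool of ", two_n)
      }
      n_ref <- round_half_up(f[, j] * two_n)
      draws <- 2L * n_individuals
      # number of ref alleles among the draws: hypergeometric per SNP
      k_ref <- stats::rhyper(nsnp, n_ref, two_n - n_ref, draws)
      # scatter the k_ref reference alleles over the draw slots at random
      u <- matrix(runif(nsnp * draws), nsnp, draws)
      rk <- t(apply(u, 1L, rank, ties.method = "first"))
      is_ref <- rk <= k_ref
      seqs <- character(n_individuals)
      for (i in seq_len(n_individuals)) {
        a1 <- ifelse(is_ref[, 2L * i - 1L], sub$snps$ref, sub$snps$alt)
        a2 <- ifelse(is_ref[, 2L * i], sub$snps$ref, sub$snps$alt)
        seqs[i] <- paste(iupac_code(a1, a2), collapse = "")
      }
      out[[j]] <- data.frame(population = sub$populations$name[j],
                             individual = paste0(sub$populations$name[j],
                                                 "_", seq_len(n_individuals)),
                             sequence = seqs, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

resolve_snp_index <- function(m, snps) {
  if (is.numeric(snps) && is.null(dim(snps))) return(as.integer(snps))
  idx <- match(paste(snps$chrom, snps$pos), paste(m$snps$chrom, m$snps$pos))
  if (anyNA(idx)) stop("focal SNP(s) not present in the matrix")
  idx
}

#' Write synthetic genotypes as FASTA
#'
#' One record per synthetic individual, named \code{<pop>_<i>}.
#'
#' @param genotypes output of \code{\link{synthesize_genotypes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes_fasta <- function(genotypes, path) {
  x <- Biostrings::DNAStringSet(genotypes$sequence)
  names(x) <- genotypes$individual
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genotype FASTA back into a data.frame
#' @param path FASTA path.
#' @return data.frame with \code{individual}, \code{sequence}.
#' @export
read_genotypes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(individual = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binary population similarity (Euclidean distance on sampled alleles)
#'
#' Per SNP, the major allele is identified over the pooled
#' \code{scope_for_major} populations (depth-weighted); then one allele is
#' sampled from every population (probability equal to its pool frequency)
#' and coded 1 (major) or 0 (minor). The distance between two populations
#' is the Euclidean distance between their 0/1 vectors, i.e. the square
#' root of the mismatch count. SNPs with undefined frequency in any
#' population are skipped with a warning.
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param snps focal SNP indices or coordinate data.frame.
#' @param scope_for_major populations defining major/minor (default: all
#'   basic and acidic pools — the global freshwater pool).
#' @param seed RNG seed.
#' @return a symmetric distance matrix (class \code{matrix}) with zero
#'   diagonal, labelled by population.
#' @export
binary_similarity <- function(m, snps = seq_len(n_snps(m)),
                              scope_for_major = NULL, seed) {
  idx <- resolve_snp_index(m, snps)
  sub <- subset_snps(m, idx)
  if (is.null(scope_for_major)) {
    scope_for_major <- sub$populations$name[
      sub$populations$habitat %in% c("basic", "acidic")]
  }
  f <- pop_freq(sub)
  drop <- rowSums(is.na(f)) > 0
  if (any(drop)) {
    warning(sum(drop), " SNP(s) skipped: undefined frequency in some population")
    sub <- subset_snps(sub, !drop)
    f <- f[!drop, , drop = FALSE]
  }
  major_ref <- pooled_freq(sub, scope_for_major) >= 0.5  # major allele is ref?
  p_major <- f                                            # per pop, per SNP
  p_major[!major_ref, ] <- 1 - f[!major_ref, , drop = FALSE]
  coded <- with_seed(seed, {
    matrix(runif(length(p_major)) < p_major, nrow(p_major), ncol(p_major))
  })
  d <- as.matrix(dist(t(coded * 1)))
  dimnames(d) <- list(sub$populations$name, sub$populations$name)
  d
}

#' Neighbor-joining tree from a population distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}), deterministic given the
#' matrix; returns the tree and can serialize it as Newick.
#'
#' @param d symmetric distance matrix with zero diagonal (>= 3 taxa).
#' @return an \pkg{ape} \code{phylo} object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least three populations")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  ape::nj(as.dist(d))
}

#' Newick serialization of a tree
#' @param tree a \code{phylo} object.
#' @return single Newick string with branch lengths.
#' @export
tree_newick <- function(tree) ape::write.tree(tree)

#' Non-metric multidimensional scaling of a population distance matrix
#'
#' Kruskal stress-1 minimising NMDS via \code{MASS::isoMDS}, seeded for
#' reproducibility. Off-diagonal zero distances (not representable by
#' isoMDS) are nudged up to half the smallest positive distance with a
#' warning. Stress is returned as a fraction in [0, 1].
#'
#' @param d symmetric distance matrix.
#' @param n_dims embedding dimension (default 2; use 1 for a single
#'   ordination axis).
#' @param seed RNG seed.
#' @return list with \code{points} (populations x n_dims) and \code{stress}.
#' @export
ordinate <- function(d, n_dims = 2, seed = 1) {
  d <- as.matrix(d)
  if (nrow(d) < n_dims + 1) stop("need more populations than dimensions")
  off <- d[upper.tri(d)]
  if (all(off == 0)) stop("degenerate all-zero distance matrix")
  if (any(off == 0)) {
    warning("zero off-diagonal distance(s) nudged for NMDS")
    eps <- min(off[off > 0]) / 2
    d[d == 0] <- eps
    diag(d) <- 0
  }
  fit <- with_seed(seed, MASS::isoMDS(as.dist(d), k = n_dims, trace = FALSE))
  list(points = fit$points, stress = fit$stress / 100)
}
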