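# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

toy_layout <- function(n_chrom = 2, len = 1e6) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

toy_populations <- function(n_basic = 2, n_acidic = 2, marine = TRUE) {
  name <- c(if (n_basic) paste0("B", seq_len(n_basic)),
            if (n_acidic) paste0("A", seq_len(n_acidic)),
            if (marine) "MAR")
  habitat <- c(rep("basic", n_basic), rep("acidic", n_acidic),
               if (marine) "marine")
  population_spec(name, habitat, pool_size = 30)
}

# A fixed 3-SNP matrix with hand-set counts (2 basic, 2 acidic, 1 marine).
toy_matrix <- function() {
  pops <- toy_populations()
  lay <- toy_layout()
  snps <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100L, 500L, 250L),
                     locus_id = c("L1", "L2", "L3"),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  ref <- matrix(c(90, 10, 50,
                  80, 20, 55,
                  10, 85, 45,
                   5, 95, 60,
                  40, 50, 52), nrow = 3, ncol = 5)
  alt <- matrix(c(10, 90, 50,
                  20, 80, 45,
                  90, 15, 55,
                  95,  5, 40,
                  60, 50, 48), nrow = 3, ncol = 5)
  snp_matrix(snps, ref, alt, pops, lay)
}

# Random matrix for oracle comparisons: uniform positions, random counts.
random_matrix <- function(n_snps = 50, pops = toy_populations(), seed = 1,
                          layout = toy_layout(), mean_depth = 60) {
  set.seed(seed)
  chrom <- sample(layout$chrom, n_snps, replace = TRUE)
  pos <- integer(n_snps)
  repeat {
    pos <- vapply(seq_len(n_snps), function(i)
      sample.int(layout$length[match(chrom[i], layout$chrom)], 1L), 0L)
    if (!anyDuplicated(data.frame(chrom, pos))) break
  }
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n_snps, replace = TRUE)
  alt <- nts[(match(ref, nts) - 1L + sample(3L, n_snps, replace = TRUE)) %% 4L + 1L]
  snps <- data.frame(chrom = chrom, pos = pos,
                     locus_id = paste0("L", sample(ceiling(n_snps / 2), n_snps,
                                                   replace = TRUE)),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  npop <- nrow(pops)
  depth <- matrix(rpois(n_snps * npop, mean_depth), n_snps, npop)
  p <- matrix(runif(n_snps * npop), n_snps, npop)
  refc <- matrix(rbinom(n_snps * npop, as.vector(depth), as.vector(p)),
                 n_snps, npop)
  snp_matrix(snps, refc, depth - refc, pops, layout)
}

# Small cohort for fast end-to-end tests.
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(layout = genome_layout(paste0("chr", 1:6), rep(2.5e6, 6)),
                n_neutral_snps = 6000, n_selected_loci = 5, seed = seed, ...)
}

expect_same_matrix <- function(a, b) {
  expect_equal(a$snps, b$snps)
  expect_equal(unname(a$ref_counts), unname(b$ref_counts))
  expect_equal(unname(a$alt_counts), unname(b$alt_counts))
  expect_equal(a$populations$name, b$populations$name)
}
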