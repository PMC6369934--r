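# Each filter is checked on its boundary examples and against a
# brute-force oracle on random matrices.

test_that("coverage filter enforces inclusive depth bounds", {
  pops <- toy_populations(1, 1, marine = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                     locus_id = paste0("L", 1:3), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  ref <- matrix(c(74, 75, 1400, 75, 75, 1401), 3, 2)  # totals 149,150,2801
  m <- snp_matrix(snps, ref, matrix(0, 3, 2), pops, toy_layout(1))
  kept <- filter_coverage(m, min_total = 150, max_total = 2800)
  expect_equal(kept$snps$pos, 200L)
  expect_equal(n_snps(filter_coverage(m, min_total = 0, max_total = Inf)), 3L)
  expect_error(filter_coverage(m, min_total = 10, max_total = 5), "min_total")

  r <- random_matrix(400, seed = 2)
  surv <- filter_coverage(r, min_total = 250, max_total = 330)
  tot <- rowSums(r$ref_counts + r$alt_counts)
  expect_equal(surv$snps$pos, r$snps$pos[tot >= 250 & tot <= 330])
})

test_that("MAF filter is strict at the threshold", {
  pops <- toy_populations(1, 1, marine = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(10L, 20L), locus_id = c("a", "b"),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  # pooled 5/95 (MAF exactly 0.05) and 50/50
  m <- snp_matrix(snps, matrix(c(3, 25, 2, 25), 2, 2),
                  matrix(c(45, 25, 50, 25), 2, 2), pops, toy_layout(1))
  expect_equal(pooled_maf(m), c(0.05, 0.5))
  kept <- filter_maf(m, min_maf = 0.05)
  expect_equal(kept$snps$pos, 20L)  # exactly 0.05 removed ("superior to")
  expect_error(filter_maf(m, min_maf = 0.6), "0.5")

  r <- random_matrix(500, seed = 9)
  surv <- filter_maf(r, min_maf = 0.2)
  maf <- pooled_maf(r)
  expect_equal(surv$snps$pos, r$snps$pos[!is.na(maf) & maf > 0.2])
})

test_that("spacing filter removes both members of a too-close pair", {
  pops <- toy_populations(1, 1, marine = FALSE)
  mk <- function(pos) {
    snps <- data.frame(chrom = "chr1", pos = pos,
                       locus_id = paste0("L", seq_along(pos)),
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
    snp_matrix(snps, matrix(10, length(pos), 2), matrix(10, length(pos), 2),
               pops, toy_layout(1))
  }
  expect_equal(n_snps(filter_spacing(mk(c(100L, 111L)), 12)), 0L)  # gap 11
  expect_equal(n_snps(filter_spacing(mk(c(100L, 112L)), 12)), 2L)  # gap 12

  # oracle: O(n^2) nearest-neighbour scan per chromosome
  r <- random_matrix(300, seed = 4, layout = toy_layout(2, 3000))
  got <- filter_spacing(r, 12)
  keep <- vapply(seq_len(n_snps(r)), function(i) {
    same <- which(r$snps$chrom == r$snps$chrom[i])
    same <- setdiff(same, i)
    !length(same) || min(abs(r$snps$pos[same] - r$snps$pos[i])) >= 12
  }, NA)
  expect_equal(got$snps$pos, r$snps$pos[keep])
})

test_that("loner selection keeps single-SNP RAD loci only", {
  r <- random_matrix(300, seed = 6)
  got <- select_loner_snps(r)
  tab <- table(r$snps$locus_id)
  expect_equal(got$snps$pos, r$snps$pos[tab[r$snps$locus_id] == 1])
  expect_equal(n_snps(select_loner_snps(got)), n_snps(got))  # idempotent
  bad <- r; bad$snps$locus_id <- ""
  expect_error(select_loner_snps(bad), "locus_id")
})

test_that("phylogeny-SNP selection applies the tip, coverage and AFD rules", {
  pops <- toy_populations(2, 2, marine = FALSE)
  lay <- genome_layout("chrI", 3e7)
  pos <- c(4999999L, 6000000L, 29000000L)
  snps <- data.frame(chrom = "chrI", pos = pos, locus_id = paste0("L", 1:3),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  m <- snp_matrix(snps, matrix(30, 3, 4), matrix(30, 3, 4), pops, lay)
  mk_scan <- function(afd) {
    s <- data.frame(chrom = "chrI", pos = pos, mean_afd = afd, n_pairs = 10L)
    class(s) <- c("category_scan", "data.frame"); s
  }
  # all low AFD: only the tip rule discriminates (29 Mb is 1 Mb from the end)
  got <- select_phylogeny_snps(m, mk_scan(c(0.1, 0.1, 0.1)),
                               mk_scan(c(0.1, 0.1, 0.1)))
  expect_equal(got$snps$pos, c(4999999L, 29000000L))
  # dropped only when AFD > 0.5 in BOTH scans
  got2 <- select_phylogeny_snps(m, mk_scan(c(0.6, 0.1, 0.6)),
                                mk_scan(c(0.3, 0.1, 0.7)))
  # first kept (high in one scan only), third excluded (high in both)
  expect_equal(got2$snps$pos, 4999999L)
  # per-pool coverage
  m$ref_counts[1, 2] <- 5; m$alt_counts[1, 2] <- 5
  got3 <- select_phylogeny_snps(m, mk_scan(c(0.1, 0.1, 0.1)),
                                mk_scan(c(0.1, 0.1, 0.1)), min_pool_cov = 40)
  expect_equal(got3$snps$pos, 29000000L)
})

test_that("phylogeny-SNP selection equals the brute-force conjunction", {
  r <- random_matrix(400, seed = 8, layout = toy_layout(2, 8e6))
  set.seed(81)
  sa <- data.frame(chrom = r$snps$chrom, pos = r$snps$pos,
                   mean_afd = runif(400), n_pairs = 10L)
  sm <- data.frame(chrom = r$snps$chrom, pos = r$snps$pos,
                   mean_afd = runif(400), n_pairs = 10L)
  got <- select_phylogeny_snps(r, sa, sm, min_pool_cov = 50, max_afd = 0.5,
                               tip_window = 2e6)
  tab <- table(r$snps$locus_id)
  len <- r$layout$length[match(r$snps$chrom, r$layout$chrom)]
  keep <- tab[r$snps$locus_id] == 1 &
    apply(pop_depth(r) >= 50, 1, all) &
    !(sa$mean_afd > 0.5 & sm$mean_afd > 0.5) &
    pmin(r$snps$pos, len - r$snps$pos + 1) <= 2e6
  expect_equal(got$snps$pos, r$snps$pos[as.vector(keep)])
})

test_that("greedy thinning enforces the minimum spacing", {
  pops <- toy_populations(1, 1, marine = FALSE)
  lay <- genome_layout("chr1", 2e6)
  snps <- data.frame(chrom = "chr1", pos = c(1L, 500000L, 1000001L),
                     locus_id = paste0("L", 1:3), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  m <- snp_matrix(snps, matrix(10, 3, 2), matrix(10, 3, 2), pops, lay)
  got <- thin_by_distance(m, 1e6)
  expect_equal(got$snps$pos, c(1L, 1000001L))
  expect_equal(n_snps(thin_by_distance(subset_snps(m, 1), 1e6)), 1L)

  r <- random_matrix(500, seed = 10, layout = toy_layout(3, 5e4))
  th <- thin_by_distance(r, 2000)
  by_chr <- split(th$snps$pos, th$snps$chrom)
  expect_true(all(vapply(by_chr, function(p)
    length(p) < 2 || min(diff(sort(p))) >= 2000, NA)))
  expect_same_matrix(thin_by_distance(th, 2000), th)  # idempotent
})

test_that("filters are order-stable and never increase the SNP count", {
  r <- random_matrix(400, seed = 12)
  f1 <- filter_maf(r, min_maf = 0.1)
  expect_lte(n_snps(f1), n_snps(r))
  f2 <- filter_coverage(f1, min_total = 200, max_total = 400)
  expect_lte(n_snps(f2), n_snps(f1))
  expect_false(is.unsorted(order(match(f2$snps$chrom, f2$layout$chrom),
                                 f2$snps$pos)))
})
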