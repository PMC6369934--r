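window_matrix <- function(pos, maf_by_pop, pops = toy_populations(),
                          depth = 100, layout = toy_layout(1)) {
  # maf_by_pop: SNPs x populations per-population MAFs (ref freq = 1 - maf)
  n <- length(pos)
  snps <- data.frame(chrom = layout$chrom[1], pos = as.integer(pos),
                     locus_id = paste0("L", seq_len(n)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  f <- 1 - maf_by_pop
  ref <- round(f * depth)
  snp_matrix(snps, ref, depth - ref, pops, layout)
}

test_that("high-MAF window counting is strict and clipped", {
  pops <- toy_populations(1, 0, marine = FALSE)
  mafs <- matrix(c(0.1, 0.25, 0.31, 0.4, 0.5), 5, 1)
  m <- window_matrix(c(100, 200, 300, 400, 500), mafs, pops = pops)
  expect_equal(high_maf_count(m, "B1", "chr1", 300, 1000, 0.3), 3L)
  expect_equal(high_maf_count(m, "B1", "chr1", 300, 100, 0.3), 1L)
  expect_equal(high_maf_count(m, "B1", "chr1", 900000, 1000, 0.3), 0L)
  # zero-depth SNP is missing, not counted
  m$ref_counts[5, 1] <- 0; m$alt_counts[5, 1] <- 0
  expect_equal(high_maf_count(m, "B1", "chr1", 300, 1000, 0.3), 2L)
  expect_error(high_maf_count(m, "B1", "chrX", 300, 1000, 0.3), "unknown")
})

test_that("window counts match a brute-force oracle on random instances", {
  for (s in 1:25) {
    r <- random_matrix(60, seed = 100 + s, layout = toy_layout(2, 5e4),
                       pops = toy_populations(2, 1, marine = FALSE))
    set.seed(200 + s)
    chrom <- sample(r$layout$chrom, 1)
    center <- sample.int(5e4, 1)
    width <- sample(c(2000, 10000, 40000), 1)
    popn <- sample(r$populations$name, 1)
    got <- high_maf_count(r, popn, chrom, center, width, 0.3)
    f <- pop_freq(r)[, popn]
    maf <- pmin(f, 1 - f)
    want <- sum(r$snps$chrom == chrom &
                  r$snps$pos >= center - width / 2 &
                  r$snps$pos <= center + width / 2 &
                  !is.na(maf) & maf > 0.3)
    expect_equal(got, want)
  }
})

test_that("relative density is a ratio of habitat-summed window counts", {
  pops <- toy_populations(2, 0, marine = FALSE)
  mafs <- matrix(0.4, 10, 2)
  m <- window_matrix(seq(1000, 10000, by = 1000), mafs, pops = pops)
  # all SNPs inside both windows: ratio 1
  expect_equal(relative_density(m, "chr1", 5000, c("B1", "B2"),
                                w_small = 20000, w_large = 20000), 1)
  # no high-MAF SNPs in the small window, some in the large: 0
  expect_equal(relative_density(m, "chr1", 500000, c("B1", "B2"),
                                w_small = 1000, w_large = 1e6), 0)
  # undefined when the large window has no qualifying SNPs
  expect_true(is.na(relative_density(m, "chr1", 900000, c("B1", "B2"),
                                     w_small = 1000, w_large = 2000)))
  expect_error(relative_density(m, "chr1", 5000, "B1", w_small = 2000,
                                w_large = 1000), "exceed")
  # duplicating every population leaves the ratio unchanged
  m2 <- m
  m2$populations <- rbind(m$populations,
                          population_spec(c("B1b", "B2b"), "basic", 30))
  m2$ref_counts <- cbind(m$ref_counts, m$ref_counts)
  m2$alt_counts <- cbind(m$alt_counts, m$alt_counts)
  colnames(m2$ref_counts) <- colnames(m2$alt_counts) <- m2$populations$name
  expect_equal(relative_density(m, "chr1", 5000, c("B1", "B2"),
                                w_small = 4000, w_large = 20000),
               relative_density(m2, "chr1", 5000,
                                c("B1", "B2", "B1b", "B2b"),
                                w_small = 4000, w_large = 20000))
  # brute-force oracle on random instances
  for (s in 1:25) {
    r <- random_matrix(80, seed = 300 + s, layout = toy_layout(1, 1e5))
    set.seed(400 + s)
    center <- sample.int(1e5, 1)
    hab <- c("B1", "B2")
    got <- relative_density(r, "chr1", center, hab,
                            w_small = 10000, w_large = 50000)
    cnt <- function(w) sum(vapply(hab, function(p) {
      f <- pop_freq(r)[, p]
      maf <- pmin(f, 1 - f)
      sum(r$snps$pos >= center - w / 2 & r$snps$pos <= center + w / 2 &
            !is.na(maf) & maf > 0.3)
    }, 0))
    want <- if (cnt(50000) == 0) NA_real_ else cnt(10000) / cnt(50000)
    expect_equal(got, want)
  }
})

test_that("sweep contrasts are zero for identical habitats and respond to sweeps", {
  pops <- toy_populations(2, 2, marine = FALSE)
  set.seed(41)
  mafs_b <- matrix(runif(200, 0, 0.5), 100, 2)
  m <- window_matrix(seq(500, 50000, length.out = 100),
                     cbind(mafs_b, mafs_b), pops = pops,
                     layout = toy_layout(1, 2e6))
  focal <- data.frame(chrom = "chr1", pos = 25000L,
                      marine_acidic_freq = 0.3)
  sw <- sweep_contrasts(m, focal, basic_pops = c("B1", "B2"),
                        acidic_pops = c("A1", "A2"),
                        w_small = 20000, w_large = 100000)
  expect_equal(sw$delta, 0)
  # halve acidic diversity in the small window only: positive delta
  small <- abs(m$snps$pos - 25000) <= 10000
  mafs_a <- cbind(mafs_b, mafs_b)
  mafs_a[small, 3:4] <- mafs_a[small, 3:4] * 0.5
  m2 <- window_matrix(m$snps$pos, mafs_a, pops = pops,
                      layout = toy_layout(1, 2e6))
  sw2 <- sweep_contrasts(m2, focal, basic_pops = c("B1", "B2"),
                         acidic_pops = c("A1", "A2"),
                         w_small = 20000, w_large = 100000)
  expect_gt(sw2$delta, 0)
})

test_that("bootstrap correlation reports exact and null-calibrated values", {
  x <- seq(0.05, 0.45, length.out = 20)
  st <- data.frame(delta = -x, marine_acidic_freq = x)
  r <- correlate_bootstrap(st, n_boot = 200, seed = 1)
  expect_equal(r$r, -1)
  expect_equal(r$ci_low, -1)
  expect_equal(r$ci_high, -1)
  expect_error(correlate_bootstrap(data.frame(delta = rep(1, 5),
                                              marine_acidic_freq = 1:5),
                                   n_boot = 10, seed = 1), "variance")
  # null calibration: independent pairs at n = 42 mostly within 2/sqrt(n)
  set.seed(2)
  inside <- vapply(1:200, function(i) {
    st0 <- data.frame(delta = rnorm(42), marine_acidic_freq = rnorm(42))
    abs(cor(st0$delta, st0$marine_acidic_freq)) < 2 / sqrt(42)
  }, NA)
  expect_gte(mean(inside), 0.85)
})

test_that("pooled pi applies the depth correction and window scaling", {
  pops <- toy_populations(1, 0, marine = FALSE)
  m <- window_matrix(5000, matrix(0.5, 1, 1), pops = pops, depth = 10000)
  # single SNP at p = 0.5, large depth: pi ~ 0.5 / window length
  got <- pooled_pi(m, "B1", "chr1", 5000, 999)
  expect_equal(got, (10000 / 9999) * 0.5 / 1000, tolerance = 1e-6)
  expect_equal(pooled_pi(m, "B1", "chr1", 500000, 1000), 0)
  # brute-force oracle on a random matrix
  r <- random_matrix(50, seed = 50, layout = toy_layout(1, 2e4))
  want <- {
    rows <- which(r$snps$pos >= 4000 & r$snps$pos <= 14000)
    dep <- pop_depth(r)[rows, "B1"]
    p <- pop_freq(r)[rows, "B1"]
    keep <- dep > 1
    sum(dep[keep] / (dep[keep] - 1) * 2 * p[keep] * (1 - p[keep])) / 10001
  }
  expect_equal(pooled_pi(r, "B1", "chr1", 9000, 10000), want)
})

test_that("habitat diversity test matches exhaustive label enumeration", {
  pops <- toy_populations(5, 5, marine = FALSE)
  r <- random_matrix(400, seed = 60, pops = pops, layout = toy_layout(2, 1e5))
  wins <- data.frame(chrom = c("chr1", "chr2"), center = c(50000, 50000))
  b <- paste0("B", 1:5); a <- paste0("A", 1:5)
  got <- habitat_diversity_test(r, wins, b, a, width = 60000, exact = TRUE)
  expect_equal(got$n_iterations, choose(10, 5))
  # independent oracle: recount windows by hand and enumerate labels
  counts <- sapply(c(b, a), function(p) {
    vapply(1:2, function(i) {
      f <- pop_freq(r)[, p]
      maf <- pmin(f, 1 - f)
      sum(r$snps$chrom == wins$chrom[i] &
            abs(r$snps$pos - wins$center[i]) <= 30000 &
            !is.na(maf) & maf > 0.3)
    }, 0L)
  })
  med <- apply(counts, 2, median)
  obs <- abs(median(med[1:5]) - median(med[6:10]))
  null <- apply(combn(10, 5), 2, function(i)
    abs(median(med[i]) - median(med[-i])))
  expect_equal(got$statistic, obs)
  expect_equal(got$p_value, mean(null >= obs))
  # identical populations give p = 1 under random permutations
  r2 <- r
  for (p in c(b, a)) { r2$ref_counts[, p] <- r$ref_counts[, "B1"]
                       r2$alt_counts[, p] <- r$alt_counts[, "B1"] }
  same <- habitat_diversity_test(r2, wins, b, a, width = 60000,
                                 n_iter = 99, seed = 1)
  expect_equal(same$p_value, 1)
})

test_that("rarer planted ancestral alleles produce larger sweep contrasts", {
  # three-point grid of ancestral acidic-allele frequency ranges: the
  # mean B-A density contrast at planted loci should weakly increase as
  # the selected allele starts rarer
  mean_delta <- vapply(list(c(0.05, 0.10), c(0.22, 0.27), c(0.40, 0.45)),
                       function(rng) {
    cfg <- small_cohort_config(seed = 11,
                               ancestral_acidic_freq_range = rng)
    cohort <- simulate_cohort(cfg)
    sel <- which(cohort$truth$class == "selected_core")
    focal <- data.frame(chrom = cohort$matrix$snps$chrom[sel],
                        pos = cohort$matrix$snps$pos[sel],
                        marine_acidic_freq = cohort$truth$p0_acidic[sel])
    sw <- suppressMessages(sweep_contrasts(
      cohort$matrix, focal,
      basic_pops = habitat_pops(cohort$matrix, "basic"),
      acidic_pops = habitat_pops(cohort$matrix, "acidic")))
    mean(sw$delta)
  }, 0)
  expect_true(all(diff(mean_delta) <= 0))
  expect_gt(mean_delta[1], mean_delta[3])
})
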