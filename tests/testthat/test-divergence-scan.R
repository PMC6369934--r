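test_that("afd is the absolute frequency difference, allele-invariant", {
  expect_equal(afd(0.5, 0.5), 0)
  expect_equal(afd(1.0, 0.0), 1.0)
  expect_equal(afd(0.85, 0.15), 0.70)
  p <- runif(20); q <- runif(20)
  expect_equal(afd(p, q), afd(1 - p, 1 - q))
  expect_true(is.na(afd(NA, 0.3)))
})

test_that("pairwise_scan enumerates freshwater pairs by category", {
  pops <- toy_populations(5, 5)
  r <- random_matrix(100, pops = pops, seed = 14)
  tab <- pairwise_scan(r, min_depth_per_pop = 50)
  expect_equal(nrow(tab$pairs), 45L)
  expect_equal(as.vector(table(tab$pairs$category)[c("BA", "BB", "AA")]),
               c(25L, 10L, 10L))
  # a pool below the depth floor silences that SNP for all its pairs
  r$ref_counts[1, "B1"] <- 10; r$alt_counts[1, "B1"] <- 10
  tab2 <- pairwise_scan(r, min_depth_per_pop = 50)
  b1_pairs <- tab2$pairs$pop1 == "B1" | tab2$pairs$pop2 == "B1"
  expect_true(all(is.na(tab2$afd[1, b1_pairs])))

  # oracle: brute-force double loop over pairs and SNPs
  f <- pop_freq(r); d <- pop_depth(r)
  for (k in sample(nrow(tab2$pairs), 10)) {
    p1 <- tab2$pairs$pop1[k]; p2 <- tab2$pairs$pop2[k]
    want <- vapply(seq_len(n_snps(r)), function(i) {
      if (d[i, p1] < 50 || d[i, p2] < 50) return(NA_real_)
      abs(f[i, p1] - f[i, p2])
    }, 0)
    expect_equal(unname(tab2$afd[, k]), want)
  }
})

test_that("category integration means available pairs above the minimum", {
  pops <- toy_populations(5, 5)
  r <- random_matrix(300, pops = pops, seed = 15, mean_depth = 70)
  tab <- pairwise_scan(r, min_depth_per_pop = 50)
  for (cat in c("BA", "BB", "AA")) {
    minp <- if (cat == "BA") 18L else 8L
    scan <- integrate_category(tab, cat, minp)
    cols <- tab$pairs$category == cat
    want_n <- rowSums(!is.na(tab$afd[, cols, drop = FALSE]))
    want <- rowMeans(tab$afd[, cols, drop = FALSE], na.rm = TRUE)
    want[want_n < minp] <- NA_real_
    expect_equal(scan$mean_afd, unname(want))
    expect_equal(scan$n_pairs, unname(want_n))
  }
  # 17 valid BA pairs at a minimum of 18 leaves the SNP missing
  tab$afd[1, which(tab$pairs$category == "BA")[1:8]] <- NA
  s <- integrate_category(tab, "BA", 18L)
  expect_true(is.na(s$mean_afd[1]))
  expect_equal(s$n_pairs[1], 17L)
})

test_that("pair standardization divides by genome-wide pair means", {
  pops <- toy_populations(2, 2, marine = FALSE)
  r <- random_matrix(200, pops = pops, seed = 16)
  tab <- pairwise_scan(r, min_depth_per_pop = 1)
  st <- standardize_pairs(tab)
  mu <- colMeans(tab$afd, na.rm = TRUE)
  expect_equal(st$afd, sweep(tab$afd, 2, mu, "/"))
  # constant pair becomes all ones
  tab$afd[, 1] <- 0.42
  expect_true(all(standardize_pairs(tab)$afd[, 1] == 1))
  # zero-mean pair is a config error
  tab$afd[, 2] <- 0
  expect_error(standardize_pairs(tab), "non-zero")
})

test_that("core-region chaining respects the 50 kb independence rule", {
  mk_scan <- function(pos, vals, chrom = "chr1") {
    s <- data.frame(chrom = chrom, pos = pos, mean_afd = vals,
                    n_pairs = 20L, stringsAsFactors = FALSE)
    class(s) <- c("category_scan", "data.frame"); s
  }
  two <- detect_core_snps(mk_scan(c(100, 50101), c(0.8, 0.9)), 0.70)
  expect_equal(nrow(two), 2L)                      # 50,001 apart
  one <- detect_core_snps(mk_scan(c(100, 50099), c(0.8, 0.9)), 0.70)
  expect_equal(nrow(one), 1L)                      # 49,999 apart
  expect_equal(one$core_pos, 50099)                # maximal AFD is the core
  single <- detect_core_snps(mk_scan(1000, 0.9), 0.70)
  expect_equal(single$core_pos, 1000)
  expect_equal(single$n_snps, 1L)
  none <- detect_core_snps(mk_scan(1000, 0.5), 0.70)
  expect_equal(nrow(none), 0L)
  # ties resolved to the smallest position
  tie <- detect_core_snps(mk_scan(c(100, 200), c(0.9, 0.9)), 0.70)
  expect_equal(tie$core_pos, 100)
})

test_that("core regions equal a brute-force union-find on random scans", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 80
    pos <- sort(sample.int(4e5, n))
    s <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    pos = pos, mean_afd = runif(n), n_pairs = 20L,
                    stringsAsFactors = FALSE)
    s <- s[order(s$chrom, s$pos), ]
    class(s) <- c("category_scan", "data.frame")
    got <- detect_core_snps(s, threshold = 0.6, max_gap = 30000)
    # oracle: union-find over passing SNPs
    pass <- s[!is.na(s$mean_afd) & s$mean_afd > 0.6, ]
    if (!nrow(pass)) { expect_equal(nrow(got), 0L); next }
    parent <- seq_len(nrow(pass))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(pass))) for (j in seq_len(nrow(pass))) {
      if (i < j && pass$chrom[i] == pass$chrom[j] &&
          abs(pass$pos[i] - pass$pos[j]) < 30000) {
        parent[find(j)] <- find(i)
      }
    }
    comp <- vapply(seq_len(nrow(pass)), find, 0L)
    want <- lapply(split(seq_len(nrow(pass)), comp), function(ix) {
      g <- pass[ix, ]
      core <- g[which(g$mean_afd == max(g$mean_afd)), , drop = FALSE]
      core <- core[which.min(core$pos), ]
      data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
                 core_pos = core$pos, core_afd = core$mean_afd)
    })
    want <- do.call(rbind, want)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(got$core_pos, want$core_pos)
    expect_setequal(got$start, want$start)
    expect_setequal(got$end, want$end)
  }
})

test_that("empirical quantile thresholding flags the expected tail", {
  set.seed(18)
  s <- data.frame(chrom = "c1", pos = seq(1, by = 1e6, length.out = 20000),
                  mean_afd = runif(20000), n_pairs = 20L,
                  stringsAsFactors = FALSE)
  class(s) <- c("category_scan", "data.frame")
  got <- detect_core_snps(s, quantile = 0.9995, max_gap = 1000)
  # SNPs spaced 1 Mb apart: every passing SNP is its own region
  expect_equal(nrow(got), sum(s$mean_afd >
                                quantile(s$mean_afd, 0.9995, type = 7)))
  expect_equal(nrow(got) / 20000, 0.0005, tolerance = 0.5)
})

test_that("fst behaves at fixation and agrees with a textbook formula", {
  expect_equal(fst(0.3, 0.3, 100, 100), 0)
  expect_gt(fst(1, 0, 1e6, 1e6), 0.999)
  expect_equal(fst(0, 0, 50, 50), 0)  # monomorphic pair convention
  set.seed(19)
  p1 <- runif(200); p2 <- runif(200)
  d1 <- sample(50:200, 200, TRUE); d2 <- sample(50:200, 200, TRUE)
  got <- fst(p1, p2, d1, d2)
  # independently coded Hudson estimator with sample-size correction
  want <- vapply(seq_len(200), function(i) {
    num <- (p1[i] - p2[i])^2 -
      p1[i] * (1 - p1[i]) / (d1[i] - 1) - p2[i] * (1 - p2[i]) / (d2[i] - 1)
    den <- p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
    if (den == 0) 0 else min(1, max(0, num / den))
  }, 0)
  expect_equal(got, want)
})
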