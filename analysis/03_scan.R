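#!/usr/bin/env Rscript

# Stage 3: integrated AFD divergence scan and core-SNP detection.
#
# Restricts to SNPs with pooled freshwater MAF above 0.2, computes AFD for
# all 45 freshwater population pairs (50x per-pool floor), integrates the
# pairwise values within the B-A, B-B and A-A comparison categories
# (>= 18 / 8 / 8 contributing pairs), and chains SNPs with integrated
# B-A AFD above 0.70 into independent core regions (50 kb rule).

library(afdscan)

pops <- read_population_config("results/populations_analysis.yaml")
lay <- read_genome_layout("results/layout.tsv")
m <- read_snp_matrix("results/matrix_ascertained.tsv", "tsv", pops, lay)
fresh <- m$populations$name[m$populations$habitat != "marine"]

m_scan <- filter_maf(m, scope = fresh, min_maf = 0.2)
tab <- pairwise_scan(m_scan, min_depth_per_pop = 50)
scan_ba <- integrate_category(tab, "BA")
scan_bb <- integrate_category(tab, "BB")
scan_aa <- integrate_category(tab, "AA")

out <- data.frame(scan_ba[, c("chrom", "pos")],
                  mean_afd_ba = scan_ba$mean_afd, n_pairs_ba = scan_ba$n_pairs,
                  mean_afd_bb = scan_bb$mean_afd, mean_afd_aa = scan_aa$mean_afd)
write.table(out, "results/category_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

regions <- detect_core_snps(scan_ba, threshold = 0.70, max_gap = 50000)
write.table(regions, "results/core_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_regions_bed(regions, "results/core_regions.bed")

ok <- !is.na(scan_ba$mean_afd)
cat(sprintf(paste0(
  "Scanned %d SNPs with MAF > 0.2 (%d informative in B-A).\n",
  "Genome-wide B-A AFD: median %.3f, 99.95th percentile %.3f.\n",
  "Detected %d independent core regions at AFD > 0.70 ",
  "(top core AFD %.3f).\n"),
  n_snps(m_scan), sum(ok), median(scan_ba$mean_afd[ok]),
  quantile(scan_ba$mean_afd[ok], 0.9995),
  nrow(regions), if (nrow(regions)) max(regions$core_afd) else NA))
cat(sprintf("Within-habitat differentiation at core SNPs stays low: "))
core_idx <- match(paste(regions$chrom, regions$core_pos),
                  paste(scan_ba$chrom, scan_ba$pos))
cat(sprintf("median B-B %.3f, A-A %.3f (vs B-A %.3f).\n",
            median(scan_bb$mean_afd[core_idx], na.rm = TRUE),
            median(scan_aa$mean_afd[core_idx], na.rm = TRUE),
            median(scan_ba$mean_afd[core_idx], na.rm = TRUE)))
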