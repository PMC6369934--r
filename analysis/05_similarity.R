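#!/usr/bin/env Rscript

# Stage 5: genetic similarity among populations.
#
# Two analyses: (i) putatively neutral structure from loner SNPs in the
# chromosome peripheries (40x per-pool floor, low differentiation in both
# the B-A and marine-freshwater scans) — synthetic diploid IUPAC
# genotypes exported as FASTA, plus an NJ tree; (ii) habitat structure at
# the core SNPs versus matched random controls — binary similarity
# matrices, NJ trees and one-dimensional NMDS, expecting {basic, marine}
# to cluster apart from {acidic} at core SNPs only.

library(afdscan)

seed <- 1
pops <- read_population_config("results/populations_analysis.yaml")
lay <- read_genome_layout("results/layout.tsv")
m <- read_snp_matrix("results/matrix_ascertained.tsv", "tsv", pops, lay)
regions <- read.table("results/core_regions.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
ctrl <- read.table("results/polarized_controls.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
subs <- setdiff(habitat_pops(m, "marine"), "MAR")
keep <- setdiff(m$populations$name, subs)   # analyse lakes + combined MAR

# (i) neutral phylogeny input
tab_mf <- mf_scan(m, marine = "MAR", min_depth_per_pop = 50)
scan_mf <- integrate_category(tab_mf, "MF", 8L)
tab_ba <- pairwise_scan(m, min_depth_per_pop = 50)
scan_ba <- integrate_category(tab_ba, "BA", 18L)
m_phylo <- select_phylogeny_snps(m, scan_ba, scan_mf, min_pool_cov = 40,
                                 max_afd = 0.5, tip_window = 5e6)
n_use <- min(n_snps(m_phylo), 2000)   # plenty for a stable NJ topology
m_use <- subset_snps(m_phylo, seq_len(n_use))
geno <- synthesize_genotypes(m_use, n_individuals = 2, seed = seed)
write_genotypes_fasta(geno, "results/neutral_genotypes.fasta")
d_neu <- binary_similarity(m_use, seed = seed)
d_neu <- d_neu[keep, keep]
writeLines(tree_newick(nj_tree(d_neu)), "results/nj_neutral.nwk")

# (ii) core vs control structure
core <- data.frame(chrom = regions$chrom, pos = regions$core_pos)
d_core <- binary_similarity(m, core, seed = seed)[keep, keep]
d_ctrl <- binary_similarity(m, ctrl[, c("chrom", "pos")],
                            seed = seed)[keep, keep]
writeLines(tree_newick(nj_tree(d_core)), "results/nj_core.nwk")
writeLines(tree_newick(nj_tree(d_ctrl)), "results/nj_control.nwk")
ord_core <- ordinate(d_core, n_dims = 1, seed = seed)
ord_ctrl <- ordinate(d_ctrl, n_dims = 1, seed = seed)
coords <- data.frame(population = keep,
                     axis1_core = ord_core$points[, 1],
                     axis1_control = ord_ctrl$points[, 1])
write.table(coords, "results/nmds_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

acid <- habitat_pops(m, "acidic")
basmar <- c(habitat_pops(m, "basic"), "MAR")
sep <- function(v) max(v[acid]) < min(v[basmar]) || min(v[acid]) > max(v[basmar])
cat(sprintf(paste0(
  "Neutral set: %d phylogeny SNPs (%d used); FASTA and NJ tree written.\n",
  "Core-SNP NMDS (stress %.3f): acidic cluster separated = %s\n",
  "Control-SNP NMDS (stress %.3f): acidic cluster separated = %s\n"),
  n_snps(m_phylo), n_use,
  ord_core$stress, sep(ord_core$points[, 1]),
  ord_ctrl$stress, sep(ord_ctrl$points[, 1])))
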