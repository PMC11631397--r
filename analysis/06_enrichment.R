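#!/usr/bin/env Rscript
# Stage 6: Monte-Carlo enrichment of genes and aneuploidies.
#
# Rains the observed number of disruptive mutations onto the coding genome
# (probability proportional to coding length) to get per-gene empirical
# P-values, runs the analogous chromosome-permutation null on the stage-5
# karyotype calls, and tests co-occurrence of the two most frequent
# aneuploidies. Iteration counts are 1e5 here (the method default is 1e6)
# to keep the driver fast; empirical P floors scale accordingly.

suppressPackageStartupMessages(library(mutscreen))
seed <- as.integer(Sys.getenv("MUTSCREEN_SEED", "1"))
n_it <- 1e5

tally_tab <- read.delim("results/gene_tally.tsv", stringsAsFactors = FALSE)
tally <- structure(list(observed = setNames(tally_tab$observed, tally_tab$gene),
                        n_mut = sum(tally_tab$observed),
                        gene_lengths = setNames(tally_tab$length, tally_tab$gene),
                        per_strain = numeric()), class = "mutation_tally")
genes <- simulate_gene_null(tally, n_iterations = n_it,
                            seed = derive_seed(seed, 6L))
write.table(genes, "results/gene_enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
sig <- genes[genes$significant, ]
cat(sprintf("gene null (%g iterations): %d significant gene(s) after Bonferroni\n",
            n_it, nrow(sig)))
print(sig[, c("gene", "observed", "expected", "empirical_p", "bonferroni_p")],
      row.names = FALSE)

kary <- read.delim("results/karyotypes.tsv", stringsAsFactors = FALSE)
per_strain <- tapply(kary$cn_min1 > 1, kary$strain, sum)
aneuploid <- per_strain[per_strain > 0]
chroms <- unique(kary$chromosome)
obs <- vapply(chroms, function(cn)
  sum(kary$cn_min1[kary$chromosome == cn] > 1), numeric(1))
an <- simulate_aneuploidy_null(as.integer(aneuploid), obs,
                               n_chromosomes = length(chroms),
                               n_iterations = n_it,
                               seed = derive_seed(seed, 7L))
an$chromosome <- chroms
write.table(an, "results/aneuploidy_enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
top <- an[order(an$empirical_p), ][1:3, ]
cat(sprintf("aneuploidy null over %d aneuploid strain(s):\n", length(aneuploid)))
print(top[, c("chromosome", "observed", "expected", "empirical_p",
              "bonferroni_p", "significant")], row.names = FALSE)

ord <- order(obs, decreasing = TRUE)
ci <- ord[1]; cj <- ord[2]
if (obs[cj] > 0) {
  both <- sum(tapply(kary$cn_min1 > 1 &
                       kary$chromosome %in% chroms[c(ci, cj)],
                     kary$strain, sum) == 2)
  co <- cooccurrence_p(obs[ci], obs[cj], length(per_strain), both,
                       n_iterations = n_it, seed = derive_seed(seed, 8L))
  cat(sprintf("co-occurrence of %s and %s: observed %d strains, empirical P %s%.3g\n",
              chroms[ci], chroms[cj], both,
              if (co$p_is_bound) "< " else "", co$empirical_p))
} else {
  cat("only one chromosome shows aneuploidy; co-occurrence test skipped\n")
}
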