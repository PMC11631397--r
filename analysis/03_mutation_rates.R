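#!/usr/bin/env Rscript
# Stage 3: mutation rates, fold increase and screen saturation.
#
# Estimates phenotypic mutation rates (colonies / cells plated, Poisson SD)
# from the stage-1 plating counts, compares mutagenized vs mock pools with
# per-concentration chi-square tests (Bonferroni corrected) and the paired
# t-test used for the canavanine control, converts the fold increase at the
# highest canavanine concentration into an induced per-bp rate, and derives
# mutations per genome plus the per-site saturation of the screen.

suppressPackageStartupMessages(library(mutscreen))
counts <- read.delim("results/simulated/plating_counts.tsv",
                     stringsAsFactors = FALSE)
dir.create("results", showWarnings = FALSE)

est <- cbind(counts, estimate_rate(counts$colonies, counts$cells_plated))
write.table(est, "results/rate_estimates.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

can_mut <- counts[counts$chemical == "canavanine" & counts$pool == "mutagenized", ]
can_mock <- counts[counts$chemical == "canavanine" & counts$pool == "mock", ]
tt <- compare_rates(can_mut, can_mock, method = "paired_t")
cat(sprintf("canavanine mutagenized vs mock, paired t-test: p = %.3g\n",
            tt$p_value))

cu_mut <- counts[counts$chemical == "copper" & counts$pool == "mutagenized", ]
cu_mock <- counts[counts$chemical == "copper" & counts$pool == "mock", ]
chi <- compare_rates(cu_mut, cu_mock)
write.table(chi, "results/rate_comparisons.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("copper mutagenized vs mock: %d/%d concentrations significant after Bonferroni\n",
            sum(chi$p_adjusted < 0.05), nrow(chi)))

# fold increase is taken at the highest canavanine concentration against
# the reference spontaneous phenotypic rate (1.52e-7 per cell), since the
# mock pool yields too few colonies for a stable denominator
base_phenotypic <- 1.52e-7
top <- max(can_mut$concentration)
fold <- (can_mut$colonies[can_mut$concentration == top] /
           can_mut$cells_plated[can_mut$concentration == top]) / base_phenotypic
per_bp <- induced_per_bp_rate(fold)
sat <- genome_saturation(per_bp, genome_length = 1.2e7,
                         cells_plated = sum(cu_mut$cells_plated))
cat(sprintf("fold increase at %g mg/L canavanine: %.1f\n", top, fold))
cat(sprintf("induced per-bp rate: %.3g; mutations per genome: %.2f\n",
            per_bp, sat$per_genome))
cat(sprintf("per-site screen saturation: %.2f mutants per genomic site\n",
            sat$per_site_saturation))
write.table(data.frame(fold_increase = fold, per_bp_rate = per_bp,
                       per_genome = sat$per_genome,
                       per_site_saturation = sat$per_site_saturation),
            "results/saturation.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
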