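#!/usr/bin/env Rscript
# Stage 2: dose-response phenotyping from the plate grids.
#
# Reads the stage-1 colony-size grids back from disk, normalizes each
# strain's stress series to its own no-stress colony, computes trapezoid
# AUC and delta-AUC against the ancestor replicates, flags physiological
# escapees (AUC <= ancestral mean + 3 SD), edge-normalizes the permissive
# grids by layer and reports pleiotropic costs, then summarizes effect
# sizes and the cost/effect-size relationship for retained mutants.

suppressPackageStartupMessages(library(mutscreen))
sim <- "results/simulated"
dir.create("results", showWarnings = FALSE)

layout <- read.delim(file.path(sim, "layout.tsv"), stringsAsFactors = FALSE)
conc <- as.numeric(readLines(file.path(sim, "concentrations.txt")))
stress <- lapply(sprintf("%.6g", conc), function(nm)
  read_plate_grid(file.path(sim, "plates", sprintf("copper_%s.tsv", nm)))$grid)
names(stress) <- sprintf("%.6g", conc)
perm_names <- c("MMD", "MMG", "CMD", "CMG", "YPD", "YPG")
permissive <- lapply(perm_names, function(nm)
  read_plate_grid(file.path(sim, "plates", sprintf("permissive_%s.tsv", nm)))$grid)
names(permissive) <- perm_names

plates <- list(stress = stress, permissive = permissive, layout = layout,
               concentrations = conc)
scores <- score_plates(plates, k = 3)

norm_perm <- lapply(permissive, normalize_edges)
occupied <- !is.na(layout$strain)
sizes <- lapply(norm_perm, function(g)
  setNames(g[cbind(layout$row, layout$col)][occupied], layout$strain[occupied]))
anc <- layout$strain[layout$role == "ancestor"]
costs <- cost_profile(sizes, lapply(sizes, function(v) v[anc]),
                      strains = layout$strain[occupied])
pheno <- merge(scores, costs, by = "strain", sort = FALSE)
write.table(pheno, "results/phenotypes.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

mut <- pheno[pheno$role == "mutant", ]
retained <- mut[!mut$escapee, ]
cat(sprintf("retention: %d of %d mutants (%.1f%%) are non-escapees\n",
            nrow(retained), nrow(mut),
            retention_percentage(nrow(retained), nrow(mut))))
cat(sprintf("retained effect sizes: median dAUC %.3f, max %.3f (assay ceiling %.1f)\n",
            median(retained$delta_auc), max(retained$delta_auc), max(conc)))

# truth check: planted vs estimated effect sizes
truth <- read.delim(file.path(sim, "plate_truth.tsv"), stringsAsFactors = FALSE)
m <- merge(retained, truth, by = "strain", suffixes = c("", ".truth"))
r <- correlate(m$delta_auc, m$true_delta_auc, "pearson")
cat(sprintf("planted vs estimated dAUC: Pearson r = %.3f\n", r$estimate))

# pleiotropic cost declines with effect size (planted slope 0.5)
cs <- correlate(retained$delta_auc, retained$mean_cost, "spearman")
cat(sprintf("cost vs effect size: Spearman rho = %.3f (p = %.2g)\n",
            cs$estimate, cs$p_value))
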