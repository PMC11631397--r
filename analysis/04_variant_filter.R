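#!/usr/bin/env Rscript
# Stage 4: six-rule site filtering and per-gene mutation tallies.
#
# Reads the stage-1 genotype VCF, applies the six site filters (per ancestor
# group), attributes retained sites to the derivative strains whose calls
# differ from their ancestor, and tallies disruptive (protein-altering)
# mutations per gene for the enrichment stage.

suppressPackageStartupMessages(library(mutscreen))
sim <- "results/simulated"
gm <- read_genotype_vcf(file.path(sim, "genotypes.vcf"))
ann <- read.delim(file.path(sim, "annotations.tsv"), stringsAsFactors = FALSE)
lens_tab <- read.delim(file.path(sim, "gene_lengths.tsv"),
                       stringsAsFactors = FALSE)
lens <- setNames(lens_tab$length, lens_tab$gene)

filt <- filter_sites(gm)
write.table(filt$removal_counts, "results/filter_removals.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("retained %d of %d sites (union over ancestor groups)\n",
            length(filt$retained_union), nrow(gm$sites)))
print(stats::aggregate(n ~ rule, filt$removal_counts, sum))

muts <- strain_mutations(gm, filt)
write.table(muts, "results/strain_mutations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("mean mutations per sequenced strain: %.2f\n",
            nrow(muts) / sum(!is.na(gm$ancestry))))

tally <- tally_disruptive(muts, ann, lens)
write.table(data.frame(gene = names(tally$observed),
                       observed = tally$observed,
                       length = tally$gene_lengths[names(tally$observed)]),
            "results/gene_tally.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("%d disruptive mutations across %d genes with >= 1 hit\n",
            tally$n_mut, sum(tally$observed > 0)))

# truth check: every planted causal site must survive the filters
truth <- read.delim(file.path(sim, "genotype_truth.tsv"),
                    stringsAsFactors = FALSE)
causal <- truth[truth$is_causal, ]
found <- paste(muts$strain, muts$chrom, muts$pos)
cat(sprintf("planted causal mutations recovered: %d/%d\n",
            sum(paste(causal$strain, causal$chrom, causal$pos) %in% found),
            nrow(causal)))
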