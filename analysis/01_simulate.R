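#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screen with planted truth.
#
# Emulates one ancestor group of the copper arm: 378 picked mutants + 6
# controls on a 384-format plate, 18 copper concentrations (0-0.8 mM), six
# permissive media, an exponential distribution of planted effect sizes,
# 24.4% physiological escapees and 10% lognormal measurement noise; 30
# sequenced strains (2 ancestors x 15 derivatives) with two planted causal
# genes, Poisson(5) passengers and mild genotyping artifacts; per-strain
# 1-kb coverage with planted chromosome VIII gains and one 9-copy focal CNV;
# Poisson plating counts for mutagenized and mock pools. Everything is
# written under results/simulated/ as plain-text standard formats so the
# later stages consume files, not R objects.

suppressPackageStartupMessages(library(mutscreen))
seed <- as.integer(Sys.getenv("MUTSCREEN_SEED", "1"))
out <- "results/simulated"
dir.create(file.path(out, "plates"), recursive = TRUE, showWarnings = FALSE)

scenario <- screen_scenario(seed = derive_seed(seed, 0L))
plates <- gen_plate_set(scenario)
for (nm in names(plates$stress))
  write_plate_grid(plates$stress[[nm]],
                   file.path(out, "plates", sprintf("copper_%s.tsv", nm)),
                   meta = list(condition = "copper", concentration_mM = nm))
for (nm in names(plates$permissive))
  write_plate_grid(plates$permissive[[nm]],
                   file.path(out, "plates", sprintf("permissive_%s.tsv", nm)),
                   meta = list(condition = nm))
write.table(plates$layout, file.path(out, "layout.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(plates$truth, file.path(out, "plate_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(sprintf("%.10g", plates$concentrations),
           file.path(out, "concentrations.txt"))

genome <- toy_genome_model(seed = derive_seed(seed, 1L))
causal <- genome$genes$name[c(1, 25)]
geno <- gen_genotype_data(genome, n_strains_per_ancestor = 15,
                          causal_genes = causal, background_mut_rate = 5,
                          artifact_rates = list(het = 0.05, missing = 0.01,
                                                multiallelic = 0.02),
                          seed = derive_seed(seed, 2L))
write_genotype_vcf(geno$genotypes, file.path(out, "genotypes.vcf"))
write.table(geno$annotations, file.path(out, "annotations.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(geno$truth, file.path(out, "genotype_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write_genome_files(genome, bed_path = file.path(out, "genes.bed"))
lens <- gene_lengths(genome)
write.table(data.frame(gene = names(lens), length = lens),
            file.path(out, "gene_lengths.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(chrom = genome$rdna$chrom, start = genome$rdna$start,
                       end = genome$rdna$end),
            file.path(out, "exclude.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

seq_strains <- names(geno$genotypes$ancestry)[!is.na(geno$genotypes$ancestry)]
set.seed(derive_seed(seed, 3L))
kary <- matrix(1L, length(seq_strains), 16,
               dimnames = list(seq_strains, NULL))
aneu <- sample(seq_strains, 9)              # 9 chr VIII gains (30% of strains)
kary[aneu, 8] <- 2L
kary[aneu[1], 3] <- 2L                      # one strain also gains chr III
cup_gene <- genome$genes[genome$genes$chrom == "chrVIII", ][2, ]
cnv <- list(chrom = "chrVIII", start = cup_gene$start, end = cup_gene$end,
            copies = 9, strains = seq_strains[1])
tracks <- gen_coverage(genome, kary, base_depth = 30, cnv = cnv,
                       seed = derive_seed(seed, 4L))
dir.create(file.path(out, "coverage"), showWarnings = FALSE)
for (s in names(tracks))
  write_coverage_bedgraph(tracks[[s]],
                          file.path(out, "coverage", paste0(s, ".bedgraph")))
write.table(data.frame(strain = rownames(kary), kary),
            file.path(out, "karyotype_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(as.data.frame(cnv), file.path(out, "cnv_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# plating counts: mock pool at the spontaneous canavanine-like frequency,
# mutagenized pool 88-fold higher, plus declining copper-resistance rates
rates <- rbind(
  data.frame(pool = "mutagenized", chemical = "canavanine",
             concentration = c(30, 45, 60), rate = 88 * 1.52e-7),
  data.frame(pool = "mock", chemical = "canavanine",
             concentration = c(30, 45, 60), rate = 1.52e-7),
  data.frame(pool = "mutagenized", chemical = "copper",
             concentration = c(0.1, 0.2, 0.4, 0.6),
             rate = c(1e-5, 3e-6, 8e-7, 2e-7)),
  data.frame(pool = "mock", chemical = "copper",
             concentration = c(0.1, 0.2, 0.4, 0.6),
             rate = c(1e-7, 3e-8, 1e-8, 2e-9)))
counts <- gen_plating_counts(rates, cells_plated = 1e7,
                             seed = derive_seed(seed, 5L))
write.table(counts, file.path(out, "plating_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("simulated: %d mutants on plates, %d sequenced strains, %d sites, %d platings\n",
            scenario$n_mutants, length(seq_strains),
            nrow(geno$genotypes$sites), nrow(counts)))
cat(sprintf("planted causal genes: %s; 9 chrVIII gains; focal CNV 9 copies in %s\n",
            paste(causal, collapse = ", "), cnv$strains))
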