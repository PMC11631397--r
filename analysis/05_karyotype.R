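#!/usr/bin/env Rscript
# Stage 5: karyotyping, diploidization and focal CNV estimation.
#
# Reads the stage-1 per-strain bedGraph coverage, calls whole-chromosome
# copy numbers from 1-kb window depth normalized to the least-covered
# chromosome (excluding the rDNA interval), screens for diploidization and
# partial-chromosome shifts, and estimates the copy number of the planted
# focal (CUP1-like) amplification.

suppressPackageStartupMessages(library(mutscreen))
sim <- "results/simulated"
excl <- read.delim(file.path(sim, "exclude.tsv"), stringsAsFactors = FALSE)
cnv <- read.delim(file.path(sim, "cnv_truth.tsv"), stringsAsFactors = FALSE)
files <- list.files(file.path(sim, "coverage"), full.names = TRUE)

calls <- list()
diploidized <- character()
for (f in files) {
  s <- sub("\\.bedgraph$", "", basename(f))
  tr <- read_coverage_bedgraph(f, excluded = excl)
  cc <- chromosome_copy_numbers(tr)
  cc$strain <- s
  calls[[s]] <- cc
  if (detect_diploidization(cc)) diploidized <- c(diploidized, s)
}
kary <- do.call(rbind, calls)
write.table(kary, "results/karyotypes.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

aneu <- kary[kary$cn_min1 > 1, ]
cat(sprintf("%d aneuploid strains; aneuploid chromosome calls:\n",
            length(unique(aneu$strain))))
print(table(aneu$chromosome))
cat(sprintf("diploidization flagged in %d strain(s)\n", length(diploidized)))

tr1 <- read_coverage_bedgraph(file.path(sim, "coverage",
                                        paste0(cnv$strains, ".bedgraph")),
                              excluded = excl)
lc <- locus_copy_number(tr1, cnv$chrom, cnv$start, cnv$end)
cat(sprintf("focal CNV in %s: %.2f copies (planted %d)\n",
            cnv$strains, lc$copy_number, cnv$copies))

# truth check against the planted karyotypes
truth <- read.delim(file.path(sim, "karyotype_truth.tsv"),
                    stringsAsFactors = FALSE)
kt <- as.matrix(truth[, -1])
acc <- mean(vapply(seq_len(nrow(truth)), function(i)
  mean(calls[[truth$strain[i]]]$cn_min1 == kt[i, ]), numeric(1)))
cat(sprintf("per-chromosome copy-number accuracy vs planted truth: %.1f%%\n",
            100 * acc))
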