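test_that("noise-free plates reproduce planted effect sizes exactly", {
  p <- gen_plate_set(noise_free_scenario(n = 30))
  scored <- score_plates(p)
  m <- merge(scored, p$truth, by = "strain", suffixes = c("", ".truth"))
  expect_equal(m$delta_auc, m$true_delta_auc, tolerance = 1e-8)
  # escapee_fraction = 0: every mutant retained
  expect_false(any(m$escapee[m$role == "mutant"]))
})

test_that("escapees phenocopy the ancestor dose curve", {
  sc <- screen_scenario(n_mutants = 12, escapee_fraction = 1, noise_cv = 0,
                        seed = 5)
  p <- gen_plate_set(sc)
  lay <- p$layout
  anc_pos <- which(lay$role == "ancestor")[1]
  mut_pos <- which(lay$role == "mutant")
  anc_curve <- vapply(p$stress, function(g) g[lay$row[anc_pos], lay$col[anc_pos]],
                      numeric(1))
  for (i in mut_pos[1:5]) {
    mut_curve <- vapply(p$stress, function(g) g[lay$row[i], lay$col[i]],
                        numeric(1))
    # same relative decline (edge bias cancels through the 0 mM plate)
    expect_equal(mut_curve / mut_curve[1], anc_curve / anc_curve[1],
                 tolerance = 1e-12)
  }
  expect_true(all(p$truth$escapee[p$truth$role == "mutant"]))
  expect_true(all(p$truth$true_delta_auc[p$truth$escapee] == 0))
})

test_that("edge bias multiplies layer means as configured", {
  nl <- mutscreen:::n_layers_of(16, 24)
  sc <- screen_scenario(n_mutants = 378, escapee_fraction = 0, noise_cv = 0,
                        effect_size = list(dist = "fixed", value = 0),
                        edge_bias = c(1.5, rep(1, nl - 1)), seed = 3)
  p <- gen_plate_set(sc)
  g <- p$stress[["0"]]
  lay <- mutscreen:::layer_matrix(16, 24)
  ratio <- mean(g[lay == 0], na.rm = TRUE) / mean(g[lay == nl - 1], na.rm = TRUE)
  expect_equal(ratio, 1.5, tolerance = 1e-9)
})

test_that("plate generation rejects an undersized layout", {
  expect_error(gen_plate_set(noise_free_scenario(n = 400), nrow = 16, ncol = 24),
               "too small")
})

test_that("plate generation is seed-deterministic", {
  sc <- screen_scenario(n_mutants = 20, seed = 42)
  p1 <- gen_plate_set(sc)
  p2 <- gen_plate_set(sc)
  expect_identical(p1, p2)
})

test_that("passenger mutation counts follow the stated Poisson rate", {
  g <- toy_genome_model(seed = 2)
  n <- 400
  gd <- gen_genotype_data(g, n_strains_per_ancestor = n / 2,
                          causal_genes = "GENE01_01",
                          background_mut_rate = 5, seed = 9)
  per_strain <- table(gd$truth$strain[!gd$truth$is_causal])
  counts <- as.numeric(per_strain)
  counts <- c(counts, rep(0, n - length(counts)))   # strains with 0 passengers
  se <- sqrt(5 / n)
  expect_lt(abs(mean(counts) - 5), 3 * se)
})

test_that("every strain carries a planted causal mutation that survives filtering", {
  g <- toy_genome_model(seed = 4)
  gd <- gen_genotype_data(g, 6, causal_genes = c("GENE02_02", "GENE09_05"),
                          background_mut_rate = 0, seed = 13)
  filt <- filter_sites(gd$genotypes)
  muts <- strain_mutations(gd$genotypes, filt)
  tr <- gd$truth[gd$truth$is_causal, ]
  expect_setequal(paste(muts$strain, muts$chrom, muts$pos),
                  paste(tr$strain, tr$chrom, tr$pos))
})

test_that("unknown causal gene names are rejected", {
  g <- toy_genome_model(seed = 1)
  expect_error(gen_genotype_data(g, 2, causal_genes = "NO_SUCH_GENE"),
               "unknown causal gene")
})

test_that("ancestral-het artifact sites are removed by the site filter", {
  g <- toy_genome_model(seed = 6)
  gd <- gen_genotype_data(g, 5, causal_genes = "GENE03_01",
                          background_mut_rate = 2,
                          artifact_rates = list(het = 0.3, missing = 0,
                                                multiallelic = 0),
                          seed = 21)
  gm <- gd$genotypes
  het_sites <- which(apply(gm$calls[, mutscreen:::ancestors_of(gm), drop = FALSE],
                           1, function(x) any(grepl("/", x))))
  expect_gt(length(het_sites), 0)
  filt <- filter_sites(gm)
  expect_length(intersect(het_sites, filt$retained_union), 0)
  # and they are attributed to rule 3
  r3 <- filt$removal_counts$n[filt$removal_counts$rule == "r3"]
  expect_gte(sum(r3), length(het_sites))
})

test_that("simulated coverage matches planted karyotypes and CNV", {
  g <- toy_genome_model(seed = 3)
  k <- matrix(1L, 2, 16, dimnames = list(c("s1", "s2"), NULL))
  k[2, 5] <- 2L
  tr <- gen_coverage(g, k, base_depth = 40, noise = "none", seed = 1)
  cc1 <- chromosome_copy_numbers(tr$s1)
  expect_true(all(cc1$mean_depth == 40))
  expect_true(all(cc1$cn_min1 == 1L))
  cc2 <- chromosome_copy_numbers(tr$s2)
  expect_equal(cc2$relative_depth[5], 2, tolerance = 1e-12)
  # focal CNV round-trip at 9 copies
  gene <- g$genes[g$genes$chrom == "chrII", ][1, ]
  tr2 <- gen_coverage(g, k[1, , drop = FALSE], base_depth = 40,
                      cnv = list(chrom = "chrII", start = gene$start,
                                 end = gene$end, copies = 9),
                      noise = "none", seed = 2)
  lc <- locus_copy_number(tr2$s1, "chrII", gene$start, gene$end)
  expect_equal(lc$copy_number, 9, tolerance = 0.05)
})

test_that("rDNA windows are depth-inflated but excluded from calls", {
  g <- toy_genome_model(seed = 3)
  tr <- gen_coverage(g, rep(1L, 16), base_depth = 30, noise = "none", seed = 1)[[1]]
  excl <- mutscreen:::window_excluded(tr)
  expect_gt(mean(tr$windows$depth[excl]), mean(tr$windows$depth[!excl]))
  cc <- chromosome_copy_numbers(tr)
  expect_true(all(cc$cn_min1 == 1L))
})

test_that("plating counts are Poisson with mean rate x cells", {
  rates <- data.frame(strain = "s", concentration = 0.1, rate = 1e-6)
  reps <- do.call(rbind, lapply(1:1000, function(i)
    gen_plating_counts(rates, cells_plated = 1e7, seed = i)))
  se <- sqrt(10 / 1000)
  expect_lt(abs(mean(reps$colonies) - 10), 3 * se)
  # zero rate gives zero counts, identical seed gives identical table
  z <- gen_plating_counts(data.frame(strain = "s", concentration = 0, rate = 0),
                          cells_plated = 1e7, seed = 1)
  expect_identical(z$colonies, 0L)
  expect_identical(gen_plating_counts(rates, 1e7, seed = 99),
                   gen_plating_counts(rates, 1e7, seed = 99))
})
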