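toy_matrix <- function(calls_by_site, gq = NULL, alt = NULL,
                       ancs = "A1", ders = c("D1", "D2", "D3")) {
  strains <- c(ancs, ders)
  calls <- do.call(rbind, calls_by_site)
  colnames(calls) <- strains
  n <- nrow(calls)
  if (is.null(gq)) gq <- matrix(99L, n, length(strains),
                                dimnames = list(NULL, strains))
  sites <- data.frame(chrom = "chrI", pos = seq_len(n) * 100,
                      ref = rep("A", n),
                      alt = alt %||% rep("T", n),
                      is_indel = FALSE, stringsAsFactors = FALSE)
  ancestry <- setNames(c(rep(NA_character_, length(ancs)),
                         rep(ancs[1], length(ders))), strains)
  genotype_matrix(sites, calls, gq, ancestry)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("each filter rule removes its hand-traced toy site", {
  gm <- toy_matrix(list(
    c("0", "1", "2", "0/1"),   # r1: 4 unique calls
    c("0", "0", "0", "."),     # r2: only one homozygous value
    c("0/1", "1", "0", "1"),   # r3: ancestor heterozygous
    c("1", "0", "0", "0"),     # r4: ancestor call shared by nobody
    c("0", "1", "0", "0")      # clean: retained
  ), alt = c("T,G", "T", "T", "T", "T"))
  res <- filter_sites(gm)
  expect_identical(res$retained$A1, 5L)
  counts <- setNames(res$removal_counts$n, res$removal_counts$rule)
  expect_equal(unname(counts[c("r1", "r2", "r3", "r4")]), rep(1, 4))
})

test_that("ancestor-het site is removed by rule 3 even when rules 1-2 pass", {
  gm <- toy_matrix(list(c("0/1", "1", "0", "1")))
  res <- filter_sites(gm)
  expect_length(res$retained$A1, 0)
  expect_equal(res$removal_counts$n[res$removal_counts$rule == "r3"], 1)
})

test_that("rule 5 is scoped to the offending ancestor group", {
  strains <- c("A1", "A2", "D1", "D2", "E1", "E2")
  calls <- matrix(c("0", "0", ".", ".", "1", "0"), 1,
                  dimnames = list(NULL, strains))
  gq <- matrix(99L, 1, 6, dimnames = list(NULL, strains))
  sites <- data.frame(chrom = "chrI", pos = 100, ref = "A", alt = "T",
                      is_indel = FALSE, stringsAsFactors = FALSE)
  ancestry <- setNames(c(NA, NA, "A1", "A1", "A2", "A2"), strains)
  gm <- genotype_matrix(sites, calls, gq, ancestry)
  res <- filter_sites(gm)
  expect_length(res$retained$A1, 0)        # 100% of A1 derivatives missing
  expect_identical(res$retained$A2, 1L)    # A2 group keeps the site
})

test_that("rule 6 drops multi-indel sites and low-GQ sites", {
  gm <- toy_matrix(list(
    c("0", "1", "2", "0"),     # two distinct indel alleles called
    c("0", "1", "0", "0"),     # SNP but one call has GQ 5
    c("0", "1", "0", "0")      # clean
  ), alt = c("AT,AGG", "T", "T"))
  gm$gq[2, "D1"] <- 5L
  res <- filter_sites(gm)
  expect_identical(res$retained$A1, 3L)
  counts <- setNames(res$removal_counts$n, res$removal_counts$rule)
  expect_equal(unname(counts["r6"]), 2)
})

test_that("removed plus retained equals total sites per ancestor group", {
  set.seed(91)
  for (i in 1:25) {
    gm <- random_toy_matrix()
    res <- filter_sites(gm)
    for (a in mutscreen:::ancestors_of(gm)) {
      n_removed <- sum(res$removal_counts$n[res$removal_counts$ancestor == a])
      expect_identical(n_removed + length(res$retained[[a]]), nrow(gm$sites))
    }
  }
})

test_that("ordered filtering retains the same sites as simultaneous predicates", {
  set.seed(17)
  for (i in 1:200) {
    gm <- random_toy_matrix()
    mine <- filter_sites(gm)
    oracle <- filter_sites_oracle(gm)
    for (a in names(oracle))
      expect_identical(mine$retained[[a]], oracle[[a]])
  }
})

test_that("mutation assignment attributes sites to differing derivatives", {
  gm <- toy_matrix(list(
    c("0", "1", "0", "1"),
    c("0", "0", "1", "0")
  ))
  res <- filter_sites(gm)
  muts <- strain_mutations(gm, res)
  expect_setequal(paste(muts$strain, muts$site),
                  c("D1 1", "D3 1", "D2 2"))
})

test_that("disruptive tallies count only protein-altering classes", {
  muts <- data.frame(strain = c("D1", "D2", "D3", "D4"),
                     chrom = "chrI", pos = c(100, 200, 300, 400),
                     stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chrI", pos = c(100, 200, 300, 400),
                    gene = c("X", "X", "X", "X"),
                    effect = c("nonsense", "nonsense", "nonsense", "synonymous"),
                    stringsAsFactors = FALSE)
  lens <- c(X = 1000, Y = 2000)
  tal <- tally_disruptive(muts, ann, lens)
  expect_equal(tal$observed, c(X = 3, Y = 0))
  expect_equal(tal$n_mut, 3)
  # empty mutation set: all-zero tally
  tal0 <- tally_disruptive(muts[0, ], ann, lens)
  expect_equal(tal0$observed, c(X = 0, Y = 0))
  expect_equal(tal0$n_mut, 0)
  # unannotated site: warned and counted as 'other'
  muts2 <- rbind(muts, data.frame(strain = "D5", chrom = "chrI", pos = 999))
  expect_warning(tal2 <- tally_disruptive(muts2, ann, lens), "lack annotation")
  expect_equal(tal2$n_mut, 3)
})

test_that("per-gene tallies recover the planted causal gene counts", {
  g <- toy_genome_model(seed = 12)
  gd <- gen_genotype_data(g, 5, causal_genes = "GENE07_04",
                          background_mut_rate = 0, seed = 3)
  res <- filter_sites(gd$genotypes)
  muts <- strain_mutations(gd$genotypes, res)
  tal <- tally_disruptive(muts, gd$annotations, gene_lengths(g))
  expect_equal(unname(tal$observed["GENE07_04"]), 10)  # 5 strains x 2 ancestors
})

test_that("SV filter keeps precise high-quality singletons and het duplications", {
  svs <- data.frame(
    type = c("deletion", "inversion", "duplication", "deletion", "deletion"),
    precise = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    quality = c(100, 100, 100, 100, 100))
  calls <- rbind(
    c("0", "1", "0"),     # precise hom-alt singleton deletion: kept
    c("0", "0/1", "0"),   # het singleton inversion: dropped
    c("0", "0/1", "0"),   # het singleton duplication: kept
    c("1", "1", "1"),     # shared by 3 strains: dropped
    c("0", "1", "0"))     # imprecise: dropped
  colnames(calls) <- c("s1", "s2", "s3")
  expect_identical(filter_svs(svs, calls), c(1L, 3L))
})
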