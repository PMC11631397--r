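flat_track <- function(depths_per_chrom, n_windows = 20, excluded = NULL) {
  chroms <- paste0("chr", as.character(as.roman(seq_along(depths_per_chrom))))
  win <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(chrom = chroms[i],
               start = (seq_len(n_windows) - 1) * 1000,
               end = seq_len(n_windows) * 1000,
               depth = depths_per_chrom[i], stringsAsFactors = FALSE)
  }))
  coverage_track(win, excluded = excluded)
}

test_that("copy numbers follow relative depth against the least-covered chromosome", {
  cc <- chromosome_copy_numbers(flat_track(rep(30, 16)))
  expect_true(all(cc$cn_min1 == 1L))
  expect_true(all(cc$cn_min2 == 2L))
  expect_false(any(cc$anomalous))

  depths <- rep(30, 16)
  depths[8] <- 60
  cc2 <- chromosome_copy_numbers(flat_track(depths))
  expect_identical(cc2$cn_min1[8], 2L)
  expect_true(all(cc2$cn_min1[-8] == 1L))
})

test_that("excluded rDNA windows do not distort the chromosome mean", {
  tr <- flat_track(rep(30, 16))
  rdna <- tr$windows$chrom == "chrXII" & tr$windows$start >= 5000 &
    tr$windows$end <= 10000
  tr$windows$depth[rdna] <- 300
  tr$excluded <- data.frame(chrom = "chrXII", start = 5000, end = 10000)
  cc <- chromosome_copy_numbers(tr)
  expect_identical(cc$cn_min1[cc$chromosome == "chrXII"], 1L)
  # without the exclusion the call would be wrong
  tr$excluded <- NULL
  cc2 <- chromosome_copy_numbers(tr)
  expect_gt(cc2$relative_depth[cc2$chromosome == "chrXII"], 1.35)
})

test_that("copy-number calls are invariant to depth rescaling", {
  depths <- c(30, 30, 60, 45, rep(30, 12))
  a <- chromosome_copy_numbers(flat_track(depths))
  b <- chromosome_copy_numbers(flat_track(depths * 7.3))
  expect_identical(a$cn_min1, b$cn_min1)
  expect_identical(a$cn_min2, b$cn_min2)
  expect_equal(a$relative_depth, b$relative_depth)
})

test_that("half-integer relative depths are flagged anomalous", {
  depths <- rep(30, 16)
  depths[4] <- 45   # 1.5x
  cc <- chromosome_copy_numbers(flat_track(depths))
  expect_true(cc$anomalous[4])
  expect_false(any(cc$anomalous[-4]))
})

test_that("diploidization is called when several chromosomes fit the doubled grid", {
  depths <- rep(30, 16)
  depths[c(3, 7, 11)] <- 45   # 1.5x under min=1 but integral under min=2
  tr <- flat_track(depths)
  expect_true(detect_diploidization(chromosome_copy_numbers(tr)))
  # a single clean 2x chromosome is ordinary aneuploidy, not diploidization
  depths2 <- rep(30, 16)
  depths2[5] <- 60
  expect_false(detect_diploidization(chromosome_copy_numbers(flat_track(depths2))))
  expect_false(detect_diploidization(chromosome_copy_numbers(flat_track(rep(30, 16)))))
})

test_that("planted karyotypes are recovered from noisy coverage", {
  genome <- toy_genome_model(n_genes_per_chrom = 4, chrom_length = 50000,
                             seed = 5)
  set.seed(55)
  n_rep <- 60
  correct <- 0L
  total <- 0L
  for (i in seq_len(n_rep)) {
    k <- rep(1L, 16)
    aneu <- sample(16, sample(0:3, 1))
    k[aneu] <- sample(2:4, length(aneu), replace = TRUE)
    tr <- gen_coverage(genome, k, base_depth = 30, seed = 1000 + i)[[1]]
    cc <- chromosome_copy_numbers(tr)
    correct <- correct + sum(cc$cn_min1 == k)
    total <- total + 16L
  }
  expect_gte(correct / total, 0.99)
})

test_that("focal locus copy number reads off the depth ratio", {
  tr <- flat_track(rep(30, 16))
  sel <- tr$windows$chrom == "chrVIII" & tr$windows$start >= 4000 &
    tr$windows$end <= 6000
  tr$windows$depth[sel] <- 270   # 9x the genome baseline
  lc <- locus_copy_number(tr, "chrVIII", 4000, 6000)
  expect_equal(lc$copy_number, 9)
  expect_equal(locus_copy_number(tr, "chrI", 0, 5000)$copy_number, 1)
  # stepwise profile exposes the CNV boundaries
  prof <- lc$profile
  expect_equal(sort(unique(prof$ratio)), c(1, 9))
  expect_error(locus_copy_number(flat_track(rep(0, 2)), "chrI", 0, 1000),
               "baseline")
})

test_that("partial-chromosome shifts are flagged for review", {
  tr <- flat_track(rep(30, 4), n_windows = 40)
  half <- tr$windows$chrom == "chrII" & tr$windows$start >= 20000
  tr$windows$depth[half] <- 60
  hits <- scan_partial_events(tr, fold = 1.5)
  expect_true("chrII" %in% hits$chrom)
  expect_equal(hits$fold[hits$chrom == "chrII"], 2, tolerance = 0.01)
  expect_equal(nrow(scan_partial_events(flat_track(rep(30, 4)))), 0)
})

test_that("inverted-repeat search finds a planted 10-bp pair and nothing else", {
  set.seed(12)
  left <- "ACGTTGCATG"
  bg <- paste(sample(c("A", "C"), 200, replace = TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 80), left, substr(bg, 81, 110), rc_chr(left),
              substr(bg, 111, 200))
  hits <- find_inverted_repeats(s, min_len = 10, max_spacer = 50)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$left_seq, left)
  expect_equal(hits$right_seq, rc_chr(left))
  expect_equal(hits$length, 10)
  expect_equal(hits$spacer, 30)
  # A/C-only background cannot host complementary matches
  expect_equal(nrow(find_inverted_repeats(bg, min_len = 5, max_spacer = 50)), 0)
})

test_that("inverted-repeat search agrees with the string-matching oracle", {
  set.seed(77)
  for (i in 1:4) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    mine <- find_inverted_repeats(s, min_len = 5, max_len = 20, max_spacer = 40)
    oracle <- brute_inverted_repeats(s, 5, 20, 40)
    expect_same_repeats(mine, oracle)
  }
})

test_that("palindromes are reported once and flagged", {
  pal <- "GGAATTCC"   # self reverse complement
  s <- paste0("AAAAAAAAAA", pal, "AAAAAAAAAA")
  hits <- find_inverted_repeats(s, min_len = 4, max_spacer = 10)
  pal_hits <- hits[hits$palindromic, ]
  expect_equal(nrow(pal_hits), 1)
  expect_equal(pal_hits$left_seq, "GGAA")
  expect_equal(pal_hits$right_seq, "TTCC")
  expect_equal(pal_hits$spacer, 0)
})

test_that("non-ACGT characters are skipped with a warning", {
  s <- paste0("ACGTTGCATGNNN", rc_chr("ACGTTGCATG"))
  expect_warning(hits <- find_inverted_repeats(s, min_len = 10, max_spacer = 10),
                 "non-ACGT")
  expect_equal(nrow(hits), 1)
})

test_that("invalid repeat-search windows are rejected", {
  expect_error(find_inverted_repeats("ACGTACGT", min_len = 3), "min_len")
  expect_error(find_inverted_repeats("ACGT", start = 0, end = 10, min_len = 4),
               "window")
})
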