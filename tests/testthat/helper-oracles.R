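# Independent oracles used by property-style tests. These deliberately use
# different algorithms (string matching, simultaneous predicates, exact
# closed forms) from the package implementations they check.

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# exhaustive inverted-repeat search: enumerate left arms, find right arms by
# exact string search of the reverse complement, keep non-extendable pairs
brute_inverted_repeats <- function(s, min_len, max_len, max_spacer) {
  n <- nchar(s)
  ok <- function(i, j, L) {
    if (i < 1 || L < 1 || j + L - 1 > n || j < i + L) return(FALSE)
    grepl("^[ACGT]+$", substr(s, i, i + L - 1)) &&
      substr(s, j, j + L - 1) == rc_chr(substr(s, i, i + L - 1))
  }
  hits <- list()
  for (L in min_len:min(max_len, floor(n / 2))) for (i in 1:(n - 2 * L + 1)) {
    pat <- rc_chr(substr(s, i, i + L - 1))
    if (grepl("[^ACGT]", pat)) next
    win_lo <- i + L
    win_hi <- min(n, i + L + max_spacer + L - 1)
    if (win_lo + L - 1 > win_hi) next
    m <- gregexpr(pat, substr(s, win_lo, win_hi), fixed = TRUE)[[1]]
    for (off in m[m > 0]) {
      j <- win_lo + off - 1
      if (j - (i + L) > max_spacer) next
      if (ok(i - 1, j, L + 1) || ok(i, j - 1, L + 1)) next
      hits[[length(hits) + 1]] <- data.frame(
        left_start = i - 1, left_end = i + L - 1,
        right_start = j - 1, right_end = j + L - 1,
        length = L, spacer = j - (i + L))
    }
  }
  if (!length(hits))
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      length = integer(), spacer = integer()))
  h <- unique(do.call(rbind, hits))
  h <- h[order(h$left_start, h$length), ]
  rownames(h) <- NULL
  h
}

expect_same_repeats <- function(mine, oracle) {
  cols <- c("left_start", "left_end", "right_start", "right_end",
            "length", "spacer")
  a <- as.data.frame(mine[cols])
  rownames(a) <- NULL
  expect_equal(a, oracle[cols], ignore_attr = TRUE)
}

# simultaneous-predicate implementation of the six site filters (the spec of
# each rule written directly, no ordering, no shared helpers)
filter_sites_oracle <- function(gm, max_missing_frac = 0.1, min_gq = 10) {
  calls <- gm$calls
  ancs <- names(gm$ancestry)[is.na(gm$ancestry)]
  miss <- function(x) x %in% c(".", "./.")
  het <- function(x) grepl("/", x, fixed = TRUE) & !miss(x)
  retained <- list()
  for (a in ancs) {
    derivs <- names(gm$ancestry)[!is.na(gm$ancestry) & gm$ancestry == a]
    keep <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      cc <- calls[i, ]
      p1 <- length(unique(cc[!miss(cc)])) < 4
      hom <- cc[!miss(cc) & !het(cc)]
      p2 <- length(unique(hom)) >= 2
      p3 <- !any(het(cc[ancs]))
      p4 <- all(vapply(ancs, function(an) {
        ac <- cc[an]
        if (miss(ac)) return(TRUE)
        oth <- cc[setdiff(names(cc), an)]
        oth <- oth[!miss(oth)]
        length(oth) == 0 || ac %in% oth
      }, logical(1)))
      p5 <- if (length(derivs) == 0) TRUE else
        mean(miss(cc[derivs])) <= max_missing_frac
      alleles <- strsplit(gm$sites$alt[i], ",")[[1]]
      codes <- setdiff(unique(unlist(strsplit(cc[!miss(cc)], "/"))), "0")
      called_alts <- alleles[as.integer(codes)]
      n_indel <- sum(nchar(called_alts) != nchar(gm$sites$ref[i]))
      gq_ok <- if (all(miss(cc))) TRUE else min(gm$gq[i, !miss(cc)]) >= min_gq
      p6 <- n_indel <= 1 && gq_ok
      keep[i] <- p1 && p2 && p3 && p4 && p5 && p6
    }
    retained[[a]] <- which(keep)
  }
  retained
}

# random toy genotype matrices for exhaustive filter property tests
random_toy_matrix <- function() {
  n_sites <- sample(2:10, 1)
  n_anc <- sample(1:2, 1)
  n_der <- sample(2:5, 1)
  ancs <- paste0("A", seq_len(n_anc))
  ders <- paste0("D", seq_len(n_der))
  strains <- c(ancs, ders)
  calls <- matrix(sample(c("0", "1", "2", "0/1", "."), n_sites * length(strains),
                         replace = TRUE,
                         prob = c(0.45, 0.25, 0.08, 0.12, 0.10)),
                  n_sites, length(strains), dimnames = list(NULL, strains))
  gq <- matrix(sample(c(99L, 50L, 5L), n_sites * length(strains),
                      replace = TRUE, prob = c(0.8, 0.15, 0.05)),
               n_sites, length(strains), dimnames = list(NULL, strains))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(seq_len(n_sites), function(i) {
    a1 <- if (stats::runif(1) < 0.3) paste0(ref[i], "T") else
      sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    a2 <- if (stats::runif(1) < 0.3) paste0(ref[i], "AA") else
      sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    paste(a1, a2, sep = ",")
  }, character(1))
  sites <- data.frame(chrom = "chrI", pos = sort(sample(1e5, n_sites)),
                      ref = ref, alt = alt,
                      is_indel = grepl("^..", alt),
                      stringsAsFactors = FALSE)
  ancestry <- stats::setNames(
    c(rep(NA_character_, n_anc), sample(ancs, n_der, replace = TRUE)),
    strains)
  genotype_matrix(sites, calls, gq, ancestry)
}

# small noise-free scenario used by several round-trip tests
noise_free_scenario <- function(n = 24, escapee_fraction = 0, seed = 101,
                                ...) {
  screen_scenario(n_mutants = n, escapee_fraction = escapee_fraction,
                  noise_cv = 0, seed = seed, ...)
}
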