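#' Find short inverted repeat pairs in a sequence window
#'
#' Searches a nucleotide sequence for pairs of substrings (left, right) where
#' the right substring is the reverse complement of the left — the signature
#' flanking structure of origin-dependent inverted-repeat amplification
#' (ODIRA) CNVs. Reported pairs are maximal: they cannot be extended inward
#' or outward while keeping complementarity and non-overlapping arms. Arms
#' that abut (spacer 0) form a palindrome and are reported once, flagged.
#'
#' The scan works along anti-diagonals of the implicit self-comparison
#' matrix: positions a and b with a + b constant pair up, a run of
#' complementary pairs along one anti-diagonal is one repeat pair, and the
#' run is truncated at the diagonal's midpoint so arms never overlap.
#' Non-ACGT characters never match and are skipped with a warning.
#'
#' @param sequence a single nucleotide string (or `genome_model` sequence
#'   element).
#' @param start,end optional 0-based half-open window (default: whole
#'   sequence).
#' @param min_len minimum arm length in bp (default 10, must be >= 4).
#' @param max_len maximum arm length to report (default Inf).
#' @param max_spacer maximum separation between arms in bp (default 100).
#' @return data.frame: left_start, left_end, right_start, right_end (0-based
#'   half-open, window coordinates offset to the full sequence), length,
#'   spacer, palindromic, left_seq, right_seq; sorted by position then
#'   length.
#' @export
find_inverted_repeats <- function(sequence, start = 0,
                                  end = nchar(sequence), min_len = 10,
                                  max_len = Inf, max_spacer = 100) {
  stop_if_not(min_len >= 4, "min_len must be >= 4")
  stop_if_not(start >= 0 && end <= nchar(sequence) && end > start,
              "window out of sequence bounds")
  s <- substr(sequence, start + 1, end)
  n <- nchar(s)
  code <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(code))
    warning(sprintf("%d non-ACGT position(s) skipped", sum(is.na(code))))
  comp_ok <- function(a, b) {
    # a, b are 0-based positions; complementary iff codes sum to 5 (A+T, C+G)
    ca <- code[a + 1]; cb <- code[b + 1]
    !is.na(ca) & !is.na(cb) & (ca + cb == 5L)
  }
  hits <- list()
  for (cc in seq(2 * min_len - 1, 2 * n - 2)) {
    a_min <- max(0, cc - n + 1)
    a_mid <- (cc - 1) %/% 2
    if (a_mid < a_min) next
    a <- a_min:a_mid
    m <- comp_ok(a, cc - a)
    r <- rle(m)
    pos_end <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= 1)) {
      lo <- a[pos_end[k] - r$lengths[k] + 1]
      hi <- a[pos_end[k]]
      # truncation at the midpoint makes the run end at a_mid at most;
      # the run is outward-maximal unless it starts at a_min by clipping
      len <- hi - lo + 1
      spacer <- cc - 2 * hi - 1
      if (len < min_len || len > max_len || spacer > max_spacer) next
      hits[[length(hits) + 1]] <- data.frame(
        left_start = lo + start, left_end = hi + 1 + start,
        right_start = cc - hi + start, right_end = cc - lo + 1 + start,
        length = len, spacer = spacer, palindromic = spacer == 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      length = integer(), spacer = integer(),
                      palindromic = logical(), left_seq = character(),
                      right_seq = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$left_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out$left_seq <- substring(sequence, out$left_start + 1, out$left_end)
  out$right_seq <- substring(sequence, out$right_start + 1, out$right_end)
  out
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over Biostrings for character input.
#'
#' @param x nucleotide string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
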