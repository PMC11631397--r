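#' Call whole-chromosome copy numbers from windowed depth
#'
#' Mean depth per chromosome is computed over non-excluded windows
#' (disregarding, e.g., the rDNA cluster), normalized to the least-covered
#' chromosome, and rounded to the nearest integer (ties away from zero)
#' under the assumption that the least-covered chromosome is present in a
#' single copy. A second estimate assumes the least-covered chromosome is
#' present in two copies (diploid baseline). Relative depths whose distance
#' from the nearest integer exceeds 0.35 (e.g. values in 1.35-1.65) are
#' flagged anomalous rather than forced to an integer.
#'
#' @param track a [coverage_track()].
#' @return data.frame of class `karyotype_call`: chromosome, mean_depth,
#'   relative_depth, cn_min1, cn_min2, anomalous.
#' @export
chromosome_copy_numbers <- function(track) {
  stop_if_not(inherits(track, "coverage_track"), "track must be a coverage_track")
  w <- track$windows
  excl <- window_excluded(track)
  chroms <- unique(w$chrom)
  mean_depth <- vapply(chroms, function(cn) {
    keep <- w$chrom == cn & !excl
    if (!any(keep))
      stop(sprintf("chromosome %s has no non-excluded windows: cannot call", cn),
           call. = FALSE)
    mean(w$depth[keep])
  }, numeric(1))
  rel <- mean_depth / min(mean_depth)
  cn1 <- pmax(1L, as.integer(round_half_away(rel)))
  cn2 <- pmax(1L, as.integer(round_half_away(2 * rel)))
  out <- data.frame(chromosome = chroms, mean_depth = unname(mean_depth),
                    relative_depth = unname(rel),
                    cn_min1 = cn1, cn_min2 = cn2,
                    anomalous = abs(rel - round_half_away(rel)) > 0.35,
                    stringsAsFactors = FALSE)
  class(out) <- c("karyotype_call", "data.frame")
  out
}

#' Detect whole-genome diploidization from a karyotype call
#'
#' A haploid line that diploidized shows several chromosomes at half-integer
#' relative depth under the haploid (min = 1) baseline but at integers under
#' the diploid (min = 2) baseline. A strain is called diploidized when more
#' than one chromosome fits the min = 2 integer grid strictly better (its
#' absolute deviation from the nearest integer is smaller after doubling).
#'
#' @param call a `karyotype_call` from [chromosome_copy_numbers()].
#' @return TRUE if the coverage pattern supports diploidization.
#' @export
detect_diploidization <- function(call) {
  rel <- call$relative_depth
  dev1 <- abs(rel - round_half_away(rel))
  dev2 <- abs(2 * rel - round_half_away(2 * rel))
  sum(dev2 < dev1) > 1
}

#' Focal-locus copy number from coverage
#'
#' Mean depth of the windows overlapping a region divided by a baseline
#' (default: the genome-wide median of non-excluded window depths, robust to
#' the focal CNV itself). A per-window ratio profile is attached so stepwise
#' CNV boundaries are visible.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end region of interest (0-based half-open).
#' @param baseline optional baseline depth; default genome-wide median.
#' @return list(copy_number, baseline, profile) where `profile` is a
#'   data.frame of per-window depth ratios across the region's chromosome.
#' @export
locus_copy_number <- function(track, chrom, start, end, baseline = NULL) {
  w <- track$windows
  excl <- window_excluded(track)
  if (is.null(baseline)) baseline <- stats::median(w$depth[!excl])
  if (!is.finite(baseline) || baseline == 0)
    stop("baseline depth is zero or undefined", call. = FALSE)
  hit <- w$chrom == chrom & w$start < end & w$end > start
  stop_if_not(any(hit), "region overlaps no coverage windows")
  on_chrom <- w[w$chrom == chrom, ]
  list(copy_number = mean(w$depth[hit]) / baseline,
       baseline = baseline,
       profile = data.frame(start = on_chrom$start, end = on_chrom$end,
                            ratio = on_chrom$depth / baseline))
}

#' Scan a chromosome for partial-chromosome copy-number shifts
#'
#' Flags candidate partial gains/losses for manual review: slides a
#' boundary along each chromosome and reports boundaries where the mean
#' depth on one side differs from the other by at least `fold` (each side
#' at least `min_windows` windows). Best (most extreme) boundary per
#' chromosome is reported.
#'
#' @param track a [coverage_track()].
#' @param fold fold-change threshold (default 1.5).
#' @param min_windows minimum windows per side (default 5).
#' @return data.frame: chrom, boundary (bp), left_mean, right_mean, fold.
#' @export
scan_partial_events <- function(track, fold = 1.5, min_windows = 5) {
  w <- track$windows
  excl <- window_excluded(track)
  out <- list()
  for (cn in unique(w$chrom)) {
    d <- w$depth[w$chrom == cn & !excl]
    st <- w$start[w$chrom == cn & !excl]
    n <- length(d)
    if (n < 2 * min_windows) next
    cums <- cumsum(d)
    i <- min_windows:(n - min_windows)
    left <- cums[i] / i
    right <- (cums[n] - cums[i]) / (n - i)
    f <- pmax(left, right) / pmin(left, right)
    best <- which.max(f)
    if (f[best] >= fold)
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, boundary = st[i[best] + 1], left_mean = left[best],
        right_mean = right[best], fold = f[best], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), boundary = numeric(),
                      left_mean = numeric(), right_mean = numeric(),
                      fold = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
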