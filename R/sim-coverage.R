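#' Construct a coverage track
#'
#' Per-chromosome ordered depth windows (default 1 kb) with optional excluded
#' intervals (e.g. the rDNA cluster, whose repeat-driven depth would distort
#' the chromosome mean).
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `depth`.
#' @param excluded optional data.frame `chrom`, `start`, `end` of intervals
#'   to ignore during karyotyping.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(windows, excluded = NULL) {
  stop_if_not(is.data.frame(windows) &&
                all(c("chrom", "start", "end", "depth") %in% names(windows)),
              "windows must have columns chrom, start, end, depth")
  stop_if_not(all(windows$depth >= 0), "depths must be non-negative")
  stop_if_not(all(windows$end > windows$start), "windows must be non-empty")
  for (cn in unique(windows$chrom)) {
    w <- windows[windows$chrom == cn, ]
    stop_if_not(all(diff(w$start) > 0) && all(w$start[-1] >= w$end[-nrow(w)]),
                sprintf("windows on %s must be sorted and non-overlapping", cn))
  }
  structure(list(windows = windows, excluded = excluded),
            class = "coverage_track")
}

window_excluded <- function(track) {
  w <- track$windows
  out <- rep(FALSE, nrow(w))
  ex <- track$excluded
  if (is.null(ex) || nrow(ex) == 0) return(out)
  for (i in seq_len(nrow(ex))) {
    out <- out | (w$chrom == ex$chrom[i] & w$start < ex$end[i] & w$end > ex$start[i])
  }
  out
}

#' Simulate per-window sequencing depth for a set of strains
#'
#' Expected depth of each 1-kb window is `base_depth` times the chromosome's
#' copy number; a focal CNV region is further scaled by its copy number; the
#' genome's rDNA interval (if any) gets arbitrarily inflated depth to
#' exercise the exclusion logic. The final partial window of a chromosome is
#' kept if at least 500 bp. Count noise is Poisson by default (short-read
#' depth behaves near-Poisson at these scales), negative binomial optionally.
#'
#' @param genome a `genome_model` (16 chromosomes expected for karyotypes).
#' @param karyotypes integer matrix, strains x chromosomes (copy numbers,
#'   >= 1), with strain rownames; a plain vector is taken as one strain.
#' @param base_depth expected reads per 1-kb window per chromosome copy.
#' @param cnv optional list(chrom, start, end, copies) focal CNV applied to
#'   every strain whose rowname appears in `cnv$strains` (default: first
#'   strain).
#' @param noise `"poisson"`, `"none"`, or `list(model = "nbinom", size = k)`.
#' @param window_size window width in bp (default 1000).
#' @param seed integer seed.
#' @return named list of [coverage_track()] objects, one per strain.
#' @export
gen_coverage <- function(genome, karyotypes, base_depth = 30, cnv = NULL,
                         noise = "poisson", window_size = 1000, seed = 1L) {
  stop_if_not(inherits(genome, "genome_model"), "genome must be a genome_model")
  if (is.vector(karyotypes))
    karyotypes <- matrix(karyotypes, nrow = 1,
                         dimnames = list("strain1", NULL))
  stop_if_not(ncol(karyotypes) == nrow(genome$chromosomes),
              "karyotype length must match chromosome count")
  stop_if_not(all(karyotypes >= 1), "karyotype entries must be >= 1")
  if (is.null(rownames(karyotypes)))
    rownames(karyotypes) <- sprintf("strain%d", seq_len(nrow(karyotypes)))
  set.seed(seed)

  chroms <- genome$chromosomes
  win <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    keep <- (ends - starts) >= min(500, window_size)
    data.frame(chrom = chroms$name[i], start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  }))
  chrom_idx <- match(win$chrom, chroms$name)

  excluded <- NULL
  rdna_mask <- rep(FALSE, nrow(win))
  if (!is.null(genome$rdna)) {
    excluded <- data.frame(chrom = genome$rdna$chrom, start = genome$rdna$start,
                           end = genome$rdna$end, stringsAsFactors = FALSE)
    rdna_mask <- win$chrom == genome$rdna$chrom &
      win$start < genome$rdna$end & win$end > genome$rdna$start
  }

  cnv_strains <- if (!is.null(cnv)) cnv$strains %||% rownames(karyotypes)[1]
  draw <- function(mu) {
    if (identical(noise, "none")) return(mu)
    if (identical(noise, "poisson")) return(stats::rpois(length(mu), mu))
    if (is.list(noise) && identical(noise$model, "nbinom"))
      return(stats::rnbinom(length(mu), size = noise$size, mu = mu))
    stop("unknown noise model", call. = FALSE)
  }

  out <- lapply(rownames(karyotypes), function(s) {
    mu <- base_depth * karyotypes[s, chrom_idx]
    if (!is.null(cnv) && s %in% cnv_strains) {
      in_cnv <- win$chrom == cnv$chrom & win$start < cnv$end & win$end > cnv$start
      mu[in_cnv] <- mu[in_cnv] * cnv$copies
    }
    mu[rdna_mask] <- mu[rdna_mask] * 10   # repeat-collapsed depth inflation
    w <- win
    w$depth <- draw(mu)
    coverage_track(w, excluded = excluded)
  })
  names(out) <- rownames(karyotypes)
  out
}

#' Simulate Poisson plating colony counts
#'
#' Colonies recovered when plating `cells_plated` cells of a pool whose true
#' resistant-mutant frequency is `rate`: counts are Poisson with mean
#' `rate * cells_plated`.
#'
#' @param rates data.frame with columns `strain`, `concentration`, `rate`
#'   (mutant frequency in \[0, 1\]) and optionally `pool`.
#' @param cells_plated cells per plating (scalar or per-row vector).
#' @param seed integer seed.
#' @return the input with columns `cells_plated` and `colonies` appended.
#' @export
gen_plating_counts <- function(rates, cells_plated, seed = 1L) {
  stop_if_not(all(rates$rate >= 0 & rates$rate <= 1), "rates must be in [0, 1]")
  stop_if_not(all(cells_plated > 0), "cells_plated must be > 0")
  set.seed(seed)
  out <- rates
  out$cells_plated <- rep_len(cells_plated, nrow(rates))
  out$colonies <- stats::rpois(nrow(out), out$rate * out$cells_plated)
  out
}
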