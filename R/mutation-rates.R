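#' Phenotypic mutation rate from a plating count
#'
#' Rate = colonies recovered / cells plated, with a Poisson standard
#' deviation `sqrt(colonies) / cells_plated` for the colony count.
#'
#' @param colonies non-negative integer colony count(s).
#' @param cells_plated cells plated (> 0), recycled.
#' @return data.frame with columns `rate`, `sd`.
#' @export
estimate_rate <- function(colonies, cells_plated) {
  stop_if_not(all(colonies >= 0), "colonies must be non-negative")
  stop_if_not(all(cells_plated > 0), "cells_plated must be positive")
  data.frame(rate = colonies / cells_plated,
             sd = sqrt(colonies) / cells_plated)
}

# 2x2 chi-square on (colonies, cells - colonies), closed form, optional Yates
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(e == 0)) stop("expected cell count of zero: test undefined", call. = FALSE)
  o <- matrix(c(a, c, b, d), 2)
  adj <- if (yates) pmin(abs(o - e), 0.5) else 0
  stat <- sum((abs(o - e) - adj)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare phenotypic mutation rates between two groups
#'
#' Pairwise 2x2 chi-square tests on (colonies, cells - colonies) at each
#' plating concentration (optionally pooled across concentrations), with
#' Bonferroni correction over the number of tests. A paired t-test across
#' concentrations (rates paired by concentration) is also available, as used
#' for the canavanine control.
#'
#' @param counts_a,counts_b data.frames with columns `concentration`,
#'   `colonies`, `cells_plated` (one row per concentration).
#' @param per_concentration test each concentration separately (TRUE) or
#'   pool all counts into a single 2x2 test (FALSE).
#' @param method `"chisq"` or `"paired_t"`.
#' @param yates apply the continuity correction (default FALSE).
#' @param bonferroni_m number of tests for correction (default: number of
#'   comparisons performed).
#' @return data.frame: concentration, statistic, p_value, p_adjusted.
#' @export
compare_rates <- function(counts_a, counts_b, per_concentration = TRUE,
                          method = c("chisq", "paired_t"), yates = FALSE,
                          bonferroni_m = NULL) {
  method <- match.arg(method)
  if (method == "paired_t") {
    m <- merge(counts_a, counts_b, by = "concentration")
    stop_if_not(nrow(m) >= 2, "paired t-test needs >= 2 matched concentrations")
    ra <- m$colonies.x / m$cells_plated.x
    rb <- m$colonies.y / m$cells_plated.y
    tt <- stats::t.test(ra, rb, paired = TRUE)
    return(data.frame(concentration = NA, statistic = unname(tt$statistic),
                      p_value = tt$p.value, p_adjusted = tt$p.value))
  }
  if (!per_concentration) {
    a <- sum(counts_a$colonies); ca <- sum(counts_a$cells_plated)
    b <- sum(counts_b$colonies); cb <- sum(counts_b$cells_plated)
    r <- chisq_2x2(a, ca - a, b, cb - b, yates = yates)
    return(data.frame(concentration = NA, statistic = r$statistic,
                      p_value = r$p_value, p_adjusted = min(1, r$p_value *
                                                              (bonferroni_m %||% 1))))
  }
  m <- merge(counts_a, counts_b, by = "concentration")
  stop_if_not(nrow(m) > 0, "no matched concentrations")
  res <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    r <- chisq_2x2(m$colonies.x[i], m$cells_plated.x[i] - m$colonies.x[i],
                   m$colonies.y[i], m$cells_plated.y[i] - m$colonies.y[i],
                   yates = yates)
    data.frame(concentration = m$concentration[i], statistic = r$statistic,
               p_value = r$p_value)
  }))
  mtests <- bonferroni_m %||% nrow(res)
  res$p_adjusted <- pmin(1, res$p_value * mtests)
  res
}

#' Induced per-base-pair mutation rate from a phenotypic fold increase
#'
#' Scales the spontaneous per-bp rate (6.44e-10 per bp per division, from
#' the canavanine fluctuation literature) by the observed fold increase in
#' phenotypic mutation rate after mutagenesis. An 88-fold increase yields
#' 5.66e-8 mutations per bp.
#'
#' @param fold_increase observed phenotypic rate fold increase (> 0).
#' @param base_per_bp spontaneous per-bp rate.
#' @return induced mutations per base pair.
#' @export
induced_per_bp_rate <- function(fold_increase, base_per_bp = 6.44e-10) {
  stop_if_not(all(fold_increase > 0), "fold_increase must be > 0")
  fold_increase * base_per_bp
}

#' Mutations per genome and per-site screen saturation
#'
#' `per_genome` is the induced per-bp rate times the genome length (0.68 for
#' 5.66e-8 x 1.2e7 bp); `per_site_saturation` is the per-bp rate times the
#' number of cells plated in the screen — the expected number of mutants in
#' the whole screen carrying a mutation at any given genomic site.
#'
#' @param per_bp_rate induced mutations per bp.
#' @param genome_length genome size in bp (default 1.2e7).
#' @param cells_plated total cells screened.
#' @return list(per_genome, per_site_saturation).
#' @export
genome_saturation <- function(per_bp_rate, genome_length = 1.2e7,
                              cells_plated) {
  stop_if_not(all(per_bp_rate >= 0), "per_bp_rate must be >= 0")
  stop_if_not(genome_length > 0 && all(cells_plated > 0),
              "genome_length and cells_plated must be > 0")
  list(per_genome = per_bp_rate * genome_length,
       per_site_saturation = per_bp_rate * cells_plated)
}

#' Retention percentage after escapee exclusion
#'
#' Bookkeeping for the screen report: the percentage of picked isolates
#' retained as true (non-escapee) mutants, printed to one decimal place.
#' With the screen's retained counts (1,107 haploid + 309 diploid copper;
#' 31 + 7 sulfite) out of 1,872 picked per stressor this prints 75.6% and
#' 2.0%.
#'
#' @param n_retained retained isolate count(s); summed.
#' @param n_selected total isolates picked for phenotyping.
#' @return retention percentage rounded to one decimal place.
#' @export
retention_percentage <- function(n_retained, n_selected) {
  stop_if_not(n_selected > 0, "n_selected must be > 0")
  round(100 * sum(n_retained) / n_selected, 1)
}
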