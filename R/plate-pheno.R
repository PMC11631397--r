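#' Edge-distance layer of a plate position
#'
#' Colonies on dense agar arrays grow larger near the plate edge (more
#' nutrient access). For normalization, positions are grouped by the number
#' of positions separating them from the nearest edge: the "layer". A
#' 1536-format (32 x 48) plate has layers 0 through 15.
#'
#' @param row,col 1-based position indices (vectors recycle).
#' @param nrow,ncol plate dimensions.
#' @return integer layer(s), 0 for positions touching an edge.
#' @export
layer_index <- function(row, col, nrow = 32, ncol = 48) {
  stop_if_not(all(row >= 1 & row <= nrow & col >= 1 & col <= ncol),
              "position out of plate bounds")
  as.integer(pmin(row - 1L, col - 1L, nrow - row, ncol - col))
}

layer_matrix <- function(nrow, ncol) {
  outer(seq_len(nrow), seq_len(ncol), function(r, c) layer_index(r, c, nrow, ncol))
}

#' Remove plate edge effects by layer normalization
#'
#' Each colony size is divided by the mean of its layer and rescaled by the
#' plate grand mean, so per-layer means become equal while the grand mean is
#' preserved. Intended for permissive-condition (no-stress) growth data;
#' stress dose-response data are instead normalized per strain to that
#' strain's own no-stress colony, which cancels position effects.
#'
#' Idempotent to numerical tolerance: applying it twice equals applying it
#' once. A layer that is entirely missing is left unscaled with a warning.
#'
#' @param grid numeric matrix of colony sizes (NA = missing).
#' @return normalized matrix of the same shape.
#' @export
normalize_edges <- function(grid) {
  stop_if_not(is.matrix(grid) && is.numeric(grid), "grid must be a numeric matrix")
  lay <- layer_matrix(nrow(grid), ncol(grid))
  grand <- mean(grid, na.rm = TRUE)
  out <- grid
  for (l in sort(unique(as.vector(lay)))) {
    idx <- lay == l
    m <- mean(grid[idx], na.rm = TRUE)
    if (!is.finite(m)) {
      warning(sprintf("layer %d has no non-missing colonies; left unscaled", l))
      next
    }
    out[idx] <- grid[idx] / m * grand
  }
  out
}

#' Trapezoid-rule area under a dose-response curve
#'
#' Resistance metric: the area under relative colony size as a function of
#' stressor concentration (mM). With relative sizes capped at 1 and
#' concentrations spanning 0-0.8 mM, the maximum attainable AUC is 0.8.
#' Missing values are dropped and the trapezoid rule is applied over the
#' remaining grid.
#'
#' @param concentration ordered numeric vector of concentrations (mM),
#'   strictly increasing, starting at 0.
#' @param relative_size numeric vector of sizes relative to the no-stress
#'   condition (NA = missing).
#' @return AUC in mM x relative size.
#' @export
dose_auc <- function(concentration, relative_size) {
  stop_if_not(length(concentration) == length(relative_size),
              "concentration and relative_size lengths differ")
  keep <- !is.na(relative_size) & !is.na(concentration)
  x <- concentration[keep]
  y <- relative_size[keep]
  if (length(x) < 2) stop("need at least 2 non-missing points for AUC", call. = FALSE)
  stop_if_not(all(diff(x) > 0), "concentrations must be strictly increasing")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Classify a physiological escapee
#'
#' Isolates that formed a colony on stressor plates without a heritable
#' resistance mutation phenocopy the ancestor when re-phenotyped. A strain is
#' called an escapee when its AUC does not exceed the ancestral mean by more
#' than `k` sample standard deviations; the boundary value is classed escapee
#' (retention requires strictly exceeding the threshold).
#'
#' @param auc the strain's AUC (vectorized).
#' @param ancestor_aucs numeric vector (>= 2) of ancestor-replicate AUCs.
#' @param k threshold multiplier (default 3).
#' @return logical, TRUE = escapee.
#' @export
classify_escapee <- function(auc, ancestor_aucs, k = 3) {
  stop_if_not(length(ancestor_aucs) >= 2,
              "need >= 2 ancestor replicate AUCs to estimate the threshold")
  auc <= mean(ancestor_aucs) + k * stats::sd(ancestor_aucs)
}

#' Effect size relative to the ancestor
#'
#' @param mutant_auc the mutant's AUC (vectorized).
#' @param ancestor_aucs ancestor-replicate AUCs.
#' @return `mutant_auc - mean(ancestor_aucs)`.
#' @export
delta_auc <- function(mutant_auc, ancestor_aucs) {
  mutant_auc - mean(ancestor_aucs)
}

#' Pleiotropic-cost profile across permissive media
#'
#' Growth of each mutant relative to the ancestor in permissive (no-stress)
#' conditions, after edge normalization: 1 means a colony of the same size as
#' the ancestor's. Conditions where the ancestor mean is zero or missing are
#' dropped with a warning; the mean cost is taken over the remaining
#' conditions.
#'
#' @param mutant_sizes named list (one element per condition) of numeric
#'   vectors of per-strain normalized colony sizes.
#' @param ancestor_sizes named list (same conditions) of ancestor-replicate
#'   normalized sizes.
#' @param strains character vector of strain ids aligned with
#'   `mutant_sizes` entries.
#' @return data.frame: strain, one column per condition, `mean_cost`.
#' @export
cost_profile <- function(mutant_sizes, ancestor_sizes,
                         strains = names(mutant_sizes[[1]])) {
  conds <- names(mutant_sizes)
  stop_if_not(!is.null(conds) && setequal(conds, names(ancestor_sizes)),
              "mutant and ancestor condition sets must match")
  ratios <- lapply(conds, function(cn) {
    anc <- mean(ancestor_sizes[[cn]], na.rm = TRUE)
    if (!is.finite(anc) || anc == 0) {
      warning(sprintf("ancestor mean undefined in condition %s; dropped", cn))
      return(rep(NA_real_, length(mutant_sizes[[cn]])))
    }
    mutant_sizes[[cn]] / anc
  })
  names(ratios) <- conds
  out <- data.frame(strain = strains, stringsAsFactors = FALSE)
  for (cn in conds) out[[cn]] <- ratios[[cn]]
  out$mean_cost <- rowMeans(as.matrix(out[conds]), na.rm = TRUE)
  out
}

#' Rank-based two-group comparison (Kruskal-Wallis)
#'
#' @param values_a,values_b numeric vectors.
#' @param bonferroni_m optional number of comparisons; the p-value is
#'   multiplied by `m` and capped at 1.
#' @return list(statistic, p_value, p_adjusted).
#' @export
compare_groups <- function(values_a, values_b, bonferroni_m = NULL) {
  stop_if_not(length(values_a) >= 1 && length(values_b) >= 1,
              "both groups must be non-empty")
  x <- c(values_a, values_b)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  if (length(unique(x)) == 1) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  res$p_adjusted <- if (is.null(bonferroni_m)) res$p_value else
    min(1, res$p_value * bonferroni_m)
  res
}

#' Correlation with significance test
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (product-moment) or `"spearman"` (rank).
#' @return list(estimate, p_value).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stop_if_not(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Score a synthetic plate set: AUC, delta-AUC, escapee calls
#'
#' Full phenotyping pass over the stress grids of a plate set: each strain's
#' colony sizes are normalized to its own no-stress (0 mM) colony, the
#' trapezoid AUC is computed over the concentration series, the ancestor
#' replicates define the escapee threshold (mean + k sd), and delta-AUC is
#' reported relative to the ancestral mean. Escapees are flagged and must be
#' excluded from downstream effect-size and cost comparisons.
#'
#' @param plates a plate set from [gen_plate_set()] (or the same structure
#'   read back from disk).
#' @param k escapee threshold multiplier.
#' @param max_missing_frac strains missing more than this fraction of
#'   concentrations are dropped (default 0.5).
#' @return data.frame: strain, role, auc, delta_auc, escapee.
#' @export
score_plates <- function(plates, k = 3, max_missing_frac = 0.5) {
  layout <- plates$layout
  conc <- plates$concentrations
  grids <- plates$stress
  stop_if_not(length(grids) == length(conc), "one stress grid per concentration")
  sizes <- vapply(grids, function(g) g[cbind(layout$row, layout$col)],
                  numeric(nrow(layout)))   # strains x concentrations
  rel <- sizes / sizes[, which(conc == 0)[1]]
  occupied <- !is.na(layout$strain)
  res <- data.frame(strain = layout$strain[occupied],
                    role = layout$role[occupied],
                    stringsAsFactors = FALSE)
  rel <- rel[occupied, , drop = FALSE]
  frac_missing <- rowMeans(is.na(rel))
  res$auc <- NA_real_
  ok <- frac_missing <= max_missing_frac
  res$auc[ok] <- apply(rel[ok, , drop = FALSE], 1, function(y) dose_auc(conc, y))
  anc <- res$auc[res$role == "ancestor" & !is.na(res$auc)]
  res$delta_auc <- delta_auc(res$auc, anc)
  res$escapee <- ifelse(res$role == "mutant" & !is.na(res$auc),
                        classify_escapee(res$auc, anc, k = k), NA)
  res
}
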