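# Dose-response model for synthetic mutants.
#
# Relative colony size follows a logistic decline in concentration,
# normalized so that the no-stress value is exactly 1:
#   rel(c) = s(c) / s(0),  s(c) = 1 / (1 + exp((c - m) / w))
# The inflection m controls resistance; w (shared shape width) is fixed at
# cmax/16. Planted dAUC values are converted to an inflection by root-finding
# so that the trapezoid AUC on the assay grid equals ancestor AUC + dAUC
# exactly (to root tolerance), which makes noise-free truth recovery exact.

logistic_rel_size <- function(conc, m, w) {
  s <- function(c) 1 / (1 + exp((c - m) / w))
  s(conc) / s(0)
}

solve_inflection <- function(target_auc, conc, w) {
  cmax <- max(conc)
  f <- function(m) dose_auc(conc, logistic_rel_size(conc, m, w)) - target_auc
  stats::uniroot(f, lower = -5 * cmax - 5 * w, upper = 5 * cmax + 5 * w,
                 tol = 1e-12)$root
}

n_layers_of <- function(nrow, ncol) min(ceiling(nrow / 2), ceiling(ncol / 2))

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Generate a synthetic plate set with planted truth
#'
#' Emulates one ancestor group of the arrayed phenotyping assay: mutants and
#' controls are placed on a plate, replica-plated (in silico) across every
#' stressor concentration and six permissive media, and imaged as colony
#' sizes (pixel counts). Each mutant's expected relative size declines with
#' concentration according to its planted dAUC; escapees phenocopy the
#' ancestor's decline; per-layer edge bias multiplies raw sizes; measurement
#' noise is multiplicative lognormal. Controls are 2 ancestor replicates, 2
#' highly resistant reference strains, and 2 mock-mutagenesis isolates
#' (which behave like the ancestor).
#'
#' @param scenario a [screen_scenario()].
#' @param nrow,ncol plate dimensions (default 384 format, 16 x 24).
#' @param base_size expected no-stress colony size in pixels.
#' @return list with elements `stress` (named list of size grids, one per
#'   concentration), `permissive` (named list of 6 condition grids),
#'   `layout` (data.frame row, col, strain, role), `concentrations`, and
#'   `truth` (data.frame strain, role, true_delta_auc, escapee,
#'   true_relative_growth).
#' @export
gen_plate_set <- function(scenario, nrow = 16, ncol = 24, base_size = 400) {
  stop_if_not(inherits(scenario, "screen_scenario"), "scenario must be a screen_scenario")
  n_controls <- 6L
  n <- scenario$n_mutants
  if (n + n_controls > nrow * ncol)
    stop(sprintf("layout %dx%d too small for %d mutants + %d controls",
                 nrow, ncol, n, n_controls), call. = FALSE)
  set.seed(scenario$seed)
  conc <- scenario$concentrations
  cmax <- max(conc)
  w <- cmax / 16

  # ancestor curve and its AUC on the assay grid
  m0 <- cmax / 10
  auc0 <- dose_auc(conc, logistic_rel_size(conc, m0, w))
  ceiling_d <- 0.98 * (cmax - auc0)

  # planted truth
  esc <- stats::runif(n) < scenario$escapee_fraction
  d <- switch(scenario$effect_size$dist,
              exponential = stats::rexp(n, rate = 1 / scenario$effect_size$mean),
              fixed = rep(scenario$effect_size$value, n))
  d <- pmin(d, ceiling_d)   # assay ceiling: effects beyond it are censored
  d[esc] <- 0
  growth <- pmax(0.1, 1 - scenario$cost_slope * d)

  strains <- sprintf("mut%04d", seq_len(n))
  roles <- c(rep("mutant", n), rep("ancestor", 2), rep("reference", 2), rep("mock", 2))
  ids <- c(strains, paste0("anc", 1:2), paste0("ref", 1:2), paste0("mock", 1:2))
  truth <- data.frame(strain = ids, role = roles,
                      true_delta_auc = c(d, rep(0, 2), rep(0.9 * ceiling_d, 2), rep(0, 2)),
                      escapee = c(esc, rep(FALSE, 6)),
                      true_relative_growth = c(growth, rep(1, 6)),
                      stringsAsFactors = FALSE)

  # inflection per strain (escapees/ancestors/mocks share the ancestor curve)
  uniq_d <- unique(truth$true_delta_auc)
  m_for <- stats::setNames(vapply(uniq_d, function(dd) {
    if (dd == 0) m0 else solve_inflection(auc0 + dd, conc, w)
  }, numeric(1)), format(uniq_d, digits = 17))
  truth$inflection <- m_for[format(truth$true_delta_auc, digits = 17)]

  # random arrangement of strains on the plate
  pos <- sample(nrow * ncol, length(ids))
  layout <- data.frame(row = ((pos - 1) %% nrow) + 1L,
                       col = ((pos - 1) %/% nrow) + 1L,
                       strain = ids, role = roles, stringsAsFactors = FALSE)

  nl <- n_layers_of(nrow, ncol)
  bias_by_layer <- rep_len(scenario$edge_bias, nl)
  lay <- layer_matrix(nrow, ncol)
  bias_grid <- matrix(bias_by_layer[lay + 1L], nrow, ncol)

  place <- function(values) {
    g <- matrix(NA_real_, nrow, ncol)
    g[cbind(layout$row, layout$col)] <- values
    g
  }
  noise <- function() {
    g <- matrix(NA_real_, nrow, ncol)
    g[cbind(layout$row, layout$col)] <- lognormal_noise(length(ids), scenario$noise_cv)
    g
  }

  stress <- lapply(conc, function(cc) {
    rel <- logistic_rel_size(cc, truth$inflection, w)
    place(base_size * rel) * bias_grid * noise()
  })
  names(stress) <- sprintf("%.6g", conc)

  permissive_media <- c("MMD", "MMG", "CMD", "CMG", "YPD", "YPG")
  permissive <- lapply(permissive_media, function(cond) {
    place(base_size * truth$true_relative_growth) * bias_grid * noise()
  })
  names(permissive) <- permissive_media

  truth$inflection <- NULL
  list(stress = stress, permissive = permissive, layout = layout,
       concentrations = conc, truth = truth)
}
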