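#' Define a synthetic screen scenario
#'
#' The stated world for the plate simulator: how many mutants are arrayed,
#' which stressor concentrations are assayed, how planted effect sizes are
#' distributed, what fraction of picked isolates are physiological escapees,
#' how strong the plate edge bias is, and how noisy the colony-size
#' measurement is.
#'
#' Defaults mirror the copper arm of the screen: 378 mutants per ancestral
#' strain arrayed with 6 controls on a 384-format plate, 18 concentrations
#' spanning 0-0.8 mM, an exponential distribution of planted beneficial
#' effects (theory expects the beneficial tail to be exponential), an escapee
#' fraction of 0.244 (the screen retained 75.6% of copper isolates), flat
#' edge bias, and 10% lognormal measurement CV.
#'
#' @param n_mutants mutants per ancestor group.
#' @param concentrations strictly increasing vector of stressor
#'   concentrations (mM) including 0.
#' @param effect_size list(dist, ...): `list(dist = "exponential",
#'   mean = 0.1)` or `list(dist = "fixed", value = x)`; dAUC scale.
#' @param escapee_fraction fraction of "mutants" that are escapees in [0, 1].
#' @param edge_bias per-layer multiplicative size factors (> 0); recycled or
#'   truncated to the number of layers of the layout at generation time.
#' @param noise_cv lognormal measurement coefficient of variation (>= 0).
#' @param cost_slope planted pleiotropic cost per unit dAUC: true relative
#'   growth in permissive media is `1 - cost_slope * dAUC` (floored at 0.1).
#' @param seed integer seed.
#' @return an object of class `screen_scenario`.
#' @export
screen_scenario <- function(n_mutants = 378,
                            concentrations = seq(0, 0.8, length.out = 18),
                            effect_size = list(dist = "exponential", mean = 0.1),
                            escapee_fraction = 0.244,
                            edge_bias = 1,
                            noise_cv = 0.1,
                            cost_slope = 0.5,
                            seed = 1L) {
  stop_if_not(length(concentrations) >= 2 && all(diff(concentrations) > 0) &&
                concentrations[1] == 0 && all(concentrations >= 0),
              "concentrations must be strictly increasing and start at 0")
  stop_if_not(escapee_fraction >= 0 && escapee_fraction <= 1,
              "escapee_fraction must be in [0, 1]")
  stop_if_not(all(edge_bias > 0), "edge bias factors must be > 0")
  stop_if_not(noise_cv >= 0, "noise_cv must be non-negative")
  stop_if_not(effect_size$dist %in% c("exponential", "fixed"),
              "effect_size$dist must be 'exponential' or 'fixed'")
  structure(list(n_mutants = n_mutants, concentrations = concentrations,
                 effect_size = effect_size,
                 escapee_fraction = escapee_fraction,
                 edge_bias = edge_bias, noise_cv = noise_cv,
                 cost_slope = cost_slope, seed = as.integer(seed)),
            class = "screen_scenario")
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat(sprintf(paste0("screen_scenario: %d mutants, %d concentrations ",
                     "(0-%g mM), escapee fraction %.3f, noise CV %.2f\n"),
              x$n_mutants, length(x$concentrations),
              max(x$concentrations), x$escapee_fraction, x$noise_cv))
  invisible(x)
}
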