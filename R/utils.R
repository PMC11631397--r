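#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Derive a reproducible child seed from a base seed
#'
#' All stochastic stages take an explicit integer seed. When one run needs
#' several independent streams (e.g. plates, then genotypes, then coverage),
#' child seeds are derived deterministically from the base seed so that a
#' single `--seed` reproduces the whole run. Values stay below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param offset non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * (offset + 1)) %% 2147483647)
}

# nearest integer, ties away from zero (round() ties-to-even is not wanted
# for copy-number calls: 1.5x must become 2, 2.5x must become 3)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
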