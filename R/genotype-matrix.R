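#' Construct a multi-strain genotype matrix
#'
#' Sites-by-strains call table for haploid ancestor/derivative strain sets.
#' Calls use VCF-style genotype codes: `"0"` hom-ref, `"1"`, `"2"`, ...
#' hom-alt (allele index), `"0/1"` heterozygous (an artifact by definition in
#' haploids), `"."` missing.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated alternates), `is_indel`.
#' @param calls character matrix, sites x strains, with strain column names.
#' @param gq integer matrix of genotype qualities, same shape as `calls`.
#' @param ancestry named character vector mapping every derivative strain to
#'   its ancestor strain (which must itself be a column); ancestors map to
#'   `NA`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, gq, ancestry) {
  stop_if_not(is.data.frame(sites) &&
                all(c("chrom", "pos", "ref", "alt", "is_indel") %in% names(sites)),
              "sites must have columns chrom, pos, ref, alt, is_indel")
  stop_if_not(is.matrix(calls) && nrow(calls) == nrow(sites),
              "calls must be a sites x strains matrix")
  stop_if_not(identical(dim(gq), dim(calls)), "gq must match calls in shape")
  strains <- colnames(calls)
  stop_if_not(!is.null(strains) && !anyDuplicated(strains),
              "calls must have unique strain column names")
  stop_if_not(all(names(ancestry) %in% strains),
              "ancestry names must be strains in the matrix")
  derivs <- names(ancestry)[!is.na(ancestry)]
  stop_if_not(all(ancestry[derivs] %in% strains),
              "every derivative must map to an ancestor present in the matrix")
  stop_if_not(setequal(names(ancestry), strains),
              "ancestry must cover every strain (ancestors map to NA)")
  structure(list(sites = sites, calls = calls, gq = gq, ancestry = ancestry),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d strains (%d ancestors)\n",
              nrow(x$sites), ncol(x$calls), sum(is.na(x$ancestry))))
  invisible(x)
}

ancestors_of <- function(gm) names(gm$ancestry)[is.na(gm$ancestry)]

derivatives_of <- function(gm, ancestor) {
  names(gm$ancestry)[!is.na(gm$ancestry) & gm$ancestry == ancestor]
}

is_het_call <- function(call) grepl("/", call, fixed = TRUE) &
  !call %in% c(".", "./.")
is_missing_call <- function(call) call %in% c(".", "./.")
is_hom_call <- function(call) !is_het_call(call) & !is_missing_call(call)
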