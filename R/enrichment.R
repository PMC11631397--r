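empirical_p <- function(exceed_count, n_iterations) {
  # zero-exceedance convention: never report 0; flag "< 1/n" downstream
  ifelse(exceed_count == 0, 1 / (n_iterations + 1),
         exceed_count / n_iterations)
}

#' Monte-Carlo null for gene-level mutation enrichment
#'
#' The "rain-down" null: each iteration places the observed total number of
#' disruptive mutations onto the coding sequences of the genome, each
#' mutation landing in a gene with probability proportional to its coding
#' length (mutations placed independently, so two can hit the same site).
#' The empirical P-value of a gene is the fraction of iterations with at
#' least as many simulated hits as observed; Bonferroni correction
#' multiplies by the number of genes tested (capped at 1). When no iteration
#' reaches the observed count, P is reported as `1/(n_iterations + 1)` and
#' flagged as a bound.
#'
#' @param tally a `mutation_tally` from [tally_disruptive()], or a list with
#'   `observed` (named counts), `n_mut`, `gene_lengths`.
#' @param n_iterations Monte-Carlo iterations (default 1e6).
#' @param seed integer seed.
#' @param bonferroni_m tests for correction (default: number of genes).
#' @param chunk_size iterations per multinomial block (memory control).
#' @return data.frame of class `enrichment_result`: gene, length, observed,
#'   expected, empirical_p, p_is_bound, bonferroni_p, significant; the
#'   iteration count and seed are attached as attributes.
#' @export
simulate_gene_null <- function(tally, n_iterations = 1e6, seed = 1L,
                               bonferroni_m = NULL, chunk_size = 20000L) {
  stop_if_not(n_iterations >= 1, "n_iterations must be >= 1")
  stop_if_not(tally$n_mut > 0, "no observed mutations to rain down")
  lens <- tally$gene_lengths
  stop_if_not(length(lens) >= 1 && all(lens > 0), "need positive gene lengths")
  obs <- tally$observed[names(lens)]
  obs[is.na(obs)] <- 0
  set.seed(seed)
  prob <- lens / sum(lens)
  exceed <- numeric(length(lens))
  done <- 0
  while (done < n_iterations) {
    k <- min(chunk_size, n_iterations - done)
    hits <- stats::rmultinom(k, size = tally$n_mut, prob = prob)
    exceed <- exceed + rowSums(hits >= obs)
    done <- done + k
  }
  p <- empirical_p(exceed, n_iterations)
  m <- bonferroni_m %||% length(lens)
  out <- data.frame(gene = names(lens), length = unname(lens),
                    observed = unname(obs),
                    expected = unname(tally$n_mut * prob),
                    empirical_p = unname(p), p_is_bound = unname(exceed == 0),
                    bonferroni_p = unname(pmin(1, p * m)),
                    stringsAsFactors = FALSE)
  out$significant <- out$bonferroni_p < 0.05
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Monte-Carlo null for chromosome aneuploidy enrichment
#'
#' Input is the observed configuration: how many aneuploid strains there
#' were and how many aneuploid chromosomes each carried. Each iteration
#' re-assigns every strain's aneuploid chromosomes uniformly at random
#' (without replacement within a strain) over the karyotype, then counts
#' strains per chromosome. The empirical P-value for a chromosome is the
#' fraction of iterations where its simulated strain count is at least the
#' observed count. Chromosome sampling is uniform, not length-weighted;
#' `chrom_weights` enables a length-weighted sensitivity analysis.
#'
#' @param n_aneuploid_per_strain integer vector: aneuploid chromosome count
#'   for each aneuploid strain (each in 1..n_chromosomes).
#' @param observed named or plain vector of observed per-chromosome strain
#'   counts (length `n_chromosomes`).
#' @param n_chromosomes karyotype size (default 16).
#' @param n_iterations Monte-Carlo iterations (default 1e6).
#' @param seed integer seed.
#' @param bonferroni_m tests for correction (default `n_chromosomes`).
#' @param chrom_weights optional sampling weights per chromosome.
#' @return data.frame of class `enrichment_result` with one row per
#'   chromosome.
#' @export
simulate_aneuploidy_null <- function(n_aneuploid_per_strain, observed,
                                     n_chromosomes = 16, n_iterations = 1e6,
                                     seed = 1L, bonferroni_m = NULL,
                                     chrom_weights = NULL) {
  stop_if_not(n_iterations >= 1, "n_iterations must be >= 1")
  k <- as.integer(n_aneuploid_per_strain)
  stop_if_not(all(k >= 1 & k <= n_chromosomes),
              "each strain's aneuploid count must be in 1..n_chromosomes")
  stop_if_not(length(observed) == n_chromosomes,
              "observed must have one count per chromosome")
  set.seed(seed)
  exceed <- numeric(n_chromosomes)
  expected_hits <- numeric(n_chromosomes)
  for (it in seq_len(n_iterations)) {
    count <- integer(n_chromosomes)
    for (ks in k) {
      sel <- sample.int(n_chromosomes, ks, prob = chrom_weights)
      count[sel] <- count[sel] + 1L
    }
    exceed <- exceed + (count >= observed)
    expected_hits <- expected_hits + count
  }
  p <- empirical_p(exceed, n_iterations)
  m <- bonferroni_m %||% n_chromosomes
  nm <- names(observed) %||% paste0("chr", as.character(utils::as.roman(seq_len(n_chromosomes))))
  out <- data.frame(chromosome = nm, observed = as.numeric(observed),
                    expected = expected_hits / n_iterations,
                    empirical_p = p, p_is_bound = exceed == 0,
                    bonferroni_p = pmin(1, p * m),
                    stringsAsFactors = FALSE)
  out$significant <- out$bonferroni_p < 0.05
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Monte-Carlo P-value for aneuploidy co-occurrence
#'
#' Given the observed marginal counts of two chromosome aneuploidies across
#' the sequenced strains, each iteration assigns each aneuploidy to an
#' independent uniform random subset of strains of the marginal size and
#' counts strains carrying both. The empirical P-value is the fraction of
#' iterations with at least the observed co-occurrence.
#'
#' @param marginal_i,marginal_j observed strain counts for the two
#'   chromosomes.
#' @param n_strains total strains.
#' @param observed_both observed count of strains with both aneuploidies.
#' @param n_iterations Monte-Carlo iterations (default 1e6).
#' @param seed integer seed.
#' @return list(empirical_p, p_is_bound, n_iterations, seed).
#' @export
cooccurrence_p <- function(marginal_i, marginal_j, n_strains, observed_both,
                           n_iterations = 1e6, seed = 1L) {
  stop_if_not(marginal_i <= n_strains && marginal_j <= n_strains,
              "marginals cannot exceed n_strains")
  if (observed_both > min(marginal_i, marginal_j))
    stop("observed_both exceeds a marginal: impossible observation",
         call. = FALSE)
  set.seed(seed)
  exceed <- 0L
  for (it in seq_len(n_iterations)) {
    a <- sample.int(n_strains, marginal_i)
    b <- sample.int(n_strains, marginal_j)
    if (length(intersect(a, b)) >= observed_both) exceed <- exceed + 1L
  }
  list(empirical_p = empirical_p(exceed, n_iterations),
       p_is_bound = exceed == 0L,
       n_iterations = n_iterations, seed = seed)
}
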