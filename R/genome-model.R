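#' Construct a genome model
#'
#' A lightweight stand-in for a reference genome: chromosome lengths, gene
#' intervals, an optional rDNA interval to exercise coverage exclusion, and
#' optional nucleotide sequence per chromosome (needed only for the
#' inverted-repeat search). All coordinates are 0-based half-open internally;
#' file writers convert at the boundary.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param genes data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open, within chromosome bounds, non-empty).
#' @param rdna optional list(chrom, start, end): interval whose coverage is
#'   excluded from karyotyping (the rDNA cluster on chromosome XII).
#' @param sequence optional named character vector of chromosome sequences.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes, rdna = NULL, sequence = NULL) {
  stop_if_not(is.data.frame(chromosomes) && all(c("name", "length") %in% names(chromosomes)),
              "chromosomes must have columns name, length")
  stop_if_not(is.data.frame(genes) && all(c("name", "chrom", "start", "end") %in% names(genes)),
              "genes must have columns name, chrom, start, end")
  stop_if_not(!anyDuplicated(chromosomes$name), "duplicate chromosome names")
  stop_if_not(all(chromosomes$length > 0), "chromosome lengths must be positive")
  stop_if_not(all(genes$chrom %in% chromosomes$name), "gene on unknown chromosome")
  stop_if_not(all(genes$end > genes$start), "zero-length gene interval")
  chr_len <- stats::setNames(chromosomes$length, chromosomes$name)
  stop_if_not(all(genes$start >= 0 & genes$end <= chr_len[genes$chrom]),
              "gene interval outside chromosome bounds")
  if (!is.null(rdna)) {
    stop_if_not(all(c("chrom", "start", "end") %in% names(rdna)) &&
                  rdna$chrom %in% chromosomes$name,
                "rdna must be list(chrom, start, end) on a known chromosome")
  }
  if (!is.null(sequence)) {
    stop_if_not(all(names(sequence) %in% chromosomes$name) &&
                  all(nchar(sequence) == chr_len[names(sequence)]),
                "sequence lengths must match chromosome lengths")
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 rdna = rdna, sequence = sequence),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes (%.2f Mb), %d genes%s%s\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes),
              if (is.null(x$rdna)) "" else ", rDNA interval set",
              if (is.null(x$sequence)) "" else ", sequence attached"))
  invisible(x)
}

#' Coding length per gene
#'
#' @param genome a `genome_model`.
#' @return named numeric vector of gene lengths (bp).
#' @export
gene_lengths <- function(genome) {
  stats::setNames(genome$genes$end - genome$genes$start, genome$genes$name)
}

#' A small 16-chromosome toy genome with planted genes
#'
#' Generates a scaled-down yeast-like genome: 16 chromosomes (roman-numeral
#' names), non-overlapping genes tiled with intergenic gaps, and an rDNA
#' interval on chromosome XII. Scaled down (~1-2 Mb total vs 12 Mb) so
#' simulation-heavy tests stay fast; chromosome count and gene density are
#' realistic.
#'
#' @param n_genes_per_chrom genes per chromosome.
#' @param chrom_length chromosome length in bp (single value or length 16).
#' @param gene_length mean gene length in bp (yeast median ~1.4 kb).
#' @param with_sequence attach random nucleotide sequence (only needed for
#'   repeat-search examples).
#' @param seed integer seed.
#' @return a `genome_model`.
#' @export
toy_genome_model <- function(n_genes_per_chrom = 10, chrom_length = 100000,
                             gene_length = 1400, with_sequence = FALSE,
                             seed = 1L) {
  set.seed(seed)
  roman <- as.character(utils::as.roman(1:16))
  lens <- rep_len(chrom_length, 16)
  chromosomes <- data.frame(name = paste0("chr", roman), length = lens,
                            stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(1:16, function(i) {
    n <- n_genes_per_chrom
    # tile genes evenly with jittered lengths; keep everything in bounds
    pitch <- floor(lens[i] / (n + 1))
    start <- pitch * seq_len(n) - pitch %/% 2
    glen <- pmax(300, round(stats::rnorm(n, gene_length, gene_length / 4)))
    glen <- pmin(glen, pitch - 100)
    data.frame(name = sprintf("GENE%02d_%02d", i, seq_len(n)),
               chrom = chromosomes$name[i],
               start = start, end = start + glen,
               stringsAsFactors = FALSE)
  }))
  rdna <- list(chrom = "chrXII", start = floor(lens[12] * 0.85),
               end = floor(lens[12] * 0.95))
  sequence <- NULL
  if (with_sequence) {
    sequence <- stats::setNames(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)), chromosomes$name)
  }
  genome_model(chromosomes, genes, rdna = rdna, sequence = sequence)
}
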