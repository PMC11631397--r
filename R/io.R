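# File-format boundaries. Internal coordinates are 0-based half-open;
# conversions happen here: VCF and repeat-pair TSV are 1-based inclusive,
# bedGraph/BED are 0-based half-open.

#' Write / read a colony-size plate grid as TSV
#'
#' A rows x cols matrix of pixel counts preceded by `#key<TAB>value`
#' metadata header lines (plate id, condition, concentration, day).
#'
#' @param grid numeric matrix.
#' @param path output file.
#' @param meta named list of metadata scalars.
#' @export
write_plate_grid <- function(grid, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s\t%s", k, meta[[k]]), con)
  utils::write.table(grid, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname write_plate_grid
#' @return `read_plate_grid`: list(grid, meta).
#' @export
read_plate_grid <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- strsplit(sub("^#", "", l), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  grid <- as.matrix(utils::read.table(text = lines[!is_meta], sep = "\t"))
  dimnames(grid) <- NULL
  list(grid = grid, meta = meta)
}

#' Write / read a genotype matrix as minimal VCF
#'
#' CHROM POS ID REF ALT QUAL FILTER INFO FORMAT plus one GT:GQ column per
#' strain; the ancestry map travels in `##ancestor=` header lines.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path (plain text `.vcf`).
#' @export
write_genotype_vcf <- function(gm, path) {
  strains <- colnames(gm$calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutscreen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
           sprintf("##ancestor=<Strain=%s,Ancestor=%s>",
                   names(gm$ancestry),
                   ifelse(is.na(gm$ancestry), ".", gm$ancestry)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strains), collapse = "\t"))
  body <- vapply(seq_len(nrow(gm$sites)), function(i) {
    gt <- paste(gm$calls[i, ], gm$gq[i, ], sep = ":")
    paste(c(gm$sites$chrom[i], gm$sites$pos[i], ".", gm$sites$ref[i],
            gm$sites$alt[i], "99", "PASS", ".", "GT:GQ", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' @rdname write_genotype_vcf
#' @return `read_genotype_vcf`: a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  lines <- readLines(path)
  anc_lines <- grep("^##ancestor=", lines, value = TRUE)
  anc_strain <- sub('.*Strain=([^,>]+).*', "\\1", anc_lines)
  anc_parent <- sub('.*Ancestor=([^,>]+).*', "\\1", anc_lines)
  header <- grep("^#CHROM", lines, value = TRUE)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  strains <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  sites <- data.frame(chrom = vapply(fields, `[`, "", 1),
                      pos = as.integer(vapply(fields, `[`, "", 2)),
                      ref = vapply(fields, `[`, "", 4),
                      alt = vapply(fields, `[`, "", 5),
                      stringsAsFactors = FALSE)
  alt1 <- vapply(strsplit(sites$alt, ","), `[`, "", 1)
  sites$is_indel <- nchar(alt1) != nchar(sites$ref)
  gtgq <- lapply(fields, function(f) {
    parts <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    list(gt = vapply(parts, `[`, "", 1),
         gq = as.integer(vapply(parts, `[`, "", 2)))
  })
  calls <- do.call(rbind, lapply(gtgq, `[[`, "gt"))
  gq <- do.call(rbind, lapply(gtgq, `[[`, "gq"))
  colnames(calls) <- colnames(gq) <- strains
  ancestry <- stats::setNames(ifelse(anc_parent == ".", NA_character_,
                                     anc_parent), anc_strain)
  genotype_matrix(sites, calls, gq, ancestry[strains])
}

#' Write / read a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output path (`.bedgraph`).
#' @export
write_coverage_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$windows$chrom,
                               IRanges::IRanges(track$windows$start + 1,
                                                track$windows$end),
                               score = track$windows$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' @rdname write_coverage_bedgraph
#' @param excluded optional exclusion data.frame to attach (chrom, start,
#'   end, 0-based half-open).
#' @return `read_coverage_bedgraph`: a [coverage_track()].
#' @export
read_coverage_bedgraph <- function(path, excluded = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1,
                            end = GenomicRanges::end(gr),
                            depth = gr$score, stringsAsFactors = FALSE),
                 excluded = excluded)
}

#' Write a genome model to FASTA + BED
#'
#' Sequence (if attached) goes to FASTA via Biostrings; gene intervals go to
#' BED (0-based half-open, as BED requires).
#'
#' @param genome a `genome_model`.
#' @param fasta_path,bed_path output paths (either may be NULL to skip).
#' @export
write_genome_files <- function(genome, fasta_path = NULL, bed_path = NULL) {
  if (!is.null(fasta_path)) {
    stop_if_not(!is.null(genome$sequence), "genome has no sequence attached")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequence),
                                fasta_path)
  }
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(genome$genes$chrom,
                                 IRanges::IRanges(genome$genes$start + 1,
                                                  genome$genes$end),
                                 name = genome$genes$name)
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(NULL)
}

#' Read gene intervals from a BED file
#'
#' @param path BED file.
#' @return data.frame name, chrom, start, end (0-based half-open).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write repeat pairs with 1-based inclusive coordinates
#'
#' @param pairs result of [find_inverted_repeats()].
#' @param path output TSV.
#' @export
write_repeat_pairs <- function(pairs, path) {
  out <- data.frame(left_start = pairs$left_start + 1,
                    left_end = pairs$left_end,
                    right_start = pairs$right_start + 1,
                    right_end = pairs$right_end,
                    length = pairs$length, spacer = pairs$spacer,
                    palindromic = pairs$palindromic,
                    left_seq = pairs$left_seq, right_seq = pairs$right_seq)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
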