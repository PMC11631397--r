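#' Six-rule site filter for haploid ancestor/derivative genotype matrices
#'
#' Applies, in order: (1) drop sites with >= 4 unique genotype calls across
#' all strains; (2) drop sites lacking 2 different homozygous calls; (3) drop
#' sites where an ancestral strain is heterozygous; (4) drop sites where an
#' ancestral call disagrees with all other calls; (5) per ancestor group,
#' drop the site for that group when > 10% of that ancestor's derivatives
#' lack a call; (6) drop sites with more than one indel allele called across
#' strains, or with genotype quality below 10. Rules 1-4 and 6 are global
#' site predicates; rule 5 is group-scoped, so retention is bookkept per
#' ancestor group and each removal is attributed to the first rule (in this
#' order) that fails.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_frac rule-5 threshold (default 0.1).
#' @param min_gq rule-6 genotype-quality floor (default 10), applied to the
#'   minimum GQ among non-missing calls at the site.
#' @param rule1_count_missing whether missing counts as a genotype call in
#'   rule 1 (default FALSE: missingness is rule 5's job).
#' @return list with `retained` (named list per ancestor of retained site
#'   row indices), `retained_union` (sorted union), and `removal_counts`
#'   (data.frame rule, ancestor, n).
#' @export
filter_sites <- function(gm, max_missing_frac = 0.1, min_gq = 10,
                         rule1_count_missing = FALSE) {
  stop_if_not(inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  calls <- gm$calls
  ancs <- ancestors_of(gm)
  stop_if_not(length(ancs) >= 1, "matrix has no ancestor strains")
  n_sites <- nrow(calls)

  uniq_calls <- apply(calls, 1, function(cc) {
    if (!rule1_count_missing) cc <- cc[!is_missing_call(cc)]
    length(unique(cc))
  })
  fail1 <- uniq_calls >= 4

  fail2 <- apply(calls, 1, function(cc) {
    hom <- cc[is_hom_call(cc)]
    length(unique(hom)) < 2
  })

  anc_calls <- calls[, ancs, drop = FALSE]
  fail3 <- apply(anc_calls, 1, function(cc) any(is_het_call(cc)))

  fail4 <- vapply(seq_len(n_sites), function(i) {
    any(vapply(ancs, function(a) {
      ac <- calls[i, a]
      if (is_missing_call(ac)) return(FALSE)
      others <- calls[i, setdiff(colnames(calls), a)]
      others <- others[!is_missing_call(others)]
      length(others) > 0 && !ac %in% others
    }, logical(1)))
  }, logical(1))

  alt_alleles <- strsplit(gm$sites$alt, ",", fixed = TRUE)
  called_codes <- lapply(seq_len(n_sites), function(i) {
    cc <- calls[i, ]
    cc <- cc[!is_missing_call(cc)]
    codes <- unique(unlist(strsplit(cc, "/", fixed = TRUE)))
    as.integer(codes[codes != "."])
  })
  n_indel_alleles <- vapply(seq_len(n_sites), function(i) {
    codes <- setdiff(called_codes[[i]], 0L)
    if (length(codes) == 0) return(0L)
    alts <- alt_alleles[[i]][codes]
    sum(nchar(alts) != nchar(gm$sites$ref[i]), na.rm = TRUE)
  }, integer(1))
  min_gq_site <- vapply(seq_len(n_sites), function(i) {
    ok <- !is_missing_call(calls[i, ])
    if (!any(ok)) return(Inf)
    min(gm$gq[i, ok])
  }, numeric(1))
  fail6 <- n_indel_alleles > 1 | min_gq_site < min_gq

  global_fail <- cbind(r1 = fail1, r2 = fail2, r3 = fail3, r4 = fail4)

  retained <- list()
  counts <- list()
  for (a in ancs) {
    derivs <- derivatives_of(gm, a)
    fail5 <- if (length(derivs) == 0) rep(FALSE, n_sites) else
      rowMeans(matrix(is_missing_call(calls[, derivs, drop = FALSE]),
                      n_sites)) > max_missing_frac
    fails <- cbind(global_fail, r5 = fail5, r6 = fail6)
    first_fail <- apply(fails, 1, function(f) if (any(f)) which(f)[1] else 0L)
    retained[[a]] <- which(first_fail == 0L)
    counts[[a]] <- data.frame(rule = paste0("r", 1:6), ancestor = a,
                              n = tabulate(first_fail, nbins = 6),
                              stringsAsFactors = FALSE)
  }
  list(retained = retained,
       retained_union = sort(unique(unlist(retained))),
       removal_counts = do.call(rbind, counts))
}

#' Assign retained sites to mutant strains
#'
#' A retained site is attributed to every derivative strain whose (non-
#' missing) call differs from its ancestor's call at that site.
#'
#' @param gm a [genotype_matrix()].
#' @param filtered result of [filter_sites()].
#' @return data.frame: strain, ancestor, site (row index), chrom, pos.
#' @export
strain_mutations <- function(gm, filtered) {
  out <- list()
  for (a in ancestors_of(gm)) {
    sites <- filtered$retained[[a]]
    for (s in derivatives_of(gm, a)) {
      sc <- gm$calls[sites, s]
      ac <- gm$calls[sites, a]
      hit <- sites[!is_missing_call(sc) & !is_missing_call(ac) & sc != ac]
      if (length(hit) > 0)
        out[[length(out) + 1]] <-
          data.frame(strain = s, ancestor = a, site = hit,
                     chrom = gm$sites$chrom[hit], pos = gm$sites$pos[hit],
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(strain = character(), ancestor = character(),
                      site = integer(), chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Tally disruptive mutations per gene
#'
#' Counts, per gene, the mutation events (strain x site) whose effect class
#' is disruptive (nonsynonymous, frameshift, nonsense, in-frame indel,
#' stop-lost); synonymous and intergenic changes are excluded. Retained
#' sites without an annotation are counted as class "other" with a warning.
#'
#' @param mutations data.frame from [strain_mutations()].
#' @param annotations data.frame chrom, pos, gene, effect.
#' @param gene_lengths named numeric vector of coding lengths (bp); genes
#'   with zero observed mutations are kept with count 0.
#' @return list of class `mutation_tally`: `observed` (named vector),
#'   `n_mut` (total disruptive events), `gene_lengths`, `per_strain`
#'   (named vector of per-strain total mutation counts).
#' @export
tally_disruptive <- function(mutations, annotations, gene_lengths) {
  stop_if_not(all(gene_lengths > 0), "gene lengths must be positive")
  key <- paste(annotations$chrom, annotations$pos)
  idx <- match(paste(mutations$chrom, mutations$pos), key)
  if (anyNA(idx))
    warning(sprintf("%d retained site(s) lack annotation; counted as 'other'",
                    sum(is.na(idx))))
  eff <- ifelse(is.na(idx), "other", annotations$effect[idx])
  gene <- ifelse(is.na(idx), NA_character_, annotations$gene[idx])
  disruptive <- eff %in% DISRUPTIVE_CLASSES & !is.na(gene)
  observed <- stats::setNames(rep(0, length(gene_lengths)), names(gene_lengths))
  if (any(disruptive)) {
    tab <- table(gene[disruptive])
    known <- intersect(names(tab), names(observed))
    observed[known] <- as.numeric(tab[known])
  }
  per_strain <- if (nrow(mutations) > 0) table(mutations$strain) else table(character())
  structure(list(observed = observed, n_mut = sum(disruptive),
                 gene_lengths = gene_lengths,
                 per_strain = stats::setNames(as.numeric(per_strain),
                                              names(per_strain))),
            class = "mutation_tally")
}

#' Filter structural-variant calls
#'
#' Post-processing of SV calls from a short-read caller: drops imprecise and
#' low-quality calls, drops calls shared by more than one strain
#' (non-singletons), and among heterozygous singletons retains only
#' duplications, since a duplication in a haploid may legitimately be called
#' heterozygous while other het singletons are artifacts.
#'
#' @param svs data.frame with columns `type` (deletion / duplication /
#'   inversion / translocation), `precise` (logical), `quality`.
#' @param calls character matrix, SVs x strains, VCF-style genotype codes.
#' @param min_quality quality floor (default 20).
#' @return integer vector of retained SV row indices.
#' @export
filter_svs <- function(svs, calls, min_quality = 20) {
  stop_if_not(nrow(svs) == nrow(calls), "svs and calls must align")
  carrier <- apply(calls, 1, function(cc)
    sum(!is_missing_call(cc) & cc != "0"))
  het_carrier <- apply(calls, 1, function(cc) any(is_het_call(cc)))
  keep <- svs$precise & svs$quality >= min_quality & carrier == 1 &
    (!het_carrier | svs$type == "duplication")
  which(keep)
}
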