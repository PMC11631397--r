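DISRUPTIVE_CLASSES <- c("nonsynonymous", "frameshift", "nonsense",
                        "in-frame indel", "stop-lost")
NONDISRUPTIVE_CLASSES <- c("synonymous", "intergenic", "other")

random_base <- function(n, exclude = NULL) {
  bases <- setdiff(c("A", "C", "G", "T"), exclude)
  sample(bases, n, replace = TRUE)
}

#' Generate a synthetic genotype matrix with planted causal mutations
#'
#' Emulates the variant-call table of a sequenced mutant screen: each
#' derivative strain carries exactly one planted disruptive mutation in a
#' randomly chosen causal gene, plus a Poisson-distributed number of
#' passenger mutations scattered over the genome (disruptive or silent
#' depending on where they land). Genotyping artifacts are injected at
#' stated rates: ancestral-heterozygous artifact sites, randomly missing
#' derivative calls, and spurious multi-allelic sites. With all artifact
#' rates at zero, every planted site survives the six-rule site filter.
#'
#' @param genome a `genome_model`.
#' @param n_strains_per_ancestor derivatives per ancestor.
#' @param causal_genes character vector of gene names from `genome`.
#' @param background_mut_rate mean passenger mutations per strain (Poisson).
#' @param artifact_rates list(het, missing, multiallelic): `het` is the
#'   expected number of ancestral-het artifact sites per real site;
#'   `missing` the per-call probability that a derivative call is missing;
#'   `multiallelic` the per-site probability of a spurious second alternate
#'   allele in a non-carrier strain.
#' @param n_ancestors number of ancestor groups.
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `annotations`
#'   (data.frame chrom, pos, gene, effect), and `truth` (data.frame strain,
#'   chrom, pos, gene, effect, is_causal).
#' @export
gen_genotype_data <- function(genome, n_strains_per_ancestor = 10,
                              causal_genes,
                              background_mut_rate = 5,
                              artifact_rates = list(het = 0, missing = 0,
                                                    multiallelic = 0),
                              n_ancestors = 2, seed = 1L) {
  stop_if_not(inherits(genome, "genome_model"), "genome must be a genome_model")
  unknown <- setdiff(causal_genes, genome$genes$name)
  if (length(unknown) > 0)
    stop("unknown causal gene name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  genes <- genome$genes
  chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)

  ancs <- sprintf("anc%d", seq_len(n_ancestors))
  derivs <- unlist(lapply(ancs, function(a)
    sprintf("%s_m%03d", a, seq_len(n_strains_per_ancestor))))
  ancestry <- stats::setNames(c(rep(NA_character_, n_ancestors),
                                rep(ancs, each = n_strains_per_ancestor)),
                              c(ancs, derivs))

  classify_position <- function(chrom, pos0) {
    # pos0 is 0-based; return gene name or NA (intergenic)
    hit <- which(genes$chrom == chrom & genes$start <= pos0 & pos0 < genes$end)
    if (length(hit) == 0) NA_character_ else genes$name[hit[1]]
  }

  events <- list()
  for (s in derivs) {
    g <- causal_genes[sample.int(length(causal_genes), 1)]
    gi <- genes[genes$name == g, ]
    pos0 <- gi$start + sample.int(gi$end - gi$start, 1) - 1L
    cls <- sample(c("nonsynonymous", "nonsense", "frameshift"), 1,
                  prob = c(0.6, 0.25, 0.15))
    events[[length(events) + 1]] <-
      data.frame(strain = s, chrom = gi$chrom, pos0 = pos0, effect = cls,
                 is_causal = TRUE, stringsAsFactors = FALSE)
    n_bg <- stats::rpois(1, background_mut_rate)
    if (n_bg > 0) {
      chroms <- sample(names(chrlen), n_bg, replace = TRUE,
                       prob = chrlen / sum(chrlen))
      p0 <- vapply(chroms, function(cn) sample.int(chrlen[[cn]], 1) - 1L,
                   integer(1))
      gene_hit <- mapply(classify_position, chroms, p0)
      cls_bg <- ifelse(is.na(gene_hit), "intergenic",
                       sample(c("nonsynonymous", "synonymous", "nonsense",
                                "frameshift", "in-frame indel", "stop-lost"),
                              n_bg, replace = TRUE,
                              prob = c(0.5, 0.25, 0.1, 0.08, 0.05, 0.02)))
      events[[length(events) + 1]] <-
        data.frame(strain = s, chrom = chroms, pos0 = p0, effect = cls_bg,
                   is_causal = FALSE, stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, events)
  ev$gene <- mapply(classify_position, ev$chrom, ev$pos0)

  # collapse events into sites; strains sharing a position share the allele
  key <- paste(ev$chrom, ev$pos0)
  site_keys <- unique(key)
  site_of_event <- match(key, site_keys)
  first <- ev[match(site_keys, key), ]
  is_indel <- first$effect %in% c("frameshift", "in-frame indel")
  ref <- random_base(length(site_keys))
  alt <- ifelse(is_indel,
                paste0(ref, random_base(length(site_keys))),  # 1-bp insertion
                vapply(ref, function(r) random_base(1, exclude = r), character(1)))
  sites <- data.frame(chrom = first$chrom, pos = first$pos0 + 1L,
                      ref = ref, alt = alt, is_indel = is_indel,
                      stringsAsFactors = FALSE)

  all_strains <- c(ancs, derivs)
  calls <- matrix("0", nrow(sites), length(all_strains),
                  dimnames = list(NULL, all_strains))
  calls[cbind(site_of_event, match(ev$strain, all_strains))] <- "1"
  gq <- matrix(99L, nrow(sites), length(all_strains),
               dimnames = list(NULL, all_strains))

  annotations <- data.frame(chrom = sites$chrom, pos = sites$pos,
                            gene = first$gene,
                            effect = first$effect, stringsAsFactors = FALSE)

  # --- artifacts -----------------------------------------------------------
  n_sites <- nrow(sites)
  if (artifact_rates$missing > 0) {
    miss <- matrix(stats::runif(n_sites * length(derivs)) < artifact_rates$missing,
                   n_sites, length(derivs))
    calls[, derivs][miss] <- "."
  }
  if (artifact_rates$multiallelic > 0) {
    hit <- which(stats::runif(n_sites) < artifact_rates$multiallelic)
    for (i in hit) {
      sites$alt[i] <- paste0(sites$alt[i], ",",
                             random_base(1, exclude = c(sites$ref[i])))
      victim <- sample(derivs, 1)
      calls[i, victim] <- "2"
    }
  }
  n_het <- stats::rpois(1, artifact_rates$het * n_sites)
  if (n_het > 0) {
    chroms <- sample(names(chrlen), n_het, replace = TRUE)
    p0 <- vapply(chroms, function(cn) sample.int(chrlen[[cn]], 1) - 1L, integer(1))
    href <- random_base(n_het)
    halt <- vapply(href, function(r) random_base(1, exclude = r), character(1))
    hsites <- data.frame(chrom = chroms, pos = p0 + 1L, ref = href, alt = halt,
                         is_indel = FALSE, stringsAsFactors = FALSE)
    hcalls <- matrix("0", n_het, length(all_strains),
                     dimnames = list(NULL, all_strains))
    hcalls[, ancs] <- "0/1"   # ancestral heterozygous: filter rule 3 target
    # scatter some derivative het/alt calls so the site is not monomorphic
    hcalls[cbind(seq_len(n_het), match(sample(derivs, n_het, replace = TRUE),
                                       all_strains))] <- "1"
    sites <- rbind(sites, hsites)
    calls <- rbind(calls, hcalls)
    gq <- rbind(gq, matrix(99L, n_het, length(all_strains),
                           dimnames = list(NULL, all_strains)))
    annotations <- rbind(annotations,
                         data.frame(chrom = hsites$chrom, pos = hsites$pos,
                                    gene = mapply(classify_position,
                                                  hsites$chrom, p0),
                                    effect = "other", stringsAsFactors = FALSE))
  }

  ord <- order(sites$chrom, sites$pos)
  truth <- data.frame(strain = ev$strain, chrom = ev$chrom, pos = ev$pos0 + 1L,
                      gene = ev$gene, effect = ev$effect,
                      is_causal = ev$is_causal, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(sites[ord, , drop = FALSE],
                                   calls[ord, , drop = FALSE],
                                   gq[ord, , drop = FALSE], ancestry),
       annotations = annotations[ord, , drop = FALSE],
       truth = truth)
}
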