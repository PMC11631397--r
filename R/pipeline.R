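#' Build a pipeline configuration
#'
#' One declarative object drives an end-to-end synthetic screen run:
#' simulate -> phenotype -> rates -> filter -> enrich -> karyotype. Every
#' stage can be toggled; all randomness derives from the single `seed` (each
#' stage gets a deterministic child stream via [derive_seed()]).
#'
#' @param seed master integer seed.
#' @param stages named logical vector of stage toggles.
#' @param scenario a [screen_scenario()] for the plate simulator.
#' @param genome a `genome_model` (default [toy_genome_model()]).
#' @param causal_genes causal gene names planted by the genotype simulator.
#' @param n_strains_per_ancestor sequenced derivatives per ancestor.
#' @param background_mut_rate mean passenger mutations per strain.
#' @param n_iterations Monte-Carlo iterations for enrichment nulls.
#' @param escapee_k escapee threshold multiplier.
#' @param base_depth sequencing depth per chromosome copy.
#' @param aneuploid_fraction fraction of sequenced strains given a chr VIII
#'   gain (the dominant real-screen karyotype class).
#' @param outdir optional directory for TSV outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c(simulate = TRUE, pheno = TRUE,
                                       rates = TRUE, filter = TRUE,
                                       enrich = TRUE, karyotype = TRUE),
                            scenario = NULL,
                            genome = NULL,
                            causal_genes = NULL,
                            n_strains_per_ancestor = 15,
                            background_mut_rate = 5,
                            n_iterations = 1e4,
                            escapee_k = 3,
                            base_depth = 30,
                            aneuploid_fraction = 0.3,
                            outdir = NULL) {
  defaults <- c(simulate = TRUE, pheno = TRUE, rates = TRUE, filter = TRUE,
                enrich = TRUE, karyotype = TRUE)
  st <- defaults
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), stages = st, scenario = scenario,
                 genome = genome, causal_genes = causal_genes,
                 n_strains_per_ancestor = n_strains_per_ancestor,
                 background_mut_rate = background_mut_rate,
                 n_iterations = n_iterations, escapee_k = escapee_k,
                 base_depth = base_depth,
                 aneuploid_fraction = aneuploid_fraction,
                 outdir = outdir),
            class = "pipeline_config")
}

log_stage <- function(report, stage, seed, ...) {
  msg <- sprintf("[%s] seed=%d %s", stage, seed,
                 paste(sprintf("%s=%s", names(list(...)), list(...)),
                       collapse = " "))
  c(report, msg)
}

#' Run the full synthetic screen pipeline
#'
#' Stages run in dependency order; disabling `simulate` disables everything
#' downstream that needs its outputs (fail-fast with the offending stage
#' named). Outputs are returned as a summary list; when `config$outdir` is
#' set, each table is also written as TSV.
#'
#' @param config a [pipeline_config()].
#' @return list with per-stage tables, a `log` of stage/seed provenance
#'   lines, and `truth` for comparison against planted values.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  st <- config$stages
  out <- list(log = character())
  need <- function(dep, stage) {
    if (!st[[dep]])
      stop(sprintf("stage '%s' requires outputs of disabled stage '%s'",
                   stage, dep), call. = FALSE)
  }

  if (st[["simulate"]]) {
    seed_sim <- derive_seed(config$seed, 0L)
    scenario <- config$scenario %||%
      screen_scenario(n_mutants = 90, noise_cv = 0.05, seed = seed_sim)
    genome <- config$genome %||% toy_genome_model(seed = derive_seed(config$seed, 1L))
    causal <- config$causal_genes %||% genome$genes$name[c(1, 25)]
    plates <- gen_plate_set(scenario)
    geno <- gen_genotype_data(genome, config$n_strains_per_ancestor, causal,
                              background_mut_rate = config$background_mut_rate,
                              seed = derive_seed(config$seed, 2L))
    n_seq <- config$n_strains_per_ancestor * 2
    seq_strains <- names(geno$genotypes$ancestry)[!is.na(geno$genotypes$ancestry)]
    set.seed(derive_seed(config$seed, 3L))
    kary <- matrix(1L, n_seq, 16, dimnames = list(seq_strains, NULL))
    n_aneu <- round(config$aneuploid_fraction * n_seq)
    if (n_aneu > 0) kary[sample(n_seq, n_aneu), 8] <- 2L   # chr VIII gain
    cnv <- list(chrom = "chrVIII",
                start = genome$genes$start[genome$genes$chrom == "chrVIII"][1],
                end = genome$genes$end[genome$genes$chrom == "chrVIII"][1],
                copies = 9, strains = seq_strains[1])
    tracks <- gen_coverage(genome, kary, base_depth = config$base_depth,
                           cnv = cnv, seed = derive_seed(config$seed, 4L))
    rates_truth <- data.frame(
      pool = rep(c("mutagenized", "mock"), each = 4),
      concentration = rep(c(0.1, 0.2, 0.4, 0.6), 2),
      rate = c(1e-5, 5e-6, 1e-6, 5e-7, 1e-7, 5e-8, 1e-8, 5e-9))
    counts <- gen_plating_counts(rates_truth, cells_plated = 1e7,
                                 seed = derive_seed(config$seed, 5L))
    out$simulated <- list(plates = plates, genotypes = geno, tracks = tracks,
                          counts = counts, karyotype_truth = kary,
                          cnv_truth = cnv, genome = genome)
    out$truth <- plates$truth
    out$log <- log_stage(out$log, "simulate", seed_sim,
                         mutants = scenario$n_mutants, strains = n_seq)
  }

  if (st[["pheno"]]) {
    need("simulate", "pheno")
    scores <- score_plates(out$simulated$plates, k = config$escapee_k)
    norm_perm <- lapply(out$simulated$plates$permissive, normalize_edges)
    layout <- out$simulated$plates$layout
    occupied <- !is.na(layout$strain)
    sizes_by_cond <- lapply(norm_perm, function(g) {
      stats::setNames(g[cbind(layout$row, layout$col)][occupied],
                      layout$strain[occupied])
    })
    anc <- layout$strain[layout$role == "ancestor"]
    costs <- cost_profile(sizes_by_cond,
                          lapply(sizes_by_cond, function(v) v[anc]),
                          strains = layout$strain[occupied])
    pheno <- merge(scores, costs, by = "strain", sort = FALSE)
    retained <- pheno$role == "mutant" & !pheno$escapee & !is.na(pheno$escapee)
    out$pheno <- pheno
    out$retention <- retention_percentage(sum(retained),
                                          sum(pheno$role == "mutant"))
    out$log <- log_stage(out$log, "pheno", config$seed,
                         retained_pct = out$retention)
  }

  if (st[["rates"]]) {
    need("simulate", "rates")
    cnt <- out$simulated$counts
    est <- cbind(cnt, estimate_rate(cnt$colonies, cnt$cells_plated))
    mut <- cnt[cnt$pool == "mutagenized", ]
    mock <- cnt[cnt$pool == "mock", ]
    cmp <- compare_rates(mut, mock)
    top <- max(mut$concentration)
    fold <- (mut$colonies[mut$concentration == top] /
               mut$cells_plated[mut$concentration == top]) /
      (mock$colonies[mock$concentration == top] /
         mock$cells_plated[mock$concentration == top])
    per_bp <- induced_per_bp_rate(fold)
    sat <- genome_saturation(per_bp, cells_plated = sum(mut$cells_plated))
    out$rates <- list(estimates = est, comparisons = cmp,
                      fold_increase = fold, per_bp_rate = per_bp,
                      per_genome = sat$per_genome,
                      per_site_saturation = sat$per_site_saturation)
    out$log <- log_stage(out$log, "rates", config$seed, fold = round(fold, 2))
  }

  if (st[["filter"]]) {
    need("simulate", "filter")
    geno <- out$simulated$genotypes
    filt <- filter_sites(geno$genotypes)
    muts <- strain_mutations(geno$genotypes, filt)
    tally <- tally_disruptive(muts, geno$annotations,
                              gene_lengths(out$simulated$genome))
    out$filter <- list(result = filt, mutations = muts, tally = tally)
    out$log <- log_stage(out$log, "filter", config$seed,
                         retained = length(filt$retained_union))
  }

  if (st[["enrich"]]) {
    need("filter", "enrich")
    gene_enr <- simulate_gene_null(out$filter$tally,
                                   n_iterations = config$n_iterations,
                                   seed = derive_seed(config$seed, 6L))
    out$enrich <- list(genes = gene_enr)
    kt <- out$simulated$karyotype_truth
    aneu <- rowSums(kt != 1)
    if (any(aneu > 0)) {
      obs <- colSums(kt != 1)
      out$enrich$aneuploidy <-
        simulate_aneuploidy_null(aneu[aneu > 0], obs,
                                 n_chromosomes = ncol(kt),
                                 n_iterations = min(config$n_iterations, 1e4),
                                 seed = derive_seed(config$seed, 7L))
    }
    out$log <- log_stage(out$log, "enrich", derive_seed(config$seed, 6L),
                         significant = sum(gene_enr$significant))
  }

  if (st[["karyotype"]]) {
    need("simulate", "karyotype")
    calls <- lapply(out$simulated$tracks, chromosome_copy_numbers)
    kary_tab <- do.call(rbind, lapply(names(calls), function(s) {
      k <- calls[[s]]
      data.frame(strain = s, chromosome = k$chromosome,
                 relative_depth = k$relative_depth, cn_min1 = k$cn_min1,
                 cn_min2 = k$cn_min2, anomalous = k$anomalous,
                 stringsAsFactors = FALSE)
    }))
    diplo <- vapply(calls, detect_diploidization, logical(1))
    cnv <- out$simulated$cnv_truth
    cnv_est <- locus_copy_number(out$simulated$tracks[[cnv$strains]],
                                 cnv$chrom, cnv$start, cnv$end)
    out$karyotype <- list(calls = kary_tab, diploidized = diplo,
                          focal_cnv_copy = cnv_est$copy_number)
    out$log <- log_stage(out$log, "karyotype", config$seed,
                         focal_cnv = round(cnv_est$copy_number, 2))
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, nm) if (!is.null(x))
      write_tsv(x, file.path(config$outdir, paste0(nm, ".tsv")))
    w(out$pheno, "phenotypes")
    w(out$rates$estimates, "rate_estimates")
    w(out$rates$comparisons, "rate_comparisons")
    w(out$filter$result$removal_counts, "filter_removals")
    w(out$filter$mutations, "strain_mutations")
    w(out$enrich$genes, "gene_enrichment")
    w(out$enrich$aneuploidy, "aneuploidy_enrichment")
    w(out$karyotype$calls, "karyotypes")
    writeLines(out$log, file.path(config$outdir, "pipeline_log.txt"))
  }
  out
}
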