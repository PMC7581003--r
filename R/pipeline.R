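#' Run the full cohort analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> ingest -> prune -> constraint -> svmerge ->
#' segregate with one configuration and one seed. All generator inputs are
#' written to `out_dir` in their interchange formats (VCF, TSV, BED), the
#' VCF is read back through the ingestion path (so the pipeline exercises
#' the same code real data would), and every stage writes its result tables
#' plus a top-level JSON report of headline numbers.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param n_perm permutations for the enrichment CIs.
#' @param kinship_threshold pruning cutoff on phi (default 0.15).
#' @param panel panel specification: list(n_unaffected, n_affected,
#'   n_discordant).
#' @param stages character subset of c("ingest", "prune", "constraint",
#'   "sv", "segregate") to run after simulation.
#' @return the report list, invisibly; written to `report.json`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("felcohort_run_"),
                         n_perm = 2000,
                         kinship_threshold = 0.15,
                         panel = list(n_unaffected = 41, n_affected = 68,
                                      n_discordant = 1),
                         stages = c("ingest", "prune", "constraint", "sv",
                                    "segregate")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, n_samples = config$n_samples,
                 n_genes = config$n_genes)

  # --- simulate -------------------------------------------------------------
  gen <- generate_genes(config)
  cohort <- generate_cohort(config, gen)
  svs <- generate_dual_caller_svs(config)
  pan <- generate_segregation_panel(panel$n_unaffected, panel$n_affected,
                                    panel$n_discordant)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  write_cohort_vcf(cohort, vcf_path)
  write_gene_table(gen$genes, file.path(out_dir, "genes.tsv"))
  write_exon_bed(gen$exons, file.path(out_dir, "exons.bed"))
  write_impact_table(cohort$impacts, file.path(out_dir, "impacts.tsv"))
  write_sv_callset(svs$callset_a, file.path(out_dir, "sv_caller_a.tsv"))
  write_sv_callset(svs$callset_b, file.path(out_dir, "sv_caller_b.tsv"))
  write_panel(pan, file.path(out_dir, "panel.tsv"))

  loaded <- NULL
  if ("ingest" %in% stages) {
    loaded <- load_sites(vcf_path, file.path(out_dir, "impacts.tsv"),
                         file.path(out_dir, "genes.tsv"))
    stats <- site_statistics(loaded$variants)
    ps <- per_sample_stats(loaded$variants, loaded$genotypes)
    write.table(ps, file.path(out_dir, "per_sample_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$site_summary <- stats
    report$mean_snvs_per_sample <- mean(ps$n_snvs)
  }

  retained <- cohort$sample_ids
  if ("prune" %in% stages && !is.null(loaded)) {
    kin <- kinship_matrix(loaded$genotypes)
    write_kinship(kin, file.path(out_dir, "kinship.tsv"))
    pruned <- prune_related(kin, threshold = kinship_threshold)
    retained <- pruned$retained
    writeLines(retained, file.path(out_dir, "retained_samples.txt"))
    report$n_retained <- length(retained)
    report$n_removed_related <- length(pruned$removed)
  }

  if ("constraint" %in% stages && !is.null(loaded)) {
    sub <- subset_samples(loaded$variants, loaded$genotypes, retained)
    genes <- assign_constraint_groups(gen$genes)
    tab <- constraint_table(sub$variants, genes)
    dens <- density_enrichment(tab, n_perm = n_perm, seed = config$seed + 10L)
    sing <- singleton_enrichment(tab, n_perm = n_perm, seed = config$seed + 11L)
    fish_c <- fisher_contrasts(tab, "counts")
    fish_s <- fisher_contrasts(tab, "singletons")
    spec <- maf_spectrum(sub$variants)
    cand <- prioritize_candidates(sub$variants, genes, sub$genotypes)
    for (nm in c("density_enrichment", "singleton_enrichment",
                 "fisher_counts", "fisher_singletons", "maf_spectrum",
                 "candidates")) {
      obj <- switch(nm, density_enrichment = dens, singleton_enrichment = sing,
                    fisher_counts = fish_c, fisher_singletons = fish_s,
                    maf_spectrum = spec, candidates = cand)
      write.table(obj, file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$density_enrichment <- dens[, c("group", "impact", "pct_diff",
                                          "pct_ci_low", "pct_ci_high")]
    report$singleton_enrichment <- sing[, c("group", "impact", "pct_diff")]
    report$n_lof_singleton_candidates <- nrow(cand)
    report$n_concordant_candidates <- sum(cand$concordant)
  }

  if ("sv" %in% stages) {
    merged <- merge_callsets(svs$callset_a, svs$callset_b)
    merged <- annotate_sv_regions(merged, gen$genes, gen$exons)
    fs <- sv_frequency_spectrum(merged, config$n_samples)
    sv_stats <- cohort_sv_stats(merged, cohort$sample_ids)
    write.table(fs$sv, file.path(out_dir, "merged_svs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fs$spectrum, file.path(out_dir, "sv_spectrum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$n_merged_svs <- nrow(merged)
    report$n_dual_caller_svs <- sum(merged$n_callers == 2)
    report$mean_svs_per_sample <- mean(sv_stats$per_sample$n_svs)
    report$n_high_frequency_svs <- sum(fs$sv$high_frequency)
  }

  if ("segregate" %in% stages) {
    counts <- panel_genotype_counts(pan)
    hwe <- hwe_chisq(counts["hom_ref"], counts["het"], counts["hom_alt"])
    conc <- concordance_report(pan)
    write.table(conc$discordant, file.path(out_dir, "discordant_samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$segregation <- list(
      genotype_counts = as.list(counts),
      hwe_chi2 = hwe$chi2, hwe_p = hwe$p_value,
      n_discordant = nrow(conc$discordant))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
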