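#' Load a multi-sample SNV VCF with impact and gene annotations
#'
#' Reads a VCF v4.2 (plain or gzipped) via vcfR, retains SNV records (REF and
#' every ALT allele a single base), and computes per-site allele count (AC),
#' allele number (AN, excluding missing genotypes), folded minor allele
#' frequency, singleton / biallelic / transition flags. Non-SNV records are
#' dropped with a message. When an impact table is given, per-source impact
#' columns (`impact_<source>`) and a collapsed primary `impact` column are
#' attached; if a source annotates a variant at several severities (e.g. per
#' transcript) the most severe class wins (LoF > missense > synonymous >
#' other). When a gene table with pLI is given, genes are binned into
#' constraint groups and a `group` column is attached.
#'
#' At multi-allelic sites the dosage counts all non-reference alleles; MAF,
#' singleton and transition flags are only defined for biallelic SNVs (NA
#' otherwise), matching the biallelic scope of the downstream statistics.
#'
#' @param vcf_path path to the VCF.
#' @param impact_path optional impact TSV (variant_id, source, impact,
#'   gene_id).
#' @param gene_path optional gene TSV (see [write_gene_table()]).
#' @param primary_source which annotation source supplies the `impact`
#'   column; default the first source listed in the table.
#' @return list with `variants`, `genotypes` (sites x samples dosage matrix
#'   with NA for missing), `sample_ids` and `n_dropped_non_snv`.
#' @export
load_sites <- function(vcf_path, impact_path = NULL, gene_path = NULL,
                       primary_source = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  is_snv <- nchar(fix$REF) == 1L & fix$REF %in% c("A", "C", "G", "T") &
    vapply(alts, function(a) length(a) >= 1 && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
           logical(1))
  n_dropped <- sum(!is_snv)
  if (n_dropped > 0) message(n_dropped, " non-SNV record(s) dropped")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- gt[is_snv, , drop = FALSE]
  fix <- fix[is_snv, , drop = FALSE]

  G <- .gt_to_dosage(gt)
  an <- as.integer(2L * rowSums(!is.na(G)))
  ac <- as.integer(rowSums(G, na.rm = TRUE))
  is_biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  maf <- ifelse(is_biallelic & an > 0, pmin(ac, an - ac) / an, NA_real_)
  transition_pairs <- c(A = "G", G = "A", C = "T", T = "C")
  is_transition <- ifelse(is_biallelic,
                          transition_pairs[fix$REF] == fix$ALT, NA)

  variants <- data.frame(
    variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    chrom = fix$CHROM, pos = fix$POS, ref = fix$REF, alt = fix$ALT,
    ac = ac, an = an, maf = maf,
    is_singleton = is_biallelic & ac == 1L,
    is_biallelic = is_biallelic,
    is_transition = as.logical(is_transition),
    stringsAsFactors = FALSE
  )
  rownames(G) <- variants$variant_id
  rownames(variants) <- NULL

  if (!is.null(impact_path)) {
    imp <- read.delim(impact_path, stringsAsFactors = FALSE)
    missing_var <- setdiff(unique(imp$variant_id), variants$variant_id)
    if (length(missing_var)) {
      warning(length(missing_var),
              " annotated variant(s) absent from the VCF were skipped")
      imp <- imp[!imp$variant_id %in% missing_var, , drop = FALSE]
    }
    sources <- unique(imp$source)
    if (is.null(primary_source)) primary_source <- sources[1]
    sev <- function(x) .impact_levels[min(match(x, .impact_levels), na.rm = TRUE)]
    for (s in sources) {
      sub <- imp[imp$source == s, , drop = FALSE]
      collapsed <- tapply(sub$impact, sub$variant_id, sev)
      variants[[paste0("impact_", s)]] <-
        as.character(collapsed[variants$variant_id])
    }
    variants$impact <- variants[[paste0("impact_", primary_source)]]
    gene_of <- tapply(imp$gene_id, imp$variant_id, function(x) x[1])
    variants$gene_id <- as.character(gene_of[variants$variant_id])
  }

  if (!is.null(gene_path)) {
    genes <- read_gene_table(gene_path)
    genes <- assign_constraint_groups(genes)
    if (!is.null(variants$gene_id))
      variants$group <- genes$group[match(variants$gene_id, genes$gene_id)]
  }

  list(variants = variants, genotypes = G,
       sample_ids = colnames(G), n_dropped_non_snv = n_dropped)
}

# "0/1", "0|1", "./." etc. -> dosage of non-reference alleles (NA if missing)
.gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 != "0" & a1 != ".") + (a2 != "0" & a2 != ".")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA
  storage.mode(d) <- "integer"
  dim(d) <- dim(gt)
  colnames(d) <- colnames(gt)
  d
}

#' Cohort-level site summary
#'
#' @param variants variant table from [load_sites()] or [generate_cohort()].
#' @return list with `n_sites`, `n_biallelic`, `pct_biallelic`,
#'   `tstv` (transitions / transversions over biallelic SNVs; NA with a
#'   warning if there are no transversions) and `singleton_fraction`
#'   (singletons / biallelic sites).
#' @export
site_statistics <- function(variants) {
  stopifnot(nrow(variants) >= 1)
  bi <- variants[variants$is_biallelic, , drop = FALSE]
  ts <- sum(bi$is_transition, na.rm = TRUE)
  tv <- sum(!bi$is_transition, na.rm = TRUE)
  tstv <- if (tv == 0) {
    warning("no transversions: Ts/Tv undefined")
    NA_real_
  } else ts / tv
  list(n_sites = nrow(variants), n_biallelic = nrow(bi),
       pct_biallelic = 100 * nrow(bi) / nrow(variants),
       n_transitions = ts, n_transversions = tv, tstv = tstv,
       singleton_fraction = mean(bi$ac == 1L))
}

#' Per-sample SNV, singleton and inbreeding statistics
#'
#' `n_snvs` counts biallelic sites at which the sample carries at least one
#' alternate allele; `n_singletons` counts sites where the cohort allele
#' count is 1 and that single allele is in this sample. The inbreeding
#' coefficient is the method-of-moments estimate
#' `F = (O_hom - E_hom) / (N - E_hom)` over polymorphic biallelic sites,
#' where the expected homozygosity uses cohort allele frequencies with the
#' small-sample correction `2N/(2N - 1)` on expected heterozygosity.
#'
#' @param variants,genotypes as returned by [load_sites()].
#' @param cohort_labels optional named vector (or vector aligned to samples)
#'   of free-text cohort labels (e.g. breed vs random bred).
#' @return data.frame with sample_id, n_snvs, n_singletons, inbreeding_f and
#'   cohort_label.
#' @export
per_sample_stats <- function(variants, genotypes, cohort_labels = NULL) {
  stopifnot(nrow(variants) == nrow(genotypes))
  bi <- variants$is_biallelic
  G <- genotypes[bi, , drop = FALSE]
  v <- variants[bi, , drop = FALSE]

  n_snvs <- colSums(G >= 1L, na.rm = TRUE)
  singleton <- v$ac == 1L
  n_singletons <- colSums(G[singleton, , drop = FALSE] == 1L, na.rm = TRUE)

  # inbreeding F over polymorphic sites
  nonmiss <- !is.na(G)
  an <- 2 * rowSums(nonmiss)
  ac <- rowSums(G, na.rm = TRUE)
  poly <- an > 2 & ac > 0 & ac < an
  Gp <- G[poly, , drop = FALSE]
  p <- (ac / an)[poly]
  corr <- (an / (an - 1))[poly]
  ehet_site <- 2 * p * (1 - p) * corr
  nm <- !is.na(Gp)
  n_used <- colSums(nm)
  e_hom <- colSums(nm * (1 - ehet_site))
  o_hom <- colSums(Gp != 1L, na.rm = TRUE)
  f <- (o_hom - e_hom) / (n_used - e_hom)

  labels <- if (is.null(cohort_labels)) NA_character_
    else if (!is.null(names(cohort_labels))) unname(cohort_labels[colnames(G)])
    else cohort_labels
  data.frame(sample_id = colnames(G), n_snvs = as.integer(n_snvs),
             n_singletons = as.integer(n_singletons), inbreeding_f = f,
             cohort_label = labels, row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of a per-sample statistic between two cohorts
#'
#' Two-sided Wilcoxon rank-sum test (exact where possible, normal
#' approximation with midranks in the presence of ties). If both groups are
#' constant and equal, a warning is raised and p = 1 is returned.
#'
#' @param values numeric per-sample statistic.
#' @param labels two-level grouping aligned with `values`.
#' @return list with `statistic`, `p_value`, `method` and group sizes.
#' @export
compare_groups <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must define exactly two groups", call. = FALSE)
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    warning("constant values in both groups; p = 1")
    return(list(statistic = NA_real_, p_value = 1, method = "degenerate",
                n = c(length(x), length(y))))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, n = c(length(x), length(y)))
}

#' Recompute site statistics after subsetting samples
#'
#' Restricts a cohort to the given samples and recomputes AC, AN, MAF and
#' the singleton flag from the remaining genotypes (used after relatedness
#' pruning, where singleton status must reflect the analysis set).
#'
#' @param variants,genotypes as returned by [load_sites()].
#' @param samples sample IDs to keep.
#' @param drop_monomorphic drop sites with AC = 0 in the subset (default TRUE).
#' @return list with updated `variants`, `genotypes`, `sample_ids`.
#' @export
subset_samples <- function(variants, genotypes, samples, drop_monomorphic = TRUE) {
  missing <- setdiff(samples, colnames(genotypes))
  if (length(missing)) stop("samples absent from genotype matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  G <- genotypes[, samples, drop = FALSE]
  an <- as.integer(2L * rowSums(!is.na(G)))
  ac <- as.integer(rowSums(G, na.rm = TRUE))
  v <- variants
  v$ac <- ac; v$an <- an
  v$maf <- ifelse(v$is_biallelic & an > 0, pmin(ac, an - ac) / an, NA_real_)
  v$is_singleton <- v$is_biallelic & ac == 1L
  if (drop_monomorphic) {
    keep <- ac > 0L
    v <- v[keep, , drop = FALSE]
    G <- G[keep, , drop = FALSE]
    rownames(v) <- NULL
  }
  list(variants = v, genotypes = G, sample_ids = samples)
}
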