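#' Simulate an annotated multi-sample SNV cohort
#'
#' For each gene `g` and coding impact `I`, the number of segregating SNVs is
#' Poisson with rate `coding_length_g / 1000 * baseline_density[I] *
#' depletion_multiplier[group(g), I]`. Every SNV receives a population allele
#' frequency from the configured MAF model and per-sample genotypes under
#' Hardy-Weinberg, conditioned on the site actually segregating in the cohort
#' (allele count >= 1), so realized per-kb densities match the configured
#' rates. Singleton status arises from the realized sample allele counts;
#' `singleton_enrichment` factors are honoured by re-drawing genotypes for a
#' computed fraction of sites (forcing or vetoing the singleton
#' configuration) so that each cell's singleton probability is multiplied by
#' the requested factor.
#'
#' Two annotation sources are emulated: the first always reports the true
#' impact, the second agrees with probability `annotation_concordance` and
#' otherwise reports a different class (possibly `"other"`).
#'
#' @param config a [sim_config()] object.
#' @param genes output of [generate_genes()] (the full list, or just its
#'   `genes` element plus an `exons` data frame via the `exons` argument).
#' @param exons exon table; defaults to `genes$exons` when `genes` is the
#'   full generator output.
#' @return list with `variants` (one row per SNV: variant_id, chrom, pos,
#'   ref, alt, gene_id, group, impact, pop_maf, ac, an, maf, is_singleton,
#'   is_biallelic), `genotypes` (sites x samples dosage matrix, 0/1/2),
#'   `impacts` (long annotation table: variant_id, source, impact, gene_id)
#'   and `sample_ids`.
#' @export
generate_cohort <- function(config, genes, exons = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(genes) && !is.data.frame(genes)) {
    exons <- genes$exons
    genes <- genes$genes
  }
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  set.seed(config$seed + 1L)

  ns <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))

  zero_len <- genes$coding_length <= 0
  if (any(zero_len)) {
    warning(sum(zero_len), " gene(s) with zero-length coding sequence skipped")
    genes <- genes[!zero_len, , drop = FALSE]
  }

  dens <- config$baseline_density
  mult <- config$depletion_multiplier
  lam <- outer(genes$coding_length / 1000, dens) * mult[genes$group, , drop = FALSE]
  nvar <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))

  gene_idx <- rep(rep(seq_len(nrow(genes)), times = ncol(nvar)), times = as.vector(nvar))
  impact <- rep(rep(.coding_impacts, each = nrow(nvar)), times = as.vector(nvar))
  nv <- length(gene_idx)
  if (nv == 0) stop("configuration produced zero variants", call. = FALSE)

  # place variants at distinct coding offsets, mapped through exon structure
  pos <- integer(nv)
  ex_by_gene <- split(exons, exons$gene_id)
  for (gi in unique(gene_idx)) {
    rows <- which(gene_idx == gi)
    ex <- ex_by_gene[[genes$gene_id[gi]]]
    el <- ex$end - ex$start + 1L
    cl <- sum(el)
    off <- sample.int(cl, min(length(rows), cl))
    rows <- rows[seq_along(off)]
    cum <- c(0L, cumsum(el))
    j <- findInterval(off - 1L, cum, rightmost.closed = FALSE)
    pos[rows] <- ex$start[j] + (off - 1L - cum[j])
  }

  # ref/alt with configured transition probability
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, nv, replace = TRUE)
  is_ts <- runif(nv) < config$transition_prob
  alt <- character(nv)
  alt[is_ts] <- transition[ref[is_ts]]
  tv_choice <- cbind(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  pick <- 1L + (runif(nv) < 0.5)
  alt[!is_ts] <- tv_choice[cbind(pick[!is_ts], match(ref[!is_ts], colnames(tv_choice)))]

  # genotypes under HWE, ascertained to segregate (AC >= 1)
  p <- .draw_maf(nv, config$maf_model)
  G <- matrix(rbinom(nv * ns, 2L, p), nv, ns)
  repeat {
    mono <- which(rowSums(G) == 0L)
    if (!length(mono)) break
    p[mono] <- .draw_maf(length(mono), config$maf_model)
    G[mono, ] <- rbinom(length(mono) * ns, 2L, p[mono])
  }

  # singleton enrichment by forced / vetoed singleton configurations
  enr <- config$singleton_enrichment
  e_of <- enr[cbind(match(genes$group[gene_idx], .constraint_groups),
                    match(impact, .coding_impacts))]
  if (any(e_of != 1)) {
    s0 <- .singleton_prob_base(ns, config$maf_model)
    up <- which(e_of > 1)
    if (length(up)) {
      pi_up <- pmin(1, s0 * (e_of[up] - 1) / (1 - s0))
      force_rows <- up[runif(length(up)) < pi_up]
      for (r in force_rows) {
        G[r, ] <- 0L
        G[r, sample.int(ns, 1)] <- 1L
      }
    }
    down <- which(e_of < 1)
    if (length(down)) {
      veto_rows <- down[runif(length(down)) < (1 - e_of[down])]
      for (r in veto_rows) {
        while (sum(G[r, ]) < 2L) {
          p[r] <- .draw_maf(1, config$maf_model)
          G[r, ] <- rbinom(ns, 2L, p[r])
        }
      }
    }
  }

  ac <- rowSums(G)
  an <- rep(2L * ns, nv)
  maf <- pmin(ac, an - ac) / an

  variants <- data.frame(
    chrom = genes$chrom[gene_idx], pos = pos, ref = ref, alt = alt,
    gene_id = genes$gene_id[gene_idx], group = genes$group[gene_idx],
    impact = impact, pop_maf = p, ac = as.integer(ac), an = an, maf = maf,
    is_singleton = ac == 1L, is_biallelic = TRUE,
    is_transition = unname(transition[ref] == alt),
    stringsAsFactors = FALSE
  )
  ord <- order(match(variants$chrom, unique(genes$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  G <- G[ord, , drop = FALSE]
  variants$variant_id <- paste(variants$chrom, variants$pos,
                               variants$ref, variants$alt, sep = ":")
  rownames(variants) <- NULL
  colnames(G) <- sample_ids
  rownames(G) <- variants$variant_id

  # two annotation sources
  n2 <- nrow(variants)
  agree <- runif(n2) < config$annotation_concordance
  other_impact <- vapply(variants$impact, function(im)
    sample(setdiff(.impact_levels, im), 1), character(1))
  impacts <- rbind(
    data.frame(variant_id = variants$variant_id, source = "ensembl_like",
               impact = variants$impact, gene_id = variants$gene_id,
               stringsAsFactors = FALSE),
    data.frame(variant_id = variants$variant_id, source = "ncbi_like",
               impact = ifelse(agree, variants$impact, other_impact),
               gene_id = variants$gene_id, stringsAsFactors = FALSE)
  )

  list(variants = variants, genotypes = G, impacts = impacts,
       sample_ids = sample_ids)
}

# P(AC = 1 | AC >= 1) for a site drawn from the MAF model in 2n alleles
.singleton_prob_base <- function(n_samples, model) {
  n2 <- 2L * n_samples
  dens <- if (model$dist == "beta") {
    norm <- pbeta(0.5, model$shape1, model$shape2)
    function(p) dbeta(p, model$shape1, model$shape2) / norm
  } else {
    function(p) dunif(p, model$min, model$max)
  }
  lo <- if (model$dist == "uniform") model$min else 0
  hi <- if (model$dist == "uniform") model$max else 0.5
  i0 <- integrate(function(p) (1 - p)^n2 * dens(p), lo, hi)$value
  i1 <- integrate(function(p) n2 * p * (1 - p)^(n2 - 1) * dens(p), lo, hi)$value
  i1 / (1 - i0)
}

#' Write a multi-sample VCF v4.2 for a simulated cohort
#'
#' @param cohort output of [generate_cohort()], or a list with `variants`,
#'   `genotypes` and `sample_ids` in the same layout.
#' @param path output file (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  G <- cohort$genotypes
  gt <- c("0/0", "0/1", "1/1")[G + 1L]
  dim(gt) <- dim(G)
  chroms <- unique(v$chrom)
  contig <- vapply(chroms, function(ch)
    sprintf("##contig=<ID=%s,length=%d>", ch, max(v$pos[v$chrom == ch]) + 10000L),
    character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=felcohort",
    contig,
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                sprintf("AC=%d;AN=%d", v$ac, v$an), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the per-source impact annotation TSV
#' @param impacts long impact table from [generate_cohort()].
#' @param path output file.
#' @export
write_impact_table <- function(impacts, path) {
  write.table(impacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
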