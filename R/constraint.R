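#' Assign genes to pLI constraint groups
#'
#' Bins genes by their probability of loss-of-function intolerance: weak if
#' pLI < 0.1, strong if pLI > 0.9, moderate otherwise (the boundary values
#' 0.1 and 0.9 fold into moderate, keeping the weak and strong bins pure).
#' Genes with missing pLI are labelled `unassigned` and excluded from every
#' constraint statistic.
#'
#' @param genes data.frame with a `pli` column in `[0, 1]` (NA allowed).
#' @param weak_max,strong_min the two pLI cutpoints.
#' @return `genes` with a `group` column.
#' @export
assign_constraint_groups <- function(genes, weak_max = 0.1, strong_min = 0.9) {
  pli <- genes$pli
  if (any(!is.na(pli) & (pli < 0 | pli > 1)))
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  group <- rep("unassigned", nrow(genes))
  group[!is.na(pli) & pli < weak_max] <- "weak"
  group[!is.na(pli) & pli >= weak_max & pli <= strong_min] <- "moderate"
  group[!is.na(pli) & pli > strong_min] <- "strong"
  genes$group <- group
  genes
}

#' Tabulate coding SNV and singleton counts by constraint group and impact
#'
#' Aggregates the count machinery behind all constraint-group statistics:
#' per (group G, impact I) the SNV count `X_GI` and singleton count `X_GIP`;
#' per group the coding length `C_G` (over all assigned genes, with or
#' without variants) and SNV count `X_G`; per impact `X_I`; and the totals
#' `X` and `X_P`. Only biallelic SNVs of a coding impact class (synonymous /
#' missense / LoF) in genes with an assigned group enter the table; variants
#' referencing unknown genes are excluded with a warning.
#'
#' @param variants variant table carrying `gene_id`, `impact`,
#'   `is_singleton` and `is_biallelic`.
#' @param genes gene table carrying `gene_id`, `coding_length` and either a
#'   `group` column or `pli` (groups are assigned on the fly).
#' @return object of class `constraint_table`: list with matrices `counts`
#'   (X_GI) and `singletons` (X_GIP), vectors `C_G`, `X_G`, `X_I`, scalars
#'   `X`, `X_P`, and `n_genes` per group.
#' @export
constraint_table <- function(variants, genes) {
  if (is.null(genes$group)) genes <- assign_constraint_groups(genes)
  v <- variants[!is.na(variants$impact) &
                  variants$impact %in% .coding_impacts &
                  variants$is_biallelic, , drop = FALSE]
  unknown <- !is.na(v$gene_id) & !(v$gene_id %in% genes$gene_id)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) referencing unknown genes excluded")
    v <- v[!unknown, , drop = FALSE]
  }
  v <- v[!is.na(v$gene_id), , drop = FALSE]
  grp <- genes$group[match(v$gene_id, genes$gene_id)]
  keep <- grp %in% .constraint_groups
  v <- v[keep, , drop = FALSE]
  grp <- factor(grp[keep], levels = .constraint_groups)
  imp <- factor(v$impact, levels = .coding_impacts)

  counts <- table(grp, imp)
  singles <- table(grp[v$is_singleton], imp[v$is_singleton])
  counts <- unclass(counts); singles <- unclass(singles)
  storage.mode(counts) <- storage.mode(singles) <- "integer"

  gk <- factor(genes$group, levels = .constraint_groups)
  C_G <- tapply(genes$coding_length, gk, sum, default = 0)
  C_G[is.na(C_G)] <- 0
  n_genes <- table(gk)

  structure(list(
    counts = counts, singletons = singles,
    C_G = as.numeric(C_G), X_G = rowSums(counts), X_I = colSums(counts),
    X = sum(counts), X_P = sum(singles),
    n_genes = as.integer(n_genes),
    groups = .constraint_groups, impacts = .coding_impacts
  ), class = "constraint_table")
}

#' @export
print.constraint_table <- function(x, ...) {
  cat("Constraint-group table:", x$X, "coding SNVs (", x$X_P, "singletons )\n")
  cat("coding kb per group:", round(x$C_G / 1000, 1), "\n")
  print(x$counts)
  invisible(x)
}

#' Observed vs expected per-kb SNV density with permutation CIs
#'
#' For each constraint group G and impact I the observed per-kb density is
#' `Y = X_GI / C_G * 1000` and the expected density under random assignment
#' of impacts to sites is `E = X_G * (X_I / X) / C_G * 1000`. The 95% CI is
#' the 2.5th/97.5th percentile of the per-kb density across `n_perm`
#' permutations in which the impact label multiset is shuffled across all
#' coding variant sites while gene (hence group) assignments stay fixed; the
#' induced cell counts are drawn with `stats::r2dtable`, which samples
#' exactly that permutation distribution (fixed group and impact margins).
#' Percent differences (observed and CI bounds) are reported on the
#' `100 * (Y - E) / E` scale.
#'
#' @param tab a [constraint_table()].
#' @param n_perm number of permutations (0 skips the CI).
#' @param seed optional integer seed for the permutation stream.
#' @return data.frame, one row per (group, impact): x (X_GI), observed,
#'   expected, pct_diff, ci_low, ci_high (density scale), pct_ci_low,
#'   pct_ci_high, perm_mean, n_perm.
#' @export
density_enrichment <- function(tab, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(tab, "constraint_table"))
  if (tab$X == 0) stop("no coding SNVs to analyse", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  C_G <- tab$C_G
  Y <- tab$counts / C_G * 1000
  E <- (tab$X_G * (tab$X_I[col(tab$counts)] / tab$X)) / C_G * 1000
  dim(E) <- dim(Y)

  out <- data.frame(
    group = rep(tab$groups, times = 3),
    impact = rep(tab$impacts, each = 3),
    x = as.vector(tab$counts),
    observed = as.vector(Y), expected = as.vector(E),
    stringsAsFactors = FALSE
  )
  out$pct_diff <- 100 * (out$observed - out$expected) / out$expected
  out$ci_low <- out$ci_high <- out$perm_mean <- NA_real_
  if (n_perm > 0) {
    perms <- r2dtable(n_perm, as.integer(tab$X_G), as.integer(tab$X_I))
    dens <- vapply(perms, function(m) as.vector(m / C_G * 1000),
                   numeric(9))                      # 9 cells x n_perm
    ci <- apply(dens, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    out$ci_low <- ci[1, ]
    out$ci_high <- ci[2, ]
    out$perm_mean <- rowMeans(dens)
    out$perm_se <- apply(dens, 1, sd) / sqrt(n_perm)
  }
  undef <- rep(C_G == 0, times = 3)
  out[undef, c("observed", "expected", "pct_diff", "ci_low", "ci_high")] <- NA_real_
  out$pct_ci_low <- 100 * (out$ci_low - out$expected) / out$expected
  out$pct_ci_high <- 100 * (out$ci_high - out$expected) / out$expected
  out$n_perm <- n_perm
  out
}

#' Observed vs expected singleton fraction with permutation CIs
#'
#' Observed `Y = X_GIP / X_GI` per (group, impact) cell; expected
#' `E = X_P / X` (identical for all cells). The null distribution shuffles
#' the singleton-status multiset across all coding sites (cell site counts
#' fixed), again sampled via `stats::r2dtable`. Cells with no SNVs are
#' reported as NA.
#'
#' @inheritParams density_enrichment
#' @return data.frame as in [density_enrichment()] with fractions in place
#'   of densities.
#' @export
singleton_enrichment <- function(tab, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(tab, "constraint_table"))
  if (tab$X == 0) stop("no coding SNVs to analyse", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  celln <- as.vector(tab$counts)
  obs <- ifelse(celln > 0, as.vector(tab$singletons) / celln, NA_real_)
  E <- tab$X_P / tab$X

  out <- data.frame(
    group = rep(tab$groups, times = 3),
    impact = rep(tab$impacts, each = 3),
    x = celln, x_singleton = as.vector(tab$singletons),
    observed = obs, expected = E, stringsAsFactors = FALSE
  )
  out$pct_diff <- 100 * (out$observed - out$expected) / out$expected
  out$ci_low <- out$ci_high <- out$perm_mean <- NA_real_
  if (n_perm > 0 && tab$X_P > 0 && tab$X_P < tab$X) {
    perms <- r2dtable(n_perm, c(tab$X_P, tab$X - tab$X_P), as.integer(celln))
    frac <- vapply(perms, function(m) ifelse(celln > 0, m[1, ] / celln, NA_real_),
                   numeric(9))
    ci <- apply(frac, 1, function(x) {
      if (all(is.na(x))) c(NA_real_, NA_real_)
      else quantile(x, probs = c(0.025, 0.975), names = FALSE)
    })
    out$ci_low <- ci[1, ]
    out$ci_high <- ci[2, ]
    out$perm_mean <- rowMeans(frac)
    out$perm_se <- apply(frac, 1, sd) / sqrt(n_perm)
  }
  out$pct_ci_low <- 100 * (out$ci_low - out$expected) / out$expected
  out$pct_ci_high <- 100 * (out$ci_high - out$expected) / out$expected
  out$n_perm <- n_perm
  out
}

#' Minor-allele-frequency spectrum by constraint group and impact
#'
#' Fractions of coding biallelic SNVs per (group, impact) falling into MAF
#' bins partitioning (0, 0.5]; optionally, singletons (allele count 1) form
#' their own leading category regardless of MAF. Within each (group, impact)
#' the fractions sum to 1.
#'
#' @param variants variant table carrying `group`, `impact`, `maf`, `ac`,
#'   `is_biallelic`.
#' @param bin_edges increasing numeric vector starting at 0 and ending at
#'   0.5; bins are left-open right-closed.
#' @param separate_singletons put AC = 1 sites in their own category.
#' @return data.frame with group, impact, bin, n and fraction.
#' @export
maf_spectrum <- function(variants, bin_edges = c(0, 0.01, 0.1, 0.5),
                         separate_singletons = TRUE) {
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 0.5)
    stop("bin_edges must increase strictly from 0 to 0.5", call. = FALSE)
  v <- variants[variants$is_biallelic & !is.na(variants$impact) &
                  variants$impact %in% .coding_impacts &
                  !is.na(variants$group) & variants$group %in% .constraint_groups, ,
                drop = FALSE]
  labs <- paste0("(", head(bin_edges, -1), ",", bin_edges[-1], "]")
  bin <- as.character(cut(v$maf, bin_edges, labels = labs))
  if (separate_singletons) {
    bin[v$ac == 1L] <- "singleton"
    labs <- c("singleton", labs)
  }
  bin <- factor(bin, levels = labs)
  grp <- factor(v$group, levels = .constraint_groups)
  imp <- factor(v$impact, levels = .coding_impacts)
  counts <- as.data.frame(table(group = grp, impact = imp, bin = bin),
                          stringsAsFactors = FALSE)
  names(counts)[4] <- "n"
  tot <- tapply(counts$n, list(counts$group, counts$impact), sum)
  counts$fraction <- counts$n / tot[cbind(counts$group, counts$impact)]
  counts
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's (with the conventional `1 + 1e-7` relative tolerance for ties).
#' The odds ratio is the sample cross-product `a*d / (b*c)`.
#'
#' @param a,b,c,d cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return list with `p_value`, `odds_ratio` (NA when undefined) and the
#'   table margins.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(list(p_value = 1, odds_ratio = NA_real_,
                margins = c(m, n, k, b + d)))
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or, margins = c(m, n, k, b + d))
}

#' Pairwise Fisher contrasts of SNV or singleton counts between groups
#'
#' In `counts` mode the 2x2 table for groups (A, B) and impact I is
#' `[[X_AI, C_A - X_AI], [X_BI, C_B - X_BI]]`: SNV sites of that impact
#' against remaining coding nucleotides. In `singletons` mode it is
#' `[[X_AIP, X_AI - X_AIP], [X_BIP, X_BI - X_BIP]]`. Significance is
#' flagged at the p < 0.05 and p < 0.001 thresholds (no multiplicity
#' correction).
#'
#' @param tab a [constraint_table()].
#' @param mode `"counts"` or `"singletons"`.
#' @return data.frame, one row per (group pair, impact), with the table
#'   cells, odds ratio, p-value and significance flags.
#' @export
fisher_contrasts <- function(tab, mode = c("counts", "singletons")) {
  stopifnot(inherits(tab, "constraint_table"))
  mode <- match.arg(mode)
  pairs <- list(c("weak", "moderate"), c("weak", "strong"), c("moderate", "strong"))
  rows <- list()
  for (pr in pairs) {
    for (imp in tab$impacts) {
      gA <- pr[1]; gB <- pr[2]
      if (mode == "counts") {
        a <- tab$counts[gA, imp]; b <- round(tab$C_G[match(gA, tab$groups)]) - a
        cc <- tab$counts[gB, imp]; d <- round(tab$C_G[match(gB, tab$groups)]) - cc
      } else {
        a <- tab$singletons[gA, imp]; b <- tab$counts[gA, imp] - a
        cc <- tab$singletons[gB, imp]; d <- tab$counts[gB, imp] - cc
      }
      ft <- fisher_exact_2x2(a, b, cc, d)
      rows[[length(rows) + 1]] <- data.frame(
        group_a = gA, group_b = gB, impact = imp,
        a = a, b = b, c = cc, d = d,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        sig_05 = ft$p_value < 0.05, sig_001 = ft$p_value < 0.001,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Prioritize loss-of-function singleton candidates in constrained genes
#'
#' Returns variants that are singletons in genes under strong constraint and
#' are annotated LoF by at least one source, flagged `concordant` when every
#' annotation source calls them LoF. When a genotype matrix is supplied the
#' carrier sample is resolved (the single sample holding the allele), and a
#' phenotype is attached if available. Candidates are sorted by concordance
#' (concordant first) then by gene pLI, descending.
#'
#' @param variants variant table with `is_singleton`, `group` and one or
#'   more `impact_<source>` columns (as from [load_sites()]).
#' @param genes gene table with `gene_id` and `pli`.
#' @param genotypes optional dosage matrix aligned to `variants`.
#' @param phenotypes optional named vector or data.frame (sample, phenotype).
#' @return data.frame of candidates.
#' @export
prioritize_candidates <- function(variants, genes, genotypes = NULL,
                                  phenotypes = NULL) {
  src_cols <- grep("^impact_", names(variants), value = TRUE)
  if (!length(src_cols)) stop("variants carry no impact_<source> columns", call. = FALSE)
  imp <- as.matrix(variants[, src_cols, drop = FALSE])
  any_lof <- rowSums(imp == "LoF", na.rm = TRUE) >= 1
  all_lof <- rowSums(imp == "LoF", na.rm = TRUE) == length(src_cols) &
    rowSums(is.na(imp)) == 0
  keep <- which(variants$is_singleton & !is.na(variants$group) &
                  variants$group == "strong" & any_lof)
  cand <- variants[keep, , drop = FALSE]
  cand$concordant <- all_lof[keep]
  cand$pli <- genes$pli[match(cand$gene_id, genes$gene_id)]

  cand$carrier <- NA_character_
  if (!is.null(genotypes) && length(keep)) {
    cand$carrier <- vapply(keep, function(i) {
      w <- which(genotypes[i, ] >= 1L)
      if (length(w) == 1) colnames(genotypes)[w] else NA_character_
    }, character(1))
  }
  if (!is.null(phenotypes)) {
    ph <- if (is.data.frame(phenotypes))
      setNames(phenotypes$phenotype, phenotypes$sample) else phenotypes
    cand$carrier_phenotype <- unname(ph[cand$carrier])
  }
  cand <- cand[order(-cand$concordant, -cand$pli), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
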