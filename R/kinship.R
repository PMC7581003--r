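#' Pairwise kinship by the KING-robust within-pair estimator
#'
#' For every pair of samples (i, j), over sites where both genotypes are
#' non-missing,
#' `phi = (N_both_het - 2 * N_opposite_hom) / (N_het_i + N_het_j)`,
#' where `N_opposite_hom` counts (hom-ref, hom-alt) and (hom-alt, hom-ref)
#' configurations. Duplicated samples give phi = 0.5, parent-offspring and
#' full-sib pairs about 0.25, and unrelated pairs about 0. The estimator
#' uses only het / opposite-homozygote configurations, so it is invariant to
#' site order and to swapping which allele is labelled alternate.
#'
#' @param genotypes sites x samples matrix of alternate-allele dosages
#'   (0/1/2, NA for missing).
#' @param min_sites pairs with fewer overlapping genotyped sites are flagged
#'   low-confidence (default 1000).
#' @return data.frame with sample_i, sample_j (i < j in column order), phi
#'   (NA when no heterozygous sites are available in the pair),
#'   n_sites_used, and low_confidence.
#' @export
kinship_matrix <- function(genotypes, min_sites = 1000) {
  G <- genotypes
  if (is.null(colnames(G))) colnames(G) <- sprintf("S%03d", seq_len(ncol(G)))
  stopifnot(ncol(G) >= 2)
  M <- !is.na(G)
  H <- (G == 1L) & M; H[!M] <- FALSE
  A0 <- (G == 0L) & M; A0[!M] <- FALSE
  A2 <- (G == 2L) & M; A2[!M] <- FALSE
  storage.mode(H) <- storage.mode(A0) <- storage.mode(A2) <- "numeric"
  Mn <- M; storage.mode(Mn) <- "numeric"

  both_het <- crossprod(H)
  opp_hom <- crossprod(A0, A2) + crossprod(A2, A0)
  het_i <- crossprod(H, Mn)           # [i, j] = het sites of i where j genotyped
  denom <- het_i + t(het_i)
  n_used <- crossprod(Mn)

  phi <- (both_het - 2 * opp_hom) / denom
  phi[denom == 0] <- NA_real_

  idx <- which(upper.tri(phi), arr.ind = TRUE)
  out <- data.frame(
    sample_i = colnames(G)[idx[, 1]],
    sample_j = colnames(G)[idx[, 2]],
    phi = phi[idx],
    n_sites_used = as.integer(n_used[idx]),
    stringsAsFactors = FALSE
  )
  out$low_confidence <- out$n_sites_used < min_sites
  out
}

#' Iteratively prune related samples
#'
#' Builds the relationship graph with an edge wherever `phi > threshold`
#' (strict inequality) and repeatedly removes the vertex of maximum degree
#' until no edge remains. Ties in degree are broken by removing the
#' lexicographically smallest sample ID, making the pruning deterministic
#' and invariant to input order.
#'
#' @param kinship data.frame from [kinship_matrix()] (needs sample_i,
#'   sample_j, phi).
#' @param threshold kinship cutoff; default 0.15 (parent-child / sibling
#'   relationships flagged above this value).
#' @return list with `retained` (sorted sample IDs) and `removed` (in
#'   removal order).
#' @export
prune_related <- function(kinship, threshold = 0.15) {
  ids <- sort(unique(c(kinship$sample_i, kinship$sample_j)))
  edges <- kinship[!is.na(kinship$phi) & kinship$phi > threshold,
                   c("sample_i", "sample_j"), drop = FALSE]
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(factor(c(edges$sample_i, edges$sample_j), levels = ids))
    worst <- sort(names(deg)[deg == max(deg)])[1]
    removed <- c(removed, worst)
    edges <- edges[edges$sample_i != worst & edges$sample_j != worst, , drop = FALSE]
  }
  list(retained = setdiff(ids, removed), removed = removed)
}

#' Write pairwise kinship estimates as TSV
#' @param kinship data.frame from [kinship_matrix()].
#' @param path file path.
#' @export
write_kinship <- function(kinship, path) {
  write.table(kinship, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
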