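#' Parse a region string like "chrB1:170786914-175975857"
#' @param x region string `chrom:start-end` (commas in numbers allowed).
#' @return list with chrom, start, end.
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", x, call. = FALSE)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Filter candidate SVs by critical region and dominant concordance
#'
#' Retains consensus SVs overlapping the critical region (by at least 1 bp)
#' that are carried by every affected discovery sample and by no unaffected
#' sample: the pattern expected of a fully penetrant autosomal dominant
#' allele in the discovery set. Adding a discordant sample can only shrink
#' the candidate set.
#'
#' @param merged consensus set from [merge_callsets()] (carriers column).
#' @param phenotypes data.frame (sample, phenotype in affected/unaffected)
#'   covering every genotyped discovery sample.
#' @param region region string or list (chrom, start, end); must be
#'   non-empty.
#' @return subset of `merged`.
#' @export
candidate_sv_filter <- function(merged, phenotypes, region) {
  if (is.character(region)) region <- parse_region(region)
  if (region$end < region$start) stop("empty region", call. = FALSE)
  affected <- phenotypes$sample[phenotypes$phenotype == "affected"]
  unaffected <- phenotypes$sample[phenotypes$phenotype == "unaffected"]
  if (!length(affected)) stop("no affected samples in the discovery set", call. = FALSE)

  in_region <- merged$chrom == region$chrom &
    merged$start <= region$end & merged$end >= region$start
  concordant <- vapply(strsplit(merged$carriers, ","), function(cc) {
    all(affected %in% cc) && !any(unaffected %in% cc)
  }, logical(1))
  out <- merged[in_region & concordant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg chi-square test on genotype counts
#'
#' Estimates the alternate allele frequency `q = (het + 2 hom_alt) / 2n`,
#' forms the expected counts `n(1-q)^2, 2nq(1-q), nq^2`, and sums
#' `(obs - exp)^2 / exp` over the three genotype classes; df = 1 (three
#' classes, one estimated frequency). No continuity correction is applied.
#' A monomorphic panel returns chi2 = 0, p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return list with counts, `allele_freq`, `chi2`, `df`, `p_value` and the
#'   expected counts.
#' @export
#' @examples
#' hwe_chisq(40, 69, 0)  # chi2 ~ 23.4, p < 0.001
hwe_chisq <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) stop("empty panel", call. = FALSE)
  q <- (n_het + 2 * n_hom_alt) / (2 * n)
  if (q == 0 || q == 1) {
    return(list(counts = c(hom_ref = n_hom_ref, het = n_het, hom_alt = n_hom_alt),
                allele_freq = q, chi2 = 0, df = 1L, p_value = 1,
                expected = c(n * (1 - q)^2, 2 * n * q * (1 - q), n * q^2)))
  }
  expected <- c(n * (1 - q)^2, 2 * n * q * (1 - q), n * q^2)
  chi2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expected)^2 / expected)
  list(counts = c(hom_ref = n_hom_ref, het = n_het, hom_alt = n_hom_alt),
       allele_freq = q, chi2 = chi2, df = 1L,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Exact binomial test for a recessive-lethal genotype ratio
#'
#' Among viable offspring of two heterozygous parents, a recessive-lethal
#' allele predicts heterozygotes and homozygous-reference offspring at a
#' 2:1 ratio. Tests the observed het count against success probability 2/3
#' with an exact two-sided binomial test; the panel is "consistent" with the
#' lethal model when p >= 0.05.
#'
#' @param n_het,n_hom_ref offspring genotype counts (hom-alt assumed
#'   inviable, so absent).
#' @return list with `p_value`, `consistent`, `expected_het` and counts.
#' @export
#' @examples
#' recessive_lethal_test(7, 4)   # consistent with 2:1
recessive_lethal_test <- function(n_het, n_hom_ref) {
  n <- n_het + n_hom_ref
  if (n <= 0) stop("no offspring", call. = FALSE)
  bt <- binom.test(n_het, n, p = 2 / 3, alternative = "two.sided")
  list(p_value = bt$p.value, consistent = bt$p.value >= 0.05,
       expected_het = 2 / 3 * n,
       counts = c(het = n_het, hom_ref = n_hom_ref))
}

#' Phenotype-genotype concordance report for a genotyping panel
#'
#' Lists unaffected carriers and affected non-carriers of a dominant
#' candidate allele, plus the phenotype-by-genotype summary table.
#' Homozygous-alternate individuals are additionally flagged as violating
#' the recessive-lethal model.
#'
#' @param panel data.frame (sample, phenotype, genotype with genotypes among
#'   `0/0`, `0/1`, `1/1`).
#' @return list with `discordant` (sample, phenotype, genotype, reason),
#'   `summary` (phenotype x genotype counts) and `n_lethal_violations`.
#' @export
concordance_report <- function(panel) {
  stopifnot(all(c("sample", "phenotype", "genotype") %in% names(panel)))
  carrier <- panel$genotype %in% c("0/1", "1/1")
  disc_unaff <- panel$phenotype == "unaffected" & carrier
  disc_aff <- panel$phenotype == "affected" & !carrier
  discordant <- rbind(
    if (any(disc_unaff)) cbind(panel[disc_unaff, ], reason = "unaffected carrier"),
    if (any(disc_aff)) cbind(panel[disc_aff, ], reason = "affected non-carrier")
  )
  if (is.null(discordant))
    discordant <- cbind(panel[0, ], reason = character(0))
  rownames(discordant) <- NULL
  list(discordant = discordant,
       summary = table(phenotype = panel$phenotype, genotype = panel$genotype),
       n_lethal_violations = sum(panel$genotype == "1/1"))
}

#' Genotype counts of a panel, in hwe_chisq() order
#' @param panel data.frame with a `genotype` column (`0/0`, `0/1`, `1/1`).
#' @return named integer vector (hom_ref, het, hom_alt).
#' @export
panel_genotype_counts <- function(panel) {
  c(hom_ref = sum(panel$genotype == "0/0"),
    het = sum(panel$genotype == "0/1"),
    hom_alt = sum(panel$genotype == "1/1"))
}
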