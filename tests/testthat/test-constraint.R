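# helper: a constraint_table built directly from cell counts
manual_table <- function(counts, singles, C_G) {
  structure(list(
    counts = counts, singletons = singles, C_G = C_G,
    X_G = rowSums(counts), X_I = colSums(counts), X = sum(counts),
    X_P = sum(singles), n_genes = c(1L, 1L, 1L),
    groups = c("weak", "moderate", "strong"),
    impacts = c("synonymous", "missense", "LoF")
  ), class = "constraint_table")
}

cellmat <- function(...) {
  matrix(c(...), 3, 3, dimnames = list(c("weak", "moderate", "strong"),
                                       c("synonymous", "missense", "LoF")))
}

test_that("pLI thresholds assign constraint groups with boundaries in moderate", {
  g <- data.frame(gene_id = letters[1:6],
                  pli = c(0.05, 0.95, 0.1, 0.9, NA, 0.5))
  out <- assign_constraint_groups(g)
  expect_equal(out$group,
               c("weak", "strong", "moderate", "moderate", "unassigned", "moderate"))
  expect_error(assign_constraint_groups(data.frame(pli = 1.2)), "0, 1")
})

test_that("tabulation aggregates counts, lengths and singletons exactly", {
  genes <- data.frame(gene_id = "g1", coding_length = 1000L, pli = 0.95)
  v <- data.frame(gene_id = "g1", impact = "synonymous",
                  is_singleton = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                  is_biallelic = TRUE)
  tab <- constraint_table(v, genes)
  expect_equal(tab$X, 5)
  expect_equal(tab$counts["strong", "synonymous"], 5L)
  expect_equal(tab$singletons["strong", "synonymous"], 2L)
  expect_equal(tab$C_G, c(0, 0, 1000))
  # empty variant table: all counts zero
  tab0 <- constraint_table(v[0, ], genes)
  expect_equal(tab0$X, 0)
  # unknown gene excluded with warning
  v2 <- rbind(v, data.frame(gene_id = "nope", impact = "LoF",
                            is_singleton = FALSE, is_biallelic = TRUE))
  expect_warning(tab2 <- constraint_table(v2, genes), "unknown gene")
  expect_equal(tab2$X, 5)
})

test_that("tabulated counts equal the generator manifest", {
  cfg <- small_config(seed = 121)
  g <- generate_genes(cfg)
  co <- generate_cohort(cfg, g)
  tab <- constraint_table(co$variants, assign_constraint_groups(g$genes))
  manifest <- table(factor(co$variants$group, tab$groups),
                    factor(co$variants$impact, tab$impacts))
  expect_equal(unclass(tab$counts), unclass(manifest), ignore_attr = TRUE)
  expect_equal(tab$X_P, sum(co$variants$is_singleton))
})

test_that("observed and expected densities follow their closed forms", {
  # Y = X_GI / C_G * 1000 and E = X_G * (X_I / X) / C_G * 1000
  counts <- cellmat(5, 10, 85, 0, 0, 0, 0, 0, 0)   # column-major fill
  tab <- manual_table(counts, counts * 0L, C_G = c(1000, 2000, 170000))
  d <- density_enrichment(tab, n_perm = 0)
  expect_equal(d$observed[d$group == "weak" & d$impact == "synonymous"], 5)
  # constructed so that X = 100, X_I(syn) = 100 -> E for moderate = X_G/C_G*1000
  expect_equal(d$expected[d$group == "moderate" & d$impact == "synonymous"],
               10 * (100 / 100) / 2000 * 1000)
  tab2 <- manual_table(cellmat(5, 55, 20, 5, 10, 5, 0, 0, 0),
                       cellmat(0, 0, 0, 0, 0, 0, 0, 0, 0),
                       C_G = c(2000, 5000, 4000))
  d2 <- density_enrichment(tab2, n_perm = 0)
  # X = 100, X_G(weak) = 10, X_I(missense) = 20, C_G = 2000: E = 1 per kb
  expect_equal(d2$expected[d2$group == "weak" & d2$impact == "missense"], 1)
})

test_that("count conservation holds: densities times lengths recover margins", {
  cfg <- small_config(seed = 131)
  co <- generate_cohort(cfg, generate_genes(cfg))
  tab <- constraint_table(co$variants,
                          assign_constraint_groups(generate_genes(cfg)$genes))
  d <- density_enrichment(tab, n_perm = 0)
  per_group <- tapply(d$observed * tab$C_G[match(d$group, tab$groups)] / 1000,
                      d$group, sum)
  expect_equal(per_group[tab$groups], tab$X_G, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("with a single populated group the expectation equals the observation", {
  counts <- cellmat(0, 0, 12, 0, 0, 30, 0, 0, 6)
  tab <- manual_table(counts, counts * 0L, C_G = c(0, 0, 9000))
  d <- density_enrichment(tab, n_perm = 0)
  strong <- d[d$group == "strong", ]
  expect_equal(strong$observed, strong$expected)
  expect_true(all(is.na(d$observed[d$group != "strong"])))
})

test_that("permutation mean matches the closed-form expected density", {
  cfg <- small_config(seed = 141)
  co <- generate_cohort(cfg, generate_genes(cfg))
  tab <- constraint_table(co$variants,
                          assign_constraint_groups(generate_genes(cfg)$genes))
  d <- density_enrichment(tab, n_perm = 2000, seed = 99)
  expect_true(all(abs(d$perm_mean - d$expected) <= 3 * d$perm_se))
  expect_true(all(d$ci_low <= d$ci_high))
})

test_that("singleton fractions follow their closed forms", {
  counts <- cellmat(12, 0, 0, 0, 0, 0, 0, 0, 0)
  singles <- cellmat(3, 0, 0, 0, 0, 0, 0, 0, 0)
  tab <- manual_table(counts, singles, C_G = c(1000, 0, 0))
  s <- singleton_enrichment(tab, n_perm = 0)
  expect_equal(s$observed[s$group == "weak" & s$impact == "synonymous"], 0.25)
  expect_equal(unique(s$expected), 3 / 12)
  # all variants singletons: every defined cell has Y = E = 1, pct_diff 0
  tab2 <- manual_table(counts, counts, C_G = c(1000, 0, 0))
  s2 <- singleton_enrichment(tab2, n_perm = 0)
  defined <- !is.na(s2$observed)
  expect_true(all(s2$observed[defined] == 1))
  expect_true(all(s2$pct_diff[defined] == 0))
})

test_that("MAF spectrum fractions are exhaustive and analytically calibrated", {
  cfg <- sim_config(n_genes = 500, n_samples = 20, seed = 151)
  co <- generate_cohort(cfg, generate_genes(cfg))
  # single bin: everything in it
  one <- maf_spectrum(co$variants, bin_edges = c(0, 0.5),
                      separate_singletons = FALSE)
  expect_true(all(one$fraction[one$n > 0] == 1))
  spec <- maf_spectrum(co$variants)
  sums <- tapply(spec$fraction, list(spec$group, spec$impact), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(maf_spectrum(co$variants, bin_edges = c(0, 0.3, 0.2, 0.5)),
               "increase")

  # analytic oracle: fold Binomial(2n, p) over the truncated Beta MAF model,
  # condition on segregation (AC >= 1), bin the folded frequency
  n2 <- 2 * cfg$n_samples
  s1 <- cfg$maf_model$shape1; s2 <- cfg$maf_model$shape2
  norm <- pbeta(0.5, s1, s2)
  pk <- vapply(0:n2, function(k) {
    integrate(function(p) dbinom(k, n2, p) * dbeta(p, s1, s2) / norm,
              0, 0.5, rel.tol = 1e-9)$value
  }, numeric(1))
  pk <- pk[-1] / sum(pk[-1])            # condition on AC >= 1
  folded <- pmin(1:n2, n2 - 1:n2) / n2
  edges <- c(0, 0.01, 0.1, 0.5)
  bin_of <- cut(folded, edges)
  expected_frac <- tapply(pk, bin_of, sum)
  expected_frac[is.na(expected_frac)] <- 0   # bins below the attainable 1/2n
  whole <- maf_spectrum(co$variants, separate_singletons = FALSE)
  obs_frac <- tapply(whole$n, whole$bin, sum) / sum(whole$n)
  n_tot <- sum(whole$n)
  for (b in seq_along(expected_frac)) {
    se <- sqrt(expected_frac[b] * (1 - expected_frac[b]) / n_tot)
    expect_lt(abs(obs_frac[b] - expected_frac[b]), 3 * se + 1e-12)
  }

  # a singleton in a 54-sample cohort has MAF 1/108 < 1%
  v54 <- data.frame(group = "weak", impact = "synonymous", ac = 1L,
                    an = 108L, maf = 1 / 108, is_biallelic = TRUE)
  sp54 <- maf_spectrum(v54, separate_singletons = FALSE)
  expect_equal(sp54$n[sp54$bin == "(0,0.01]" & sp54$group == "weak" &
                        sp54$impact == "synonymous"], 1)
})

test_that("Fisher exact odds ratios and p-values follow the hypergeometric rule", {
  expect_equal(fisher_exact_2x2(2, 8, 8, 2)$odds_ratio, 0.0625)
  r <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_value, 1)
  expect_true(is.na(fisher_exact_2x2(0, 0, 3, 4)$odds_ratio))
  # independent oracle + stats::fisher.test agreement on random tables
  set.seed(42)
  for (i in 1:60) {
    tb <- matrix(rpois(4, 8), 2)
    r <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(r$p_value,
                 fisher_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-9)
    expect_equal(r$p_value, stats::fisher.test(tb)$p.value, tolerance = 1e-6)
  }
})

test_that("Fisher p and OR are invariant to simultaneous row and column swaps", {
  set.seed(43)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    r1 <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    r2 <- fisher_exact_2x2(tb[2, 2], tb[2, 1], tb[1, 2], tb[1, 1])
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$odds_ratio, r2$odds_ratio)
  }
})

test_that("pairwise contrasts build the tables the two modes define", {
  counts <- cellmat(20, 10, 5, 8, 4, 2, 3, 2, 1)
  singles <- cellmat(5, 2, 1, 2, 1, 1, 1, 1, 0)
  tab <- manual_table(counts, singles, C_G = c(10000, 6000, 3000))
  fc <- fisher_contrasts(tab, "counts")
  row <- fc[fc$group_a == "weak" & fc$group_b == "strong" &
              fc$impact == "synonymous", ]
  expect_equal(row$a, 20)
  expect_equal(row$b, 10000 - 20)
  expect_equal(row$c, 5)
  expect_equal(row$d, 3000 - 5)
  fs <- fisher_contrasts(tab, "singletons")
  row2 <- fs[fs$group_a == "moderate" & fs$group_b == "strong" &
               fs$impact == "missense", ]
  expect_equal(unlist(row2[c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 3, 1, 1))
  expect_equal(nrow(fc), 9)
})

test_that("LoF singleton candidates are gated on group, singleton state and sources", {
  genes <- data.frame(gene_id = c("g1", "g2"), pli = c(0.95, 0.5))
  v <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    gene_id = c("g1", "g2", "g1", "g1"),
    group = c("strong", "moderate", "strong", "strong"),
    is_singleton = c(TRUE, TRUE, TRUE, FALSE),
    impact_ensembl_like = c("LoF", "LoF", "LoF", "LoF"),
    impact_ncbi_like = c("LoF", "LoF", "missense", "LoF"),
    stringsAsFactors = FALSE
  )
  cand <- prioritize_candidates(v, genes)
  expect_equal(sort(cand$variant_id), c("v1", "v3"))   # v2 wrong group, v4 not singleton
  expect_true(cand$concordant[cand$variant_id == "v1"])
  expect_false(cand$concordant[cand$variant_id == "v3"])
  expect_equal(cand$variant_id[1], "v1")               # concordant sorts first
})

test_that("planted concordant candidates are all recovered from a cohort", {
  cfg <- small_config(seed = 161)
  g <- generate_genes(cfg)
  co <- generate_cohort(cfg, g)
  wide <- co$variants
  imp2 <- co$impacts[co$impacts$source == "ncbi_like", ]
  wide$impact_ensembl_like <- wide$impact
  wide$impact_ncbi_like <- imp2$impact[match(wide$variant_id, imp2$variant_id)]
  cand <- prioritize_candidates(wide, g$genes, co$genotypes)
  truth <- wide$is_singleton & wide$group == "strong" &
    (wide$impact_ensembl_like == "LoF" | wide$impact_ncbi_like == "LoF")
  expect_equal(nrow(cand), sum(truth))
  expect_equal(sum(cand$concordant),
               sum(wide$is_singleton & wide$group == "strong" &
                     wide$impact_ensembl_like == "LoF" &
                     wide$impact_ncbi_like == "LoF"))
  # every singleton's carrier is resolvable
  expect_false(any(is.na(cand$carrier)))
})
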