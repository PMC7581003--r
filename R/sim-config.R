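#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every tunable of the synthetic-data generators.
#' Defaults emulate a small, diverse resequencing cohort: gene constraint
#' groups in the proportions of a typical pLI-annotated ortholog set
#' (weak/moderate/strong = 0.620/0.197/0.183), lognormal coding lengths with a
#' ~1.5 kb median, a rare-skewed Beta(0.3, 3) allele-frequency model truncated
#' to (0, 0.5], and a transition probability of 0.709 (Ts/Tv of about 2.44).
#' Per-impact baseline densities are per-cohort SNVs per coding kb; the LoF
#' rate is set high enough that every group-by-impact cell is populated in
#' cohorts of a few hundred to a few thousand genes.
#'
#' `depletion_multiplier` and `singleton_enrichment` are 3x3 matrices
#' (rows: weak/moderate/strong; columns: synonymous/missense/LoF) of positive
#' factors applied, respectively, to the Poisson SNV rate and to the
#' singleton probability of each cell. They may also be given as a named
#' vector like `c("strong:LoF" = 0.5)`; unnamed cells default to 1.
#'
#' @param n_genes number of genes to simulate.
#' @param group_proportions fractions of genes in the weak/moderate/strong
#'   constraint groups; must sum to 1 (within 1e-9).
#' @param coding_length_model list with `dist = "lognormal"` (`meanlog`,
#'   `sdlog`) or `dist = "constant"` (`length`), in bp.
#' @param n_samples number of diploid samples in the cohort.
#' @param baseline_density named per-impact SNVs per kb of coding sequence.
#' @param depletion_multiplier,singleton_enrichment positive multipliers per
#'   (constraint group, impact); see Details.
#' @param maf_model list with `dist = "beta"` (`shape1`, `shape2`), truncated
#'   to (0, 0.5], or `dist = "uniform"` (`min`, `max` within (0, 0.5]).
#' @param transition_prob probability a simulated SNV is a transition.
#' @param annotation_concordance probability the second simulated annotation
#'   source agrees with the first (true) impact.
#' @param n_svs number of true structural variants to simulate.
#' @param sv_type_probs named sampling weights over DEL/DUP/INS/INV.
#' @param sv_size_range span-type (DEL/DUP/INV) size range, bp.
#' @param ins_size_range inserted-sequence length range for INS, bp.
#' @param sv_carrier_model Beta parameters for the per-SV carrier frequency.
#' @param sv_jitter list with `breakpoint` (half-width, bp), `size`
#'   (half-width, bp) and `dropout` (per-caller miss probability). A
#'   breakpoint jitter of 50 bp or more is allowed but flagged with a
#'   warning, since two independently jittered calls are then no longer
#'   guaranteed to fall within the 50 bp merge window.
#' @param seed integer seed; identical configurations (including seed) give
#'   byte-identical generator output.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_samples = 8, seed = 42)
#' genes <- generate_genes(cfg)
sim_config <- function(n_genes = 500,
                       group_proportions = c(weak = 0.620, moderate = 0.197, strong = 0.183),
                       coding_length_model = list(dist = "lognormal", meanlog = log(1500), sdlog = 0.5),
                       n_samples = 20,
                       baseline_density = c(synonymous = 6, missense = 3.5, LoF = 0.3),
                       depletion_multiplier = NULL,
                       singleton_enrichment = NULL,
                       maf_model = list(dist = "beta", shape1 = 0.3, shape2 = 3),
                       transition_prob = 0.709,
                       annotation_concordance = 0.9,
                       n_svs = 300,
                       sv_type_probs = c(DEL = 0.6, DUP = 0.15, INS = 0.15, INV = 0.1),
                       sv_size_range = c(1000, 10000),
                       ins_size_range = c(50, 500),
                       sv_carrier_model = list(shape1 = 0.4, shape2 = 2),
                       sv_jitter = list(breakpoint = 25, size = 250, dropout = 0.1),
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1, n_svs >= 0)
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1", call. = FALSE)
  if (any(group_proportions < 0)) stop("group_proportions must be non-negative", call. = FALSE)
  if (is.null(names(group_proportions))) names(group_proportions) <- .constraint_groups

  if (!all(.coding_impacts %in% names(baseline_density)))
    stop("baseline_density needs entries for synonymous, missense and LoF", call. = FALSE)
  if (any(baseline_density < 0)) stop("baseline_density must be non-negative", call. = FALSE)

  depletion_multiplier <- as_multiplier_matrix(depletion_multiplier, "depletion_multiplier")
  singleton_enrichment <- as_multiplier_matrix(singleton_enrichment, "singleton_enrichment")

  .check_length_model(coding_length_model)
  .check_maf_model(maf_model)
  stopifnot(transition_prob >= 0, transition_prob <= 1,
            annotation_concordance >= 0, annotation_concordance <= 1)
  stopifnot(length(sv_size_range) == 2, sv_size_range[1] <= sv_size_range[2],
            length(ins_size_range) == 2, ins_size_range[1] <= ins_size_range[2])
  if (!all(c("breakpoint", "size", "dropout") %in% names(sv_jitter)))
    stop("sv_jitter needs breakpoint, size and dropout", call. = FALSE)
  if (sv_jitter$breakpoint >= 50)
    warning("breakpoint jitter >= 50 bp: dual-caller merge recovery is no longer guaranteed")
  if (sv_jitter$dropout < 0 || sv_jitter$dropout > 1)
    stop("sv_jitter$dropout must be in [0, 1]", call. = FALSE)

  structure(list(
    n_genes = as.integer(n_genes),
    group_proportions = group_proportions,
    coding_length_model = coding_length_model,
    n_samples = as.integer(n_samples),
    baseline_density = baseline_density[.coding_impacts],
    depletion_multiplier = depletion_multiplier,
    singleton_enrichment = singleton_enrichment,
    maf_model = maf_model,
    transition_prob = transition_prob,
    annotation_concordance = annotation_concordance,
    n_svs = as.integer(n_svs),
    sv_type_probs = sv_type_probs,
    sv_size_range = sv_size_range,
    ins_size_range = ins_size_range,
    sv_carrier_model = sv_carrier_model,
    sv_jitter = sv_jitter,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Normalise a (group, impact) multiplier specification to a 3x3 matrix
#'
#' @param x `NULL` (all ones), a full 3x3 matrix, or a named vector with
#'   names of the form `"group:impact"` (e.g. `"strong:LoF"`).
#' @param what label used in error messages.
#' @return 3x3 numeric matrix, rows weak/moderate/strong, columns
#'   synonymous/missense/LoF.
#' @export
as_multiplier_matrix <- function(x, what = "multiplier") {
  m <- matrix(1, 3, 3, dimnames = list(.constraint_groups, .coding_impacts))
  if (is.null(x)) return(m)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3, 3))) stop(what, " matrix must be 3x3", call. = FALSE)
    m[] <- x
    if (!is.null(rownames(x))) m <- x[.constraint_groups, .coding_impacts]
  } else {
    if (is.null(names(x))) stop(what, " vector must be named 'group:impact'", call. = FALSE)
    parts <- strsplit(names(x), ":", fixed = TRUE)
    for (i in seq_along(x)) {
      g <- parts[[i]][1]; imp <- parts[[i]][2]
      if (!(g %in% .constraint_groups) || !(imp %in% .coding_impacts))
        stop(what, ": unknown cell '", names(x)[i], "'", call. = FALSE)
      m[g, imp] <- x[i]
    }
  }
  if (any(!is.finite(m)) || any(m <= 0))
    stop(what, " values must be positive and finite", call. = FALSE)
  m
}

.check_length_model <- function(m) {
  if (identical(m$dist, "constant")) {
    if (is.null(m$length) || m$length <= 0) stop("constant length model needs length > 0", call. = FALSE)
  } else if (identical(m$dist, "lognormal")) {
    if (is.null(m$meanlog) || is.null(m$sdlog) || m$sdlog < 0)
      stop("lognormal length model needs meanlog and sdlog >= 0", call. = FALSE)
  } else stop("unknown coding_length_model dist: ", m$dist, call. = FALSE)
  invisible(m)
}

.check_maf_model <- function(m) {
  if (identical(m$dist, "beta")) {
    if (is.null(m$shape1) || is.null(m$shape2) || m$shape1 <= 0 || m$shape2 <= 0)
      stop("beta maf model needs positive shape1/shape2", call. = FALSE)
  } else if (identical(m$dist, "uniform")) {
    if (is.null(m$min) || is.null(m$max) || m$min <= 0 || m$max > 0.5 || m$min > m$max)
      stop("uniform maf model needs 0 < min <= max <= 0.5", call. = FALSE)
  } else stop("unknown maf_model dist: ", m$dist, call. = FALSE)
  invisible(m)
}

# draw n population allele frequencies on (0, 0.5]
.draw_maf <- function(n, model) {
  if (n == 0) return(numeric(0))
  if (model$dist == "uniform") return(runif(n, model$min, model$max))
  p <- rbeta(n, model$shape1, model$shape2)
  bad <- which(p > 0.5 | p <= 0)
  while (length(bad)) {
    p[bad] <- rbeta(length(bad), model$shape1, model$shape2)
    bad <- bad[p[bad] > 0.5 | p[bad] <= 0]
  }
  p
}
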