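# shared fixtures and independent oracles for the test suite

small_config <- function(seed = 11, ...) {
  sim_config(n_genes = 120, n_samples = 10, n_svs = 120, seed = seed, ...)
}

# hand-written minimal VCF used by the ingestion tests
write_mini_vcf <- function(path, rows, samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

# gene-drop simulation: genotypes for unrelated / parent-offspring /
# full-sib pairs under HWE (independent of the package's estimator)
gene_drop_pair <- function(n_sites, relation, p = runif(n_sites, 0.1, 0.5)) {
  draw_geno <- function(h1, h2) h1 + h2
  h <- function() rbinom(n_sites, 1, p)
  if (relation == "unrelated") {
    g1 <- draw_geno(h(), h()); g2 <- draw_geno(h(), h())
  } else if (relation == "parent_offspring") {
    m1 <- h(); m2 <- h()               # parent haplotypes
    g1 <- draw_geno(m1, m2)
    transmit <- ifelse(rbinom(n_sites, 1, 0.5) == 1, m1, m2)
    g2 <- draw_geno(transmit, h())
  } else if (relation == "full_sibs") {
    m1 <- h(); m2 <- h(); f1 <- h(); f2 <- h()
    pick <- function(a, b) ifelse(rbinom(n_sites, 1, 0.5) == 1, a, b)
    g1 <- draw_geno(pick(m1, m2), pick(f1, f2))
    g2 <- draw_geno(pick(m1, m2), pick(f1, f2))
  } else stop("unknown relation")
  cbind(A = g1, B = g2)
}

# brute-force two-sided Fisher p by enumerating all tables with the observed
# margins, probabilities from log-binomial coefficients (independent of
# dhyper-based implementation)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[match(a, xs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# brute-force all-pairs SV merge partner selection (oracle for the
# windowed implementation); returns matched index pairs into a and b
merge_oracle_pairs <- function(a, b, breakpoint_tol = 50, size_tol = 500,
                               reciprocal = 0.5) {
  cand <- NULL
  for (ia in seq_len(nrow(a))) {
    for (ib in seq_len(nrow(b))) {
      if (a$chrom[ia] != b$chrom[ib]) next
      if (a$type[ia] != b$type[ib] || a$type[ia] == "INS") next
      if (abs(a$start[ia] - b$start[ib]) > breakpoint_tol) next
      if (abs(a$size[ia] - b$size[ib]) > size_tol) next
      if (a$type[ia] == "INV" && a$strand[ia] != b$strand[ib]) next
      ov <- min(a$end[ia], b$end[ib]) - max(a$start[ia], b$start[ib]) + 1
      if (ov < reciprocal * (a$end[ia] - a$start[ia] + 1)) next
      if (ov < reciprocal * (b$end[ib] - b$start[ib] + 1)) next
      cand <- rbind(cand, data.frame(
        ia = ia, ib = ib, dstart = abs(a$start[ia] - b$start[ib]),
        dsize = abs(a$size[ia] - b$size[ib])))
    }
  }
  out <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$dstart, cand$dsize, cand$ia, cand$ib), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (r in seq_len(nrow(cand))) {
      if (!used_a[cand$ia[r]] && !used_b[cand$ib[r]]) {
        used_a[cand$ia[r]] <- used_b[cand$ib[r]] <- TRUE
        out <- rbind(out, cand[r, c("ia", "ib")])
      }
    }
  }
  out
}

# vectorized all-pairs variant of the merge oracle (for large call sets):
# same matching rule, candidate pairs found by exhaustive outer comparison
merge_oracle_pairs_fast <- function(a, b, breakpoint_tol = 50, size_tol = 500,
                                    reciprocal = 0.5) {
  na <- nrow(a); nb <- nrow(b)
  if (!na || !nb) return(NULL)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  ok <- a$chrom[ia] == b$chrom[ib] & a$type[ia] == b$type[ib] &
    a$type[ia] != "INS" &
    abs(a$start[ia] - b$start[ib]) <= breakpoint_tol &
    abs(a$size[ia] - b$size[ib]) <= size_tol &
    (a$type[ia] != "INV" | a$strand[ia] == b$strand[ib])
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]) + 1
  ok <- ok & ov >= reciprocal * (a$end[ia] - a$start[ia] + 1) &
    ov >= reciprocal * (b$end[ib] - b$start[ib] + 1)
  cand <- data.frame(ia = ia[ok], ib = ib[ok],
                     dstart = abs(a$start[ia[ok]] - b$start[ib[ok]]),
                     dsize = abs(a$size[ia[ok]] - b$size[ib[ok]]))
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand$dstart, cand$dsize, cand$ia, cand$ib), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb); out <- NULL
  for (r in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[r]] && !used_b[cand$ib[r]]) {
      used_a[cand$ia[r]] <- used_b[cand$ib[r]] <- TRUE
      out <- rbind(out, cand[r, c("ia", "ib")])
    }
  }
  out
}

# random span-only call sets for merge equivalence testing
random_callsets <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE)
  start <- sort(sample.int(5e6, n))
  size <- sample(900:8000, n, replace = TRUE)
  mk <- function(caller) {
    keep <- runif(n) < 0.9
    st <- start + sample(-40:40, n, replace = TRUE)
    sz <- size + sample(-300:300, n, replace = TRUE)
    df <- data.frame(caller = caller, chrom = "chr1", start = st,
                     end = st + sz - 1L, type = types,
                     strand = ifelse(types == "INV",
                                     sample(c("++", "--"), n, replace = TRUE), "."),
                     size = sz, carriers = "S001", stringsAsFactors = FALSE)
    df <- df[keep, , drop = FALSE]
    df[order(df$chrom, df$start), , drop = FALSE]
  }
  list(a = mk("callerA"), b = mk("callerB"))
}
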