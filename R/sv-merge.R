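#' Merge two structural-variant call sets into a consensus set
#'
#' Two span-type calls (DEL/DUP/INV) merge iff they are on the same
#' chromosome, of the same type, with compatible strand (enforced literally
#' for inversions, vacuous for DEL/DUP), start positions within
#' `breakpoint_tol` (50 bp), sizes within `size_tol` (500 bp) and, when
#' `require_reciprocal` is TRUE, reciprocal overlap of at least
#' `reciprocal` (50%) of each span. Matching is one-to-one: candidate pairs
#' are ranked by smallest start distance, ties by smallest size difference,
#' and assigned greedily. Insertions are taken only from the designated
#' authoritative caller (short-insertion resolution differs strongly
#' between callers) and retained only when carried by more than two
#' individuals. Unmerged span-type calls are retained and tagged
#' single-caller. Consensus breakpoints come from the designated primary
#' caller when it supports the merge, otherwise from the other caller;
#' genotypes are the per-sample union of carriers.
#'
#' @param callset_a,callset_b call-set data frames (columns chrom, start,
#'   end, type, strand, size, carriers, caller), each sorted by
#'   (chrom, start).
#' @param ins_authority caller name whose insertion calls are authoritative;
#'   defaults to the caller of `callset_b`. Also the primary caller for
#'   consensus breakpoints.
#' @param breakpoint_tol,size_tol,reciprocal merge thresholds.
#' @param require_reciprocal require the reciprocal-overlap criterion in
#'   addition to the proximity/size criteria (default TRUE).
#' @param min_ins_carriers minimum carrier count for retained insertions
#'   (default 3, i.e. "more than 2 individuals").
#' @return data.frame of consensus SVs sorted by (chrom, start): chrom,
#'   start, end, type, strand, size, callers (comma-joined), n_callers,
#'   single_caller flag, carriers, n_carriers.
#' @export
merge_callsets <- function(callset_a, callset_b, ins_authority = NULL,
                           breakpoint_tol = 50, size_tol = 500,
                           reciprocal = 0.5, require_reciprocal = TRUE,
                           min_ins_carriers = 3) {
  .check_callset(callset_a, "callset_a")
  .check_callset(callset_b, "callset_b")
  caller_a <- if (nrow(callset_a)) callset_a$caller[1] else "caller_a"
  caller_b <- if (nrow(callset_b)) callset_b$caller[1] else "caller_b"
  if (is.null(ins_authority)) ins_authority <- caller_b
  primary <- ins_authority

  span_a <- callset_a[callset_a$type != "INS", , drop = FALSE]
  span_b <- callset_b[callset_b$type != "INS", , drop = FALSE]

  pairs <- .candidate_pairs(span_a, span_b, breakpoint_tol, size_tol,
                            reciprocal, require_reciprocal)
  used_a <- logical(nrow(span_a)); used_b <- logical(nrow(span_b))
  match_a <- integer(0); match_b <- integer(0)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$dstart, pairs$dsize, pairs$ia, pairs$ib), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      ia <- pairs$ia[r]; ib <- pairs$ib[r]
      if (!used_a[ia] && !used_b[ib]) {
        used_a[ia] <- used_b[ib] <- TRUE
        match_a <- c(match_a, ia); match_b <- c(match_b, ib)
      }
    }
  }

  union_carriers <- function(x, y) {
    paste(sort(unique(c(strsplit(x, ",")[[1]], strsplit(y, ",")[[1]]))),
          collapse = ",")
  }
  merged <- NULL
  if (length(match_a)) {
    keep_from <- if (primary == caller_b) span_b[match_b, , drop = FALSE]
      else span_a[match_a, , drop = FALSE]
    merged <- data.frame(
      chrom = keep_from$chrom, start = keep_from$start, end = keep_from$end,
      type = keep_from$type, strand = keep_from$strand, size = keep_from$size,
      callers = paste(caller_a, caller_b, sep = ","), n_callers = 2L,
      single_caller = FALSE,
      carriers = mapply(union_carriers, span_a$carriers[match_a],
                        span_b$carriers[match_b], USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  singles <- rbind(
    .as_consensus(span_a[!used_a, , drop = FALSE], caller_a),
    .as_consensus(span_b[!used_b, , drop = FALSE], caller_b)
  )

  ins <- if (ins_authority == caller_b) callset_b else callset_a
  ins <- ins[ins$type == "INS", , drop = FALSE]
  if (nrow(ins)) {
    n_car <- vapply(strsplit(ins$carriers, ","), length, integer(1))
    ins <- ins[n_car >= min_ins_carriers, , drop = FALSE]
  }
  ins_rows <- .as_consensus(ins, ins_authority)
  if (!is.null(ins_rows) && nrow(ins_rows)) ins_rows$single_caller <- FALSE

  out <- rbind(merged, singles, ins_rows)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      type = character(0), strand = character(0), size = integer(0),
                      callers = character(0), n_callers = integer(0),
                      single_caller = logical(0), carriers = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE))
  }
  out$n_carriers <- vapply(strsplit(out$carriers, ","), length, integer(1))
  out <- out[order(out$chrom, out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_callset <- function(cs, what) {
  need <- c("caller", "chrom", "start", "end", "type", "strand", "size", "carriers")
  if (!all(need %in% names(cs)))
    stop(what, " must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(cs$type), c("DEL", "DUP", "INS", "INV"))
  if (length(bad)) stop(what, ": unknown SV type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(cs) > 1) {
    split_start <- split(cs$start, cs$chrom)
    if (any(vapply(split_start, is.unsorted, logical(1))))
      stop(what, " must be sorted by (chrom, start)", call. = FALSE)
  }
  invisible(cs)
}

# all pairs satisfying the merge criteria, with their distances
.candidate_pairs <- function(a, b, breakpoint_tol, size_tol, reciprocal,
                             require_reciprocal) {
  empty <- data.frame(ia = integer(0), ib = integer(0),
                      dstart = integer(0), dsize = integer(0))
  if (!nrow(a) || !nrow(b)) return(empty)
  res <- vector("list", nrow(a))
  for (ia in seq_len(nrow(a))) {
    cand <- which(b$chrom == a$chrom[ia] & b$type == a$type[ia] &
                    abs(b$start - a$start[ia]) <= breakpoint_tol)
    if (!length(cand)) next
    ok <- abs(b$size[cand] - a$size[ia]) <= size_tol
    if (a$type[ia] == "INV") ok <- ok & (b$strand[cand] == a$strand[ia])
    if (require_reciprocal) {
      ov <- pmin(b$end[cand], a$end[ia]) - pmax(b$start[cand], a$start[ia]) + 1
      len_a <- a$end[ia] - a$start[ia] + 1
      len_b <- b$end[cand] - b$start[cand] + 1
      ok <- ok & ov >= reciprocal * len_a & ov >= reciprocal * len_b
    }
    cand <- cand[ok]
    if (length(cand)) {
      res[[ia]] <- data.frame(ia = ia, ib = cand,
                              dstart = abs(b$start[cand] - a$start[ia]),
                              dsize = abs(b$size[cand] - a$size[ia]))
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) empty else out
}

.as_consensus <- function(cs, caller) {
  if (is.null(cs) || nrow(cs) == 0) return(NULL)
  data.frame(chrom = cs$chrom, start = cs$start, end = cs$end, type = cs$type,
             strand = cs$strand, size = cs$size, callers = caller,
             n_callers = 1L, single_caller = TRUE, carriers = cs$carriers,
             stringsAsFactors = FALSE)
}

#' Population-frequency spectrum of a consensus SV set
#'
#' Population frequency is the fraction of samples carrying at least one
#' alternate allele. Per SV type, the fraction of SVs in each frequency bin
#' is reported (bins are left-open right-closed and sum to 1 per type);
#' SVs above `high_freq_cutoff` are flagged as likely reference-minor sites.
#'
#' @param merged consensus set from [merge_callsets()].
#' @param n_samples number of genotyped samples (> 0).
#' @param bin_edges frequency bin edges covering (0, 1].
#' @param high_freq_cutoff flag threshold (default 0.9).
#' @return list with `sv` (input + frequency + high_frequency flag) and
#'   `spectrum` (type, bin, n, fraction).
#' @export
sv_frequency_spectrum <- function(merged, n_samples,
                                  bin_edges = c(0, 0.02, 0.1, 0.5, 1),
                                  high_freq_cutoff = 0.9) {
  if (n_samples <= 0) stop("n_samples must be positive", call. = FALSE)
  merged$frequency <- merged$n_carriers / n_samples
  merged$high_frequency <- merged$frequency > high_freq_cutoff
  labs <- paste0("(", head(bin_edges, -1), ",", bin_edges[-1], "]")
  bin <- cut(merged$frequency, bin_edges, labels = labs)
  spec <- as.data.frame(table(type = merged$type, bin = bin),
                        stringsAsFactors = FALSE)
  names(spec)[3] <- "n"
  tot <- tapply(spec$n, spec$type, sum)
  spec$fraction <- spec$n / tot[spec$type]
  list(sv = merged, spectrum = spec)
}

#' Annotate consensus SVs with genomic region labels
#'
#' Each SV receives every label whose region it overlaps by at least 1 bp
#' (multi-labelling allowed): `exonic`, `intronic` (gene body minus exons),
#' `5kb_upstream` / `5kb_downstream` (strand-aware gene flanks), optional
#' `utr5` / `utr3` when UTR features are supplied, and `intergenic` iff the
#' SV overlaps no gene body and no flank. SVs on chromosomes absent from
#' the gene models are labelled intergenic with a warning.
#'
#' @param merged consensus set from [merge_callsets()].
#' @param genes gene table (gene_id, chrom, start, end, strand).
#' @param exons exon table (gene_id, chrom, start, end).
#' @param utr5,utr3 optional feature tables (chrom, start, end).
#' @param flank flank width in bp (default 5000).
#' @return `merged` with logical label columns and a `region_labels`
#'   comma-joined summary column.
#' @export
annotate_sv_regions <- function(merged, genes, exons, utr5 = NULL, utr3 = NULL,
                                flank = 5000) {
  orphan <- !(merged$chrom %in% genes$chrom)
  if (any(orphan))
    warning(sum(orphan), " SV(s) on chromosomes absent from the gene models; ",
            "labelled intergenic")
  all_chroms <- unique(c(merged$chrom, genes$chrom))
  gr <- function(df) GenomicRanges::GRanges(
    factor(df$chrom, levels = all_chroms),
    IRanges::IRanges(df$start, df$end))

  sv_gr <- gr(merged)
  gene_gr <- gr(genes)
  exon_gr <- gr(exons)
  intron_gr <- GenomicRanges::setdiff(GenomicRanges::reduce(gene_gr),
                                      GenomicRanges::reduce(exon_gr))
  stranded <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = all_chroms),
    IRanges::IRanges(genes$start, genes$end), strand = genes$strand)
  up_gr <- GenomicRanges::flank(stranded, flank, start = TRUE)
  up_gr <- GenomicRanges::trim(up_gr)
  down_gr <- GenomicRanges::flank(stranded, flank, start = FALSE)
  down_gr <- GenomicRanges::trim(down_gr)

  merged$exonic <- IRanges::overlapsAny(sv_gr, exon_gr)
  merged$intronic <- IRanges::overlapsAny(sv_gr, intron_gr)
  merged$`5kb_upstream` <- IRanges::overlapsAny(sv_gr, up_gr, ignore.strand = TRUE)
  merged$`5kb_downstream` <- IRanges::overlapsAny(sv_gr, down_gr, ignore.strand = TRUE)
  if (!is.null(utr5)) merged$utr5 <- IRanges::overlapsAny(sv_gr, gr(utr5))
  if (!is.null(utr3)) merged$utr3 <- IRanges::overlapsAny(sv_gr, gr(utr3))
  in_gene <- IRanges::overlapsAny(sv_gr, gene_gr)
  merged$intergenic <- !in_gene & !merged$`5kb_upstream` & !merged$`5kb_downstream`

  label_cols <- intersect(c("intergenic", "intronic", "exonic", "5kb_upstream",
                            "5kb_downstream", "utr5", "utr3"), names(merged))
  merged$region_labels <- apply(as.matrix(merged[, label_cols, drop = FALSE]), 1,
                                function(r) paste(label_cols[r], collapse = ","))
  merged
}

#' Per-sample SV burden, per-type sizes and cohort comparison
#'
#' Counts consensus SVs carried by each sample, summarizes sizes per SV
#' type, and (when two cohort labels are given) compares per-sample SV
#' counts between cohorts with a Welch two-sample t-test. Cohorts with
#' fewer than two samples skip the test with a warning.
#'
#' @param merged consensus set from [merge_callsets()].
#' @param sample_ids all genotyped samples (so zero-carriers are reported).
#' @param cohort_labels optional named vector of two-level labels.
#' @return list with `per_sample`, `size_summary` and `t_test` (NULL when
#'   not performed).
#' @export
cohort_sv_stats <- function(merged, sample_ids, cohort_labels = NULL) {
  car_list <- strsplit(merged$carriers, ",")
  counts <- table(factor(unlist(car_list), levels = sample_ids))
  per_sample <- data.frame(sample_id = sample_ids,
                           n_svs = as.integer(counts),
                           stringsAsFactors = FALSE)
  size_summary <- if (nrow(merged) == 0) {
    data.frame(type = character(0), mean_size = numeric(0), n = integer(0))
  } else {
    agg <- aggregate(size ~ type, data = merged,
                     FUN = function(x) c(mean = mean(x), n = length(x)))
    data.frame(type = agg$type, mean_size = agg$size[, "mean"],
               n = as.integer(agg$size[, "n"]))
  }
  t_test <- NULL
  if (!is.null(cohort_labels)) {
    lab <- unname(cohort_labels[per_sample$sample_id])
    groups <- split(per_sample$n_svs, lab)
    if (length(groups) == 2 && all(lengths(groups) >= 2)) {
      tt <- t.test(groups[[1]], groups[[2]])
      t_test <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                     means = vapply(groups, mean, numeric(1)))
    } else warning("cohort comparison skipped: need two cohorts of >= 2 samples")
  }
  list(per_sample = per_sample, size_summary = size_summary, t_test = t_test)
}
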