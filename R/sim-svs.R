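#' Simulate jittered dual-caller structural-variant call sets
#'
#' Places `n_svs` non-overlapping true SVs (DEL/DUP/INS/INV) on synthetic
#' chromosomes with per-sample carrier status, then has two emulated callers
#' ("lumpy_like" and "delly_like") each report every true SV with probability
#' `1 - dropout`, with breakpoints perturbed uniformly within the breakpoint
#' jitter half-width and sizes within the size jitter half-width. True SVs
#' are spaced at least 2 kb apart so calls of different origin can never fall
#' inside the 50 bp merge window. The truth table records which reported
#' calls share an origin.
#'
#' @param config a [sim_config()] object.
#' @return list with `callset_a` (lumpy_like), `callset_b` (delly_like),
#'   both sorted by (chrom, start), and `truth` (one row per true SV with
#'   reported-by flags). Call set columns: call_id, caller, sv_id, chrom,
#'   start, end, type, strand, size, carriers (comma-separated sample IDs).
#' @export
generate_dual_caller_svs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_svs
  ns <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))

  type <- sample(names(config$sv_type_probs), n, replace = TRUE,
                 prob = config$sv_type_probs)
  span <- type != "INS"
  size <- integer(n)
  size[span] <- as.integer(round(runif(sum(span), config$sv_size_range[1],
                                       config$sv_size_range[2])))
  size[!span] <- as.integer(round(runif(sum(!span), config$ins_size_range[1],
                                        config$ins_size_range[2])))

  n_chrom <- max(1L, min(4L, n %/% 50L + 1L))
  chrom <- sprintf("chr%d", rep_len(seq_len(n_chrom), n))
  chrom <- chrom[order(match(chrom, unique(chrom)))]
  start <- integer(n)
  cursor <- setNames(rep(10000L, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  for (i in seq_len(n)) {
    start[i] <- cursor[[chrom[i]]] + as.integer(sample(2000:7000, 1))
    footprint <- if (span[i]) size[i] else 1L
    cursor[[chrom[i]]] <- start[i] + footprint
  }
  end <- ifelse(span, start + size - 1L, start)
  strand <- ifelse(type == "INV", sample(c("++", "--"), n, replace = TRUE), ".")

  freq <- rbeta(n, config$sv_carrier_model$shape1, config$sv_carrier_model$shape2)
  carriers <- lapply(seq_len(n), function(i) {
    cc <- sample_ids[runif(ns) < freq[i]]
    if (!length(cc)) cc <- sample(sample_ids, 1)
    sort(cc)
  })

  truth <- data.frame(
    sv_id = sprintf("SV%05d", seq_len(n)), chrom = chrom, start = start,
    end = end, type = type, strand = strand, size = size,
    n_carriers = lengths(carriers),
    carriers = vapply(carriers, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )

  jit <- config$sv_jitter
  report <- function(caller) {
    keep <- runif(n) >= jit$dropout
    idx <- which(keep)
    if (!length(idx)) {
      return(data.frame(call_id = character(0), caller = character(0),
                        sv_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0), type = character(0),
                        strand = character(0), size = integer(0),
                        carriers = character(0), stringsAsFactors = FALSE))
    }
    b_jit <- as.integer(round(runif(length(idx), -jit$breakpoint, jit$breakpoint)))
    s_jit <- as.integer(round(runif(length(idx), -jit$size, jit$size)))
    st <- start[idx] + b_jit
    sz <- pmax(50L, size[idx] + s_jit)
    en <- ifelse(span[idx], st + sz - 1L, st)
    out <- data.frame(
      call_id = paste0(caller, "_", truth$sv_id[idx]), caller = caller,
      sv_id = truth$sv_id[idx], chrom = chrom[idx], start = st,
      end = as.integer(en), type = type[idx], strand = strand[idx],
      size = sz, carriers = truth$carriers[idx], stringsAsFactors = FALSE
    )
    out[order(match(out$chrom, unique(chrom)), out$start), , drop = FALSE]
  }
  callset_a <- report("lumpy_like")
  callset_b <- report("delly_like")
  truth$reported_a <- truth$sv_id %in% callset_a$sv_id
  truth$reported_b <- truth$sv_id %in% callset_b$sv_id
  rownames(callset_a) <- rownames(callset_b) <- rownames(truth) <- NULL
  list(callset_a = callset_a, callset_b = callset_b, truth = truth,
       sample_ids = sample_ids)
}

#' Write / read an SV call set TSV
#' @param callset call set data frame from [generate_dual_caller_svs()].
#' @param path file path.
#' @export
write_sv_callset <- function(callset, path) {
  write.table(callset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_callset
#' @export
read_sv_callset <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
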