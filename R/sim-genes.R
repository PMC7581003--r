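#' Simulate a pLI-stratified gene set on synthetic chromosomes
#'
#' Draws `n_genes` genes with coding lengths from the configured length
#' model, assigns constraint groups in the exact configured proportions
#' (largest-remainder rounding) and places non-overlapping multi-exon gene
#' models sequentially on a small set of synthetic chromosomes. pLI values
#' are drawn uniformly within each group's band (weak < 0.1, moderate in
#' [0.1, 0.9], strong > 0.9) so that group membership is consistent with the
#' thresholds used downstream.
#'
#' @param config a [sim_config()] object.
#' @return list with `genes` (gene_id, chrom, start, end, strand,
#'   coding_length, pli, group) and `exons` (gene_id, chrom, start, end);
#'   coordinates are 1-based inclusive.
#' @export
generate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes

  n_per_group <- largest_remainder(config$group_proportions, n)
  group <- rep(.constraint_groups, n_per_group)

  pli <- numeric(n)
  pli[group == "weak"] <- runif(sum(group == "weak"), 0, 0.1 - 1e-6)
  pli[group == "moderate"] <- runif(sum(group == "moderate"), 0.1, 0.9)
  pli[group == "strong"] <- runif(sum(group == "strong"), 0.9 + 1e-6, 1)

  lm <- config$coding_length_model
  coding_length <- if (lm$dist == "constant") rep(as.integer(lm$length), n)
    else pmax(150L, as.integer(round(rlnorm(n, lm$meanlog, lm$sdlog))))

  # shuffle group order along the genome so group and position are independent
  ord <- sample.int(n)
  group <- group[ord]; pli <- pli[ord]
  gene_id <- sprintf("GENE%05d", seq_len(n))

  n_exons <- pmax(1L, 1L + rpois(n, 1.5))
  n_exons <- pmin(n_exons, pmax(1L, coding_length %/% 50L))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  n_chrom <- max(1L, min(5L, n %/% 20L + 1L))
  chrom_of <- sprintf("chr%d", rep_len(seq_len(n_chrom), n))
  # keep genes of one chromosome together, in genome order
  ord2 <- order(match(chrom_of, unique(chrom_of)))
  chrom_of <- chrom_of[ord2]

  genes <- vector("list", n)
  exons <- vector("list", n)
  cursor <- setNames(rep(1L, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  for (i in seq_len(n)) {
    k <- n_exons[i]
    # split coding length over k exons, each at least 1 bp
    el <- if (k == 1) coding_length[i] else
      as.vector(rmultinom(1, coding_length[i] - k, rep(1 / k, k))) + 1L
    introns <- if (k > 1) sample(500:3000, k - 1, replace = TRUE) else integer(0)
    chrom <- chrom_of[i]
    start <- cursor[[chrom]] + sample(5000:15000, 1)
    ex_start <- start + c(0L, cumsum(el[-k] + introns))
    ex_end <- ex_start + el - 1L
    genes[[i]] <- data.frame(gene_id = gene_id[i], chrom = chrom,
                             start = start, end = ex_end[k], strand = strand[i],
                             coding_length = as.integer(coding_length[i]),
                             pli = pli[i], group = group[i],
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gene_id[i], chrom = chrom,
                             start = as.integer(ex_start), end = as.integer(ex_end),
                             stringsAsFactors = FALSE)
    cursor[[chrom]] <- ex_end[k]
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Largest-remainder apportionment of n items into proportions
#'
#' @param p non-negative proportions summing to 1.
#' @param n total count to distribute.
#' @return integer vector summing to `n`; ties in remainders are broken in
#'   the order of `p`.
#' @export
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Write the gene table TSV
#' @param genes gene data frame from [generate_genes()].
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand",
                        "coding_length", "pli")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#' @param path gene TSV written by [write_gene_table()] (or equivalent with
#'   columns gene_id, chrom, start, end, strand, coding_length, pli).
#' @export
read_gene_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write exons as BED6 (0-based half-open)
#' @param exons exon data frame from [generate_genes()].
#' @param path output file.
#' @export
write_exon_bed <- function(exons, path) {
  bed <- data.frame(exons$chrom, exons$start - 1L, exons$end,
                    exons$gene_id, 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
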