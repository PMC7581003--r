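#' Simulate a dominant-disease genotyping panel
#'
#' Builds the genotyping panel of a dominant, recessive-lethal candidate
#' allele: affected samples are heterozygous, unaffected samples homozygous
#' reference except for a stated number of discordant unaffected carriers,
#' and no homozygous-alternate individuals occur (the homozygote is assumed
#' inviable). The construction is deterministic: the first
#' `discordant_unaffected_carriers` unaffected samples carry the allele.
#'
#' @param n_unaffected,n_affected panel sizes per phenotype.
#' @param discordant_unaffected_carriers number of unaffected heterozygotes.
#' @return data.frame with sample, phenotype (`affected`/`unaffected`) and
#'   genotype (`0/0`, `0/1`, `1/1`).
#' @export
#' @examples
#' p <- generate_segregation_panel(41, 68, 1)
#' table(p$genotype)  # 40 hom-ref, 69 het
generate_segregation_panel <- function(n_unaffected, n_affected,
                                       discordant_unaffected_carriers = 0) {
  stopifnot(n_unaffected >= 0, n_affected >= 0,
            discordant_unaffected_carriers >= 0,
            discordant_unaffected_carriers <= n_unaffected)
  u <- if (n_unaffected > 0) data.frame(
    sample = sprintf("U%03d", seq_len(n_unaffected)),
    phenotype = "unaffected",
    genotype = c(rep("0/1", discordant_unaffected_carriers),
                 rep("0/0", n_unaffected - discordant_unaffected_carriers)),
    stringsAsFactors = FALSE) else NULL
  a <- if (n_affected > 0) data.frame(
    sample = sprintf("A%03d", seq_len(n_affected)),
    phenotype = "affected", genotype = "0/1",
    stringsAsFactors = FALSE) else NULL
  out <- rbind(u, a)
  rownames(out) <- NULL
  out
}

#' Write / read a segregation panel TSV
#' @param panel panel data frame.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
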