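# Gene-model serialization: FASTA of genomic segments + TSV of CDS
# coordinates (0-based half-open internally; the TSV stores the same).

#' Write gene models as FASTA + coordinate TSV
#'
#' @param models Named list of [GeneModel-class] objects.
#' @param fastaPath FASTA of genomic segments (ids = gene names).
#' @param tsvPath TSV with columns `gene`, `cds_start`, `cds_end`
#'   (0-based half-open), `strand`.
#' @export
writeGeneModels <- function(models, fastaPath, tsvPath) {
  seqs <- DNAStringSet(vapply(models, function(m) as.character(m@sequence),
                              character(1)))
  names(seqs) <- vapply(models, geneName, character(1))
  writeXStringSet(seqs, fastaPath)
  tab <- data.frame(
    gene = names(seqs),
    cds_start = vapply(models, function(m) m@cdsStart, integer(1)),
    cds_end = vapply(models, function(m) m@cdsEnd, integer(1)),
    strand = vapply(models, function(m) m@strand, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastaPath, tsvPath))
}

#' Read gene models written by [writeGeneModels()]
#'
#' @param fastaPath FASTA path.
#' @param tsvPath Coordinate TSV path.
#' @return Named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(fastaPath, tsvPath) {
  seqs <- readDNAStringSet(fastaPath)
  tab <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    GeneModel(tab$gene[i], as.character(seqs[[tab$gene[i]]]),
              tab$cds_start[i], tab$cds_end[i], tab$strand[i])
  })
  stats::setNames(out, tab$gene)
}
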