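#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom Biostrings DNAString DNAStringSet AAString translate
#'   reverseComplement readDNAStringSet writeXStringSet subseq BStringSet
#' @useDynLib cassetteScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GeneModel: a gene plus its genomic context
#'
#' Holds the genomic segment hosting one gene (CDS plus flanks long enough
#' for repair-arm design), the CDS coordinates within that segment
#' (0-based, half-open) and the coding strand. The translated CDS is the
#' protein the variant specifications refer to.
#'
#' @slot geneName Gene identifier.
#' @slot sequence `DNAString`, the genomic segment (gene plus flanks).
#' @slot cdsStart,cdsEnd Integer, 0-based half-open CDS coordinates into
#'   `sequence`.
#' @slot strand `"+"` or `"-"`; on `"-"` the CDS is read as the reverse
#'   complement of `sequence[cdsStart:cdsEnd]`.
#' @export
setClass("GeneModel",
  representation(
    geneName = "character",
    sequence = "DNAString",
    cdsStart = "integer",
    cdsEnd = "integer",
    strand = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  len <- length(object@sequence)
  if (length(object@geneName) != 1L || !nzchar(object@geneName))
    msg <- c(msg, "geneName must be a single non-empty string")
  if (object@cdsStart < 0L || object@cdsEnd > len ||
      object@cdsStart >= object@cdsEnd)
    msg <- c(msg, "CDS coordinates out of range")
  else if ((object@cdsEnd - object@cdsStart) %% 3L != 0L)
    msg <- c(msg, "CDS length must be divisible by 3")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneName Gene identifier.
#' @param sequence Genomic segment as a string or `DNAString`.
#' @param cdsStart,cdsEnd 0-based half-open CDS coordinates.
#' @param strand `"+"` (default) or `"-"`.
#' @return A [GeneModel-class] object.
#' @examples
#' gm <- GeneModel("toy", paste0(strrep("A", 9), "ATGGTTTGGTAA", strrep("T", 9)),
#'                 9, 21)
#' geneProtein(gm)
#' @export
GeneModel <- function(geneName, sequence, cdsStart, cdsEnd, strand = "+") {
  if (!is(sequence, "DNAString")) sequence <- DNAString(as.character(sequence))
  new("GeneModel", geneName = as.character(geneName), sequence = sequence,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      strand = strand)
}

#' TargetSet: functional residues selected for mutagenesis
#'
#' Per-gene sets of 1-based residue positions with their functional
#' category and sublibrary assignment, plus the configured regulator panel
#' the set was built against.
#'
#' @slot targets `data.frame` with columns `gene`, `position`, `wt_aa`
#'   (may be `NA` when no protein sequence was supplied), `category`,
#'   `sublibrary`.
#' @slot panel Character vector of panel gene names.
#' @export
setClass("TargetSet",
  representation(targets = "data.frame", panel = "character")
)

setValidity("TargetSet", function(object) {
  msg <- character(0)
  need <- c("gene", "position", "wt_aa", "category", "sublibrary")
  if (!all(need %in% names(object@targets)))
    msg <- c(msg, paste("targets must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@targets) &&
        !all(object@targets$category %in% siteCategories()))
      msg <- c(msg, "categories outside the closed category set")
    if (nrow(object@targets) && any(object@targets$position < 1L))
      msg <- c(msg, "positions must be >= 1")
    if (!all(object@targets$gene %in% object@panel))
      msg <- c(msg, "target gene outside the configured panel")
  }
  if (length(msg)) msg else TRUE
})

#' OligoPool: the designed cassette library
#'
#' All successfully designed editing cassettes (design metadata plus the
#' full 230-nt oligo sequences) together with a log of variants that could
#' not be designed and why.
#'
#' @slot design `data.frame`, one row per cassette: `cassette_id`, `gene`,
#'   `position`, `wt_aa`, `mut_aa`, `is_control`, `spacer`, `pam`,
#'   `pam_strand`, `pam_disruption`, `sublibrary`.
#' @slot sequences `DNAStringSet` of full cassette sequences, names =
#'   cassette ids.
#' @slot failures `data.frame` of skipped variants: `gene`, `position`,
#'   `mut_aa`, `reason`.
#' @export
setClass("OligoPool",
  representation(design = "data.frame", sequences = "DNAStringSet",
                 failures = "data.frame")
)

setValidity("OligoPool", function(object) {
  msg <- character(0)
  d <- object@design
  if (nrow(d) != length(object@sequences))
    msg <- c(msg, "design rows and sequences differ in number")
  if (anyDuplicated(d$cassette_id))
    msg <- c(msg, "cassette ids must be unique")
  if (length(object@sequences) &&
      !identical(names(object@sequences), d$cassette_id))
    msg <- c(msg, "sequence names must equal design cassette_id, in order")
  if (length(object@sequences) &&
      !all(Biostrings::width(object@sequences) == 230L))
    msg <- c(msg, "every cassette must be exactly 230 nt")
  if (length(msg)) msg else TRUE
})

#' CassetteCounts: per-sample cassette read counts
#'
#' A cassette-by-sample count matrix with per-sample unmapped and
#' ambiguous read bins. The class invariant is read conservation:
#' `colSums(counts) + unmapped + ambiguous == total` for every sample.
#'
#' @slot counts Integer matrix, rows = cassette ids, columns = samples.
#' @slot unmapped,ambiguous,total Named numeric vectors per sample.
#' @export
setClass("CassetteCounts",
  representation(counts = "matrix", unmapped = "numeric",
                 ambiguous = "numeric", total = "numeric")
)

setValidity("CassetteCounts", function(object) {
  msg <- character(0)
  sn <- colnames(object@counts)
  if (is.null(sn)) msg <- c(msg, "count matrix must have sample column names")
  for (slot in c("unmapped", "ambiguous", "total")) {
    v <- slot(object, slot)
    if (!identical(names(v), sn))
      msg <- c(msg, paste0("'", slot, "' names must match sample names"))
  }
  if (!length(msg)) {
    lhs <- colSums(object@counts) + object@unmapped + object@ambiguous
    if (!isTRUE(all.equal(unname(lhs), unname(object@total))))
      msg <- c(msg, "mapped + unmapped + ambiguous must equal total per sample")
  }
  if (any(object@counts < 0)) msg <- c(msg, "negative counts")
  if (length(msg)) msg else TRUE
})

#' ScreenNull: synonymous-control null model for one condition
#'
#' Mean and sample (n-1) standard deviation of the synonymous-control
#' fitness scores under one selection condition, and the derived hit
#' cutoff `mean + k * sd`.
#'
#' @slot condition Condition label.
#' @slot mean,sd Control fitness mean and sample SD.
#' @slot k Cutoff multiplier (default 2).
#' @slot cutoff `mean + k * sd`.
#' @slot nControls Number of control cassettes used.
#' @export
setClass("ScreenNull",
  representation(condition = "character", mean = "numeric", sd = "numeric",
                 k = "numeric", cutoff = "numeric", nControls = "integer")
)

setValidity("ScreenNull", function(object) {
  msg <- character(0)
  if (object@nControls < 2L) msg <- c(msg, "need >= 2 controls")
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (!isTRUE(all.equal(object@cutoff, object@mean + object@k * object@sd)))
    msg <- c(msg, "cutoff must equal mean + k * sd")
  if (length(msg)) msg else TRUE
})
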