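# Packaged reference tables: codon usage, site-type vocabulary, and the
# global-regulator sublibrary panel.

# E. coli K-12 codon usage, occurrences per 1000 codons. Only the ranking
# within each amino acid matters (mutant-codon policy picks the most used).
.CODON_USAGE <- c(
  TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7,
  CTT = 11.0, CTC = 11.0, CTA =  3.9, CTG = 52.6,
  ATT = 30.3, ATC = 25.1, ATA =  4.4, ATG = 27.9,
  GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
  TCT =  8.5, TCC =  8.6, TCA =  7.2, TCG =  8.9,
  CCT =  7.0, CCC =  5.5, CCA =  8.4, CCG = 23.2,
  ACT =  9.0, ACC = 23.4, ACA =  7.1, ACG = 14.4,
  GCT = 15.3, GCC = 25.5, GCA = 20.1, GCG = 33.6,
  TAT = 16.2, TAC = 12.2, TAA =  2.0, TAG =  0.2,
  CAT = 12.9, CAC =  9.7, CAA = 15.3, CAG = 28.8,
  AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
  GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
  TGT =  5.2, TGC =  6.4, TGA =  0.9, TGG = 15.2,
  CGT = 20.9, CGC = 22.0, CGA =  3.6, CGG =  5.4,
  AGT =  8.8, AGC = 16.1, AGA =  2.1, AGG =  1.2,
  GGT = 24.7, GGC = 29.6, GGA =  8.0, GGG = 11.1
)

#' Codon usage table
#'
#' Returns the packaged *E. coli* K-12 codon usage table as a data frame of
#' codon, encoded amino acid (one-letter code, `*` for stop), and usage per
#' 1000 codons. The cassette designer picks mutant codons by descending
#' usage, which keeps designs deterministic and biased toward
#' well-expressed codons.
#'
#' @return A `data.frame` with columns `codon`, `aa`, `usage`.
#' @examples
#' head(codonUsageTable())
#' @export
.tableCache <- new.env(parent = emptyenv())

codonUsageTable <- function() {
  if (is.null(.tableCache$codonTab)) {
    codons <- names(.CODON_USAGE)
    aa <- vapply(codons, function(cd) {
      as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                         no.init.codon = TRUE))
    }, character(1))
    .tableCache$codonTab <- data.frame(
      codon = codons, aa = unname(aa), usage = unname(.CODON_USAGE),
      stringsAsFactors = FALSE)
  }
  .tableCache$codonTab
}

# codon -> one-letter amino acid, via the cached table
.codonAA <- function(codon) {
  tab <- codonUsageTable()
  tab$aa[match(codon, tab$codon)]
}

#' Codons encoding an amino acid, ranked by usage
#'
#' @param aa One-letter amino-acid code (or `*` for stop).
#' @return Character vector of codons, most used first.
#' @examples
#' codonsForAA("L")
#' @export
codonsForAA <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) == 1L)
  if (is.null(.tableCache$byAA)) {
    tab <- codonUsageTable()
    tab <- tab[order(-tab$usage, tab$codon), ]
    .tableCache$byAA <- split(tab$codon, tab$aa)
  }
  out <- .tableCache$byAA[[aa]]
  if (is.null(out)) stop("no codon encodes '", aa, "'")
  out
}

# Closed category set mirroring the sublibrary "site type" vocabulary.
.SITE_CATEGORIES <- c("active_site", "dna_binding", "dimerization", "predicted")

# Synonym map: normalized annotation text -> category. Lookup lowercases and
# strips punctuation/plurals first; anything containing "predict" and any
# unmatched string falls back to "predicted" (the catch-all category).
.SITE_SYNONYMS <- c(
  "active site"        = "active_site",
  "active sites"       = "active_site",
  "catalytic site"     = "active_site",
  "catalytic residue"  = "active_site",
  "dna binding"        = "dna_binding",
  "dna binding site"   = "dna_binding",
  "dna binding sites"  = "dna_binding",
  "dna contact"        = "dna_binding",
  "helix turn helix"   = "dna_binding",
  "dimerization"       = "dimerization",
  "dimerisation"       = "dimerization",
  "dimer interface"    = "dimerization",
  "oligomerization"    = "dimerization",
  "predicted"          = "predicted",
  "predicted site"     = "predicted",
  "ligand proximal"    = "predicted",
  "ligand binding"     = "predicted",
  "metal binding"      = "predicted"
)

#' Functional-site categories
#'
#' The closed set of functional-residue categories used throughout:
#' `active_site`, `dna_binding`, `dimerization`, `predicted`.
#'
#' @return Character vector of category names.
#' @export
siteCategories <- function() .SITE_CATEGORIES

#' Normalize free-text site-type labels
#'
#' Maps annotation site-type strings (e.g. `"Active sites"`,
#' `"DNA binding sites"`, `"metal binding (predicted)"`) onto the closed
#' category set via a packaged synonym map. Text is lowercased and stripped
#' of punctuation before lookup. Strings containing "predict" map to
#' `predicted`; any other unmatched string also maps to `predicted` (the
#' catch-all category) with a warning.
#'
#' @param x Character vector of site-type labels.
#' @return Character vector of categories (see [siteCategories()]).
#' @examples
#' normalizeSiteType(c("Active sites", "Dimerization", "metal binding (predicted)"))
#' @export
normalizeSiteType <- function(x) {
  stopifnot(is.character(x))
  key <- tolower(x)
  key <- gsub("[[:punct:]]+", " ", key)
  key <- gsub("[[:space:]]+", " ", trimws(key))
  out <- unname(.SITE_SYNONYMS[key])
  miss <- is.na(out)
  if (any(miss)) {
    is_pred <- grepl("predict", key[miss], fixed = TRUE)
    if (any(!is_pred)) {
      warning("unrecognized site type(s) mapped to 'predicted': ",
              paste(unique(x[miss][!is_pred]), collapse = ", "))
    }
    out[miss] <- "predicted"
  }
  out
}

# Sublibrary panel of the 23-gene global-regulator screen: five functional
# sublibraries with their gene lists and designed variant counts.
.PANEL <- list(
  G1 = list(
    site_type = "Active sites",
    genes = c("hns", "cspA", "arcA", "fur", "narL", "lrp", "mlc", "ihfB",
              "cspE", "crp", "phoB", "dnaA", "rpoS", "rpoE", "fnr", "soxR",
              "ihfA", "fis"),
    size = 7000L
  ),
  G2 = list(
    site_type = "DNA binding sites",
    genes = c("cspA", "arcA", "narL", "lrp", "mlc", "ihfB", "cspE", "argP",
              "crp"),
    size = 7340L
  ),
  G3 = list(
    site_type = "DNA binding sites",
    genes = c("phoB", "cytR", "dnaA", "soxS", "rpoS", "rpoN", "rpoE", "fnr",
              "soxR", "ihfA", "fis"),
    size = 7400L
  ),
  G4 = list(
    site_type = "Dimerization",
    genes = c("arcA", "fur", "narL", "mlc", "ihfB", "crp", "phoB", "cytR",
              "rpoE", "soxR", "ihfA", "fis"),
    size = 5260L
  ),
  G5 = list(
    site_type = "Predicted",
    genes = c("hns", "cspA", "arcA", "fur", "narL", "lrp", "mlc", "cspE",
              "argP", "crp", "phoB", "cytR", "dnaA", "soxS", "rpoS", "fnr",
              "soxR", "ihfA", "fis", "rpoH"),
    size = 7340L
  )
)

#' Global-regulator sublibrary panel
#'
#' The packaged description of the five-sublibrary global-regulator panel:
#' per sublibrary (G1-G5) its functional site type, gene list, and designed
#' library size. The gene-list union spans the 23 regulators of the screen
#' and the sizes sum to the 34,340 designed variants.
#'
#' @return A `data.frame` with columns `sublibrary`, `site_type`,
#'   `category` (normalized), `n_genes`, `library_size`, and a list column
#'   `genes`.
#' @examples
#' p <- regulatorPanel()
#' sum(p$library_size)
#' length(unique(unlist(p$genes)))
#' @export
regulatorPanel <- function() {
  out <- data.frame(
    sublibrary = names(.PANEL),
    site_type = vapply(.PANEL, `[[`, character(1), "site_type"),
    n_genes = vapply(.PANEL, function(p) length(p$genes), integer(1)),
    library_size = vapply(.PANEL, `[[`, integer(1), "size"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$category <- normalizeSiteType(out$site_type)
  out$genes <- lapply(.PANEL, `[[`, "genes")
  out[, c("sublibrary", "site_type", "category", "n_genes",
          "library_size", "genes")]
}
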