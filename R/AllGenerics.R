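# Generics and accessors for the core classes.

#' @rdname GeneModel-class
#' @param object,x A package object.
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname GeneModel-class
#' @export
setMethod("geneName", "GeneModel", function(x) x@geneName)

#' Translated protein of a GeneModel
#'
#' @param x A [GeneModel-class].
#' @return An `AAString` with the protein sequence (no stop).
#' @export
setGeneric("geneProtein", function(x) standardGeneric("geneProtein"))

#' @rdname geneProtein
#' @export
setMethod("geneProtein", "GeneModel", function(x) {
  # default initiator handling: GTG/TTG starts are read as formyl-Met (M)
  aa <- translate(geneCDS(x))
  n <- length(aa)
  if (n && as.character(subseq(aa, n, n)) == "*") aa <- subseq(aa, 1L, n - 1L)
  aa
})

#' Coding sequence of a GeneModel
#'
#' @param x A [GeneModel-class].
#' @return A `DNAString` of the CDS read 5' to 3' on the coding strand.
#' @export
setGeneric("geneCDS", function(x) standardGeneric("geneCDS"))

#' @rdname geneCDS
#' @export
setMethod("geneCDS", "GeneModel", function(x) {
  cds <- subseq(x@sequence, x@cdsStart + 1L, x@cdsEnd)
  if (x@strand == "-") cds <- reverseComplement(cds)
  cds
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel '", object@geneName, "': ", length(object@sequence),
      " nt segment, CDS [", object@cdsStart, ", ", object@cdsEnd,
      ") strand ", object@strand, ", ",
      (object@cdsEnd - object@cdsStart) %/% 3L - 1L, " aa\n", sep = "")
})

#' Targets table of a TargetSet
#'
#' @param x A [TargetSet-class].
#' @return `data.frame` of gene, position, wt_aa, category, sublibrary.
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname targets
#' @export
setMethod("targets", "TargetSet", function(x) x@targets)

#' Panel gene names of a TargetSet
#'
#' @param x A [TargetSet-class].
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname panelGenes
#' @export
setMethod("panelGenes", "TargetSet", function(x) x@panel)

setMethod("show", "TargetSet", function(object) {
  t <- object@targets
  cat("TargetSet: ", length(unique(t$gene)), " gene(s), ",
      nrow(unique(t[, c("gene", "position")])), " residue(s), ",
      nrow(t), " (residue, category) entries\n", sep = "")
  if (nrow(t)) {
    tab <- table(t$sublibrary)
    cat("  sublibraries: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
})

#' Design table of an OligoPool
#'
#' @param x An [OligoPool-class].
#' @export
setGeneric("cassetteDesign", function(x) standardGeneric("cassetteDesign"))

#' @rdname cassetteDesign
#' @export
setMethod("cassetteDesign", "OligoPool", function(x) x@design)

#' Cassette sequences of an OligoPool
#'
#' @param x An [OligoPool-class].
#' @return Named `DNAStringSet` of 230-nt cassettes.
#' @export
setGeneric("cassetteSequences", function(x) standardGeneric("cassetteSequences"))

#' @rdname cassetteSequences
#' @export
setMethod("cassetteSequences", "OligoPool", function(x) x@sequences)

#' Design-failure log of an OligoPool
#'
#' @param x An [OligoPool-class].
#' @export
setGeneric("designFailures", function(x) standardGeneric("designFailures"))

#' @rdname designFailures
#' @export
setMethod("designFailures", "OligoPool", function(x) x@failures)

setMethod("show", "OligoPool", function(object) {
  d <- object@design
  cat("OligoPool: ", nrow(d), " cassette(s) (",
      sum(d$is_control), " synonymous controls), ",
      nrow(object@failures), " design failure(s)\n", sep = "")
  if (nrow(d))
    cat("  genes: ", paste(unique(d$gene), collapse = ", "), "\n", sep = "")
})

setMethod("length", "OligoPool", function(x) nrow(x@design))

#' @describeIn cassetteDesign Subset an OligoPool by cassette id or index.
#' @param i Cassette ids (character) or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "OligoPool", function(x, i, j, ..., drop = FALSE) {
  idx <- if (is.character(i)) match(i, x@design$cassette_id) else i
  if (anyNA(idx)) stop("unknown cassette id(s)")
  d <- x@design[idx, , drop = FALSE]
  rownames(d) <- NULL
  new("OligoPool", design = d,
      sequences = x@sequences[idx], failures = x@failures)
})

#' Count matrix of a CassetteCounts
#'
#' @param x A [CassetteCounts-class].
#' @export
setGeneric("cassetteCounts", function(x) standardGeneric("cassetteCounts"))

#' @rdname cassetteCounts
#' @export
setMethod("cassetteCounts", "CassetteCounts", function(x) x@counts)

#' Per-sample unmapped-read counts
#' @param x A [CassetteCounts-class].
#' @export
setGeneric("unmappedReads", function(x) standardGeneric("unmappedReads"))

#' @rdname unmappedReads
#' @export
setMethod("unmappedReads", "CassetteCounts", function(x) x@unmapped)

#' Per-sample ambiguous-read counts
#' @param x A [CassetteCounts-class].
#' @export
setGeneric("ambiguousReads", function(x) standardGeneric("ambiguousReads"))

#' @rdname ambiguousReads
#' @export
setMethod("ambiguousReads", "CassetteCounts", function(x) x@ambiguous)

#' Per-sample total read counts
#' @param x A [CassetteCounts-class].
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname totalReads
#' @export
setMethod("totalReads", "CassetteCounts", function(x) x@total)

setMethod("show", "CassetteCounts", function(object) {
  cat("CassetteCounts: ", nrow(object@counts), " cassette(s) x ",
      ncol(object@counts), " sample(s)\n", sep = "")
  for (s in colnames(object@counts)) {
    cat("  ", s, ": total=", object@total[s],
        " mapped=", sum(object@counts[, s]),
        " unmapped=", object@unmapped[s],
        " ambiguous=", object@ambiguous[s], "\n", sep = "")
  }
})

#' Hit cutoff of a ScreenNull
#'
#' @param x A [ScreenNull-class].
#' @return `mean + k * sd` for the condition.
#' @export
setGeneric("nullCutoff", function(x) standardGeneric("nullCutoff"))

#' @rdname nullCutoff
#' @export
setMethod("nullCutoff", "ScreenNull", function(x) x@cutoff)

setMethod("show", "ScreenNull", function(object) {
  cat("ScreenNull [", object@condition, "]: mean=",
      signif(object@mean, 4), " sd=", signif(object@sd, 4),
      " k=", object@k, " cutoff=", signif(object@cutoff, 4),
      " (n=", object@nControls, " controls)\n", sep = "")
})
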