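# Functional-residue selection: feature-table parsing, ligand-proximity
# calls from structures, and assembly into sublibrary target sets.

# Hetero residue names treated as solvent/buffer, never as ligands.
.SOLVENT_EXCLUDE <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA",
                      "ZN", "SO4", "PO4", "GOL", "EDO", "ACT", "PEG", "DMS")

#' Parse a functional-annotation feature table
#'
#' Reads tabular annotation records (one row per annotated residue) into
#' normalized functional annotations. Site-type text is mapped onto the
#' closed category set via [normalizeSiteType()]; duplicate
#' (gene, position, category) records are collapsed; positions outside the
#' protein are rejected.
#'
#' @param rows A `data.frame` with columns `gene`, `position`, `site_type`
#'   and optionally `source`, or a path to a TSV file with those columns.
#' @param proteins Optional named list of protein sequences (strings or
#'   `AAString`), used to range-check positions and fill `wt_aa`.
#' @return A `data.frame` with columns `gene`, `position`, `category`,
#'   `source`, `wt_aa` (`NA` when no protein was supplied).
#' @examples
#' parseFeatureTable(data.frame(gene = "soxR", position = 121,
#'                              site_type = "Active sites"))
#' @export
parseFeatureTable <- function(rows, proteins = NULL) {
  if (is.character(rows) && length(rows) == 1L) {
    rows <- utils::read.delim(rows, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(rows))
  need <- c("gene", "position", "site_type")
  if (!all(need %in% names(rows)))
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  if (is.null(rows$source)) rows$source <- NA_character_
  pos <- suppressWarnings(as.numeric(rows$position))
  bad <- is.na(pos) | pos != floor(pos) | pos < 1
  if (any(bad))
    stop("non-integer or non-positive position in row(s): ",
         paste(which(bad), collapse = ", "))
  if (!is.null(proteins)) {
    unknown <- !rows$gene %in% names(proteins)
    if (any(unknown))
      stop("unknown gene name in row(s): ",
           paste(which(unknown), collapse = ", "), " (",
           paste(unique(rows$gene[unknown]), collapse = ", "), ")")
    plen <- vapply(proteins, function(p) nchar(as.character(p)), numeric(1))
    oor <- pos > plen[rows$gene]
    if (any(oor))
      stop("position beyond protein length in row(s): ",
           paste(which(oor), collapse = ", "))
  }
  out <- data.frame(
    gene = as.character(rows$gene),
    position = as.integer(pos),
    category = normalizeSiteType(as.character(rows$site_type)),
    source = as.character(rows$source),
    stringsAsFactors = FALSE
  )
  out$wt_aa <- if (is.null(proteins)) NA_character_ else {
    vapply(seq_len(nrow(out)), function(i) {
      substr(as.character(proteins[[out$gene[i]]]), out$position[i],
             out$position[i])
    }, character(1))
  }
  out <- out[!duplicated(out[, c("gene", "position", "category")]), ,
             drop = FALSE]
  out <- out[order(out$gene, out$position, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a PDB-format structure into an atom table
#'
#' Parses a PDB coordinate file and returns one row per atom with its
#' 1-based residue index, residue name, atom name, coordinates, and a
#' ligand flag. Hetero records are treated as ligand atoms unless their
#' residue name is in the solvent/buffer exclusion list (waters and common
#' ions/cryoprotectants by default).
#'
#' @param path Path to a PDB-format file.
#' @param solventExclude Character vector of hetero residue names never
#'   treated as ligands.
#' @return A `data.frame` with columns `residue_index`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z`, `is_ligand`.
#' @export
readStructure <- function(path, solventExclude = .SOLVENT_EXCLUDE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  data.frame(
    residue_index = as.integer(a$resno),
    residue_name = as.character(a$resid),
    atom_name = as.character(a$elety),
    x = a$x, y = a$y, z = a$z,
    is_ligand = a$type == "HETATM" & !(a$resid %in% solventExclude),
    stringsAsFactors = FALSE
  )
}

#' Residues within a distance cutoff of any ligand atom
#'
#' Returns every polymer residue with at least one atom whose Euclidean
#' distance to at least one ligand atom is less than or equal to `radius`
#' (inclusive boundary). This is the ligand-proximity rule used to
#' nominate predicted functional residues from ligand-bound structures;
#' the default radius is 5 Angstroms.
#'
#' @param atoms Atom table as returned by [readStructure()] (columns
#'   `residue_index`, `x`, `y`, `z`, `is_ligand`).
#' @param radius Distance cutoff in Angstroms (> 0).
#' @return Sorted integer vector of 1-based residue indices.
#' @examples
#' atoms <- data.frame(residue_index = c(NA, 7),
#'                     x = c(0, 3), y = c(0, 4), z = c(0, 0),
#'                     is_ligand = c(TRUE, FALSE))
#' ligandProximalResidues(atoms, radius = 5)  # distance exactly 5.0 -> kept
#' @export
ligandProximalResidues <- function(atoms, radius = 5) {
  stopifnot(is.data.frame(atoms), radius > 0)
  if (nrow(atoms) == 0L) stop("empty structure")
  lig <- atoms[atoms$is_ligand, , drop = FALSE]
  pol <- atoms[!atoms$is_ligand, , drop = FALSE]
  if (nrow(lig) == 0L) stop("structure has no ligand atoms")
  if (nrow(pol) == 0L) return(integer(0))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  pm <- cbind(pol$x, pol$y, pol$z)
  lm <- cbind(lig$x, lig$y, lig$z)
  # squared-distance matrix polymer x ligand, vectorized
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * tcrossprod(pm, lm)
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  near <- apply(d2 <= radius^2 + 1e-12, 1L, any)
  sort(unique(as.integer(pol$residue_index[near])))
}

#' Build sublibrary target sets
#'
#' Merges parsed functional annotations with structure-derived residues
#' and partitions them into the panel's sublibraries by category. A gene
#' may appear in several sublibraries; a panel gene with no targeted
#' residue is kept in the summary with count 0 (with a warning).
#'
#' @param annotations Annotation `data.frame` from [parseFeatureTable()].
#' @param structureHits Optional `data.frame` with columns `gene`,
#'   `position` (residues nominated from structures, e.g.
#'   [ligandProximalResidues()] output) and optionally `category`
#'   (defaults to `"predicted"`).
#' @param panel Panel configuration: a `data.frame` as returned by
#'   [regulatorPanel()] (columns `sublibrary`, `category`, list column
#'   `genes`), or a path to a YAML file with entries
#'   `sublibrary: {category: ..., genes: [...]}`.
#' @param proteins Optional named protein sequences to fill `wt_aa`.
#' @return A [TargetSet-class].
#' @export
buildTargetSets <- function(annotations, structureHits = NULL, panel,
                            proteins = NULL) {
  if (is.character(panel) && length(panel) == 1L) panel <- readPanelConfig(panel)
  stopifnot(is.data.frame(panel),
            all(c("sublibrary", "category", "genes") %in% names(panel)))
  panelGenes <- unique(unlist(panel$genes))
  if (length(panelGenes) == 0L) stop("empty panel")

  ann <- annotations[, c("gene", "position", "category"), drop = FALSE]
  if (!is.null(structureHits) && nrow(structureHits)) {
    sh <- structureHits
    if (is.null(sh$category)) sh$category <- "predicted"
    sh$category <- normalizeSiteType(as.character(sh$category))
    ann <- rbind(ann, sh[, c("gene", "position", "category"), drop = FALSE])
  }
  ann$position <- as.integer(ann$position)
  bad <- !ann$gene %in% panelGenes
  if (any(bad))
    stop("annotated gene(s) outside the panel: ",
         paste(unique(ann$gene[bad]), collapse = ", "))
  ann <- ann[!duplicated(ann[, c("gene", "position", "category")]), ,
             drop = FALSE]

  # assign each (gene, residue, category) to every matching sublibrary row
  pieces <- lapply(seq_len(nrow(panel)), function(i) {
    sel <- ann$category == panel$category[i] &
      ann$gene %in% panel$genes[[i]]
    if (!any(sel)) return(NULL)
    cbind(ann[sel, , drop = FALSE], sublibrary = panel$sublibrary[i])
  })
  tg <- do.call(rbind, pieces)
  if (is.null(tg))
    tg <- data.frame(gene = character(0), position = integer(0),
                     category = character(0), sublibrary = character(0))
  orphan <- !paste(ann$gene, ann$position, ann$category) %in%
    paste(tg$gene, tg$position, tg$category)
  if (any(orphan))
    warning(sum(orphan), " annotation(s) match no sublibrary ",
            "(gene/category combination absent from the panel) and were dropped")
  tg$wt_aa <- if (is.null(proteins)) NA_character_ else {
    vapply(seq_len(nrow(tg)), function(i) {
      substr(as.character(proteins[[tg$gene[i]]]), tg$position[i],
             tg$position[i])
    }, character(1))
  }
  tg <- tg[order(tg$sublibrary, tg$gene, tg$position, tg$category), ,
           drop = FALSE]
  tg <- tg[, c("gene", "position", "wt_aa", "category", "sublibrary")]
  rownames(tg) <- NULL

  zero <- setdiff(panelGenes, unique(tg$gene))
  if (length(zero))
    warning("panel gene(s) with zero targeted residues: ",
            paste(zero, collapse = ", "))
  new("TargetSet", targets = tg, panel = panelGenes)
}

#' Read a sublibrary panel configuration from YAML
#'
#' Expected layout: a mapping of sublibrary name to `category` and
#' `genes` entries.
#'
#' @param path YAML file path.
#' @return A `data.frame` with `sublibrary`, `category`, list column `genes`.
#' @export
readPanelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- data.frame(
    sublibrary = names(cfg),
    category = vapply(cfg, function(x) normalizeSiteType(x$category),
                      character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$genes <- lapply(cfg, function(x) as.character(x$genes))
  out
}

#' Per-sublibrary summary of a TargetSet
#'
#' @param x A [TargetSet-class].
#' @return `data.frame` with `sublibrary`, `n_genes`, `n_residues`,
#'   `n_entries`.
#' @export
targetSummary <- function(x) {
  stopifnot(is(x, "TargetSet"))
  t <- targets(x)
  libs <- sort(unique(t$sublibrary))
  out <- do.call(rbind, lapply(libs, function(s) {
    sub <- t[t$sublibrary == s, , drop = FALSE]
    data.frame(sublibrary = s, n_genes = length(unique(sub$gene)),
               n_residues = nrow(unique(sub[, c("gene", "position")])),
               n_entries = nrow(sub), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(sublibrary = character(0), n_genes = integer(0),
                      n_residues = integer(0), n_entries = integer(0))
  rownames(out) <- NULL
  out
}

#' Write a TargetSet to TSV + JSON summary
#'
#' @param x A [TargetSet-class].
#' @param tsvPath Output TSV path (gene, position, wt_aa, category,
#'   sublibrary).
#' @param jsonPath Optional JSON path for the per-sublibrary summary.
#' @return Invisibly, the paths written.
#' @export
writeTargetSet <- function(x, tsvPath, jsonPath = NULL) {
  stopifnot(is(x, "TargetSet"))
  utils::write.table(targets(x), tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath)) {
    s <- targetSummary(x)
    jsonlite::write_json(
      lapply(split(s, s$sublibrary), function(r)
        list(n_genes = r$n_genes, n_residues = r$n_residues,
             n_entries = r$n_entries)),
      jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsvPath, jsonPath))
}

#' Read a TargetSet written by [writeTargetSet()]
#'
#' @param tsvPath TSV path.
#' @param panel Optional panel gene names; defaults to the genes present.
#' @return A [TargetSet-class].
#' @export
readTargetSet <- function(tsvPath, panel = NULL) {
  t <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  t$position <- as.integer(t$position)
  t$wt_aa <- as.character(t$wt_aa)
  if (is.null(panel)) panel <- unique(t$gene)
  new("TargetSet", targets = t, panel = panel)
}
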