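# Editing-cassette design: variant enumeration, spacer/PAM selection,
# repair-arm construction with PAM disruption, and 230-nt oligo assembly.

.rc <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

# no.init.codon: never apply initiator-codon rules (CTG/TTG -> M) when
# translating isolated codons or edited CDSs
.translateDNA <- function(x)
  as.character(translate(DNAString(x), no.init.codon = TRUE))

# 0-based half-open genomic range of a residue's codon within the segment
.codonRange <- function(gm, residue) {
  nres <- (gm@cdsEnd - gm@cdsStart) %/% 3L - 1L  # excluding stop
  if (residue < 1L || residue > nres)
    stop("residue ", residue, " outside protein of length ", nres)
  if (gm@strand == "+") {
    s <- gm@cdsStart + 3L * (residue - 1L)
  } else {
    s <- gm@cdsEnd - 3L * residue
  }
  c(start = s, end = s + 3L)
}

#' Default cassette design configuration
#'
#' The cassette layout fixes the hard 230-nt total:
#' 15-nt 5' priming site, repair arm (142 nt by default), 20-nt
#' junction/priming site, 20-nt spacer, 33-nt 3' priming site
#' (15 + 142 + 20 + 20 + 33 = 230). The priming/junction sequences are
#' fixed synthetic handles shared by all cassettes; the 3' element is the
#' start of the sgRNA scaffold. All lengths are configurable under the
#' hard 230-nt total.
#'
#' @param armLength Repair-arm length in nt.
#' @param searchWindow Maximum distance (nt) between the Cas9 cut site and
#'   the midpoint of the edited codon; keeps the edit within efficient
#'   HDR range of the cut.
#' @param spacerLength Spacer length (20 for S. pyogenes Cas9).
#' @param prime5,junction,prime3 Fixed handle sequences.
#' @param totalLength Hard cassette length (230).
#' @param multiCodon If `TRUE`, emit one cassette per synonymous codon of
#'   each substitution rather than only the most-used codon.
#' @return A list of design parameters (validated to sum to
#'   `totalLength`).
#' @export
cassetteDesignConfig <- function(armLength = 142L,
                                 searchWindow = 30L,
                                 spacerLength = 20L,
                                 prime5 = "ACACCGGTTCTTCGG",
                                 junction = "CGTAAGCTTGGCACCGAGTC",
                                 prime3 = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAG",
                                 totalLength = 230L,
                                 multiCodon = FALSE) {
  cfg <- list(armLength = as.integer(armLength),
              searchWindow = as.integer(searchWindow),
              spacerLength = as.integer(spacerLength),
              prime5 = prime5, junction = junction, prime3 = prime3,
              totalLength = as.integer(totalLength),
              multiCodon = isTRUE(multiCodon))
  got <- nchar(prime5) + cfg$armLength + nchar(junction) +
    cfg$spacerLength + nchar(prime3)
  if (got != cfg$totalLength)
    stop("layout segments sum to ", got, ", not ", cfg$totalLength)
  cfg
}

#' Read a design configuration from YAML
#'
#' Keys mirror the arguments of [cassetteDesignConfig()]; missing keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @export
readDesignConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(cassetteDesignConfig,
          cfg[intersect(names(cfg), names(formals(cassetteDesignConfig)))])
}

#' Enumerate variant specifications for a target set
#'
#' For each targeted residue, emits one specification per non-wild-type
#' amino acid in `mutationAlphabet` plus (when `includeControls`) one
#' synonymous-control specification. Residues whose wild-type amino acid
#' has a single codon (Met, Trp) cannot carry a synonymous control; these
#' are logged in the `control_unavailable` attribute rather than silently
#' dropped. Output ordering is deterministic: gene, position, mutant
#' amino acid.
#'
#' @param targetSet A [TargetSet-class].
#' @param geneModels Named list of [GeneModel-class] objects covering the
#'   target genes (used to read wild-type amino acids).
#' @param mutationAlphabet Amino acids to substitute to; default the 20
#'   standard amino acids (i.e. 19 non-wild-type substitutions per
#'   residue).
#' @param includeControls Emit per-residue synonymous controls.
#' @return `data.frame` with `gene`, `position`, `wt_aa`, `mut_aa`,
#'   `is_control`, plus attribute `control_unavailable`.
#' @export
enumerateVariants <- function(targetSet, geneModels,
                              mutationAlphabet = NULL,
                              includeControls = TRUE) {
  stopifnot(is(targetSet, "TargetSet"))
  t <- targets(targetSet)
  if (nrow(t) == 0L) stop("empty target set")
  if (is.null(mutationAlphabet))
    mutationAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- unique(t[, c("gene", "position")])
  miss <- setdiff(unique(res$gene), names(geneModels))
  if (length(miss))
    stop("no gene model for: ", paste(miss, collapse = ", "))
  specs <- list()
  noCtrl <- list()
  for (i in seq_len(nrow(res))) {
    g <- res$gene[i]; p <- res$position[i]
    prot <- as.character(geneProtein(geneModels[[g]]))
    wt <- substr(prot, p, p)
    muts <- sort(setdiff(mutationAlphabet, wt))
    specs[[length(specs) + 1L]] <- data.frame(
      gene = g, position = p, wt_aa = wt, mut_aa = muts,
      is_control = FALSE, stringsAsFactors = FALSE)
    if (includeControls) {
      if (length(codonsForAA(wt)) >= 2L) {
        specs[[length(specs) + 1L]] <- data.frame(
          gene = g, position = p, wt_aa = wt, mut_aa = wt,
          is_control = TRUE, stringsAsFactors = FALSE)
      } else {
        noCtrl[[length(noCtrl) + 1L]] <- data.frame(
          gene = g, position = p, wt_aa = wt,
          reason = "single-codon amino acid, no synonymous control",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, specs)
  out <- out[order(out$gene, out$position, out$mut_aa, out$is_control), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_unavailable") <- if (length(noCtrl))
    do.call(rbind, noCtrl)
  else
    data.frame(gene = character(0), position = integer(0),
               wt_aa = character(0), reason = character(0))
  out
}

#' Select a spacer and PAM for a target residue
#'
#' Scans both strands of the gene segment for NGG protospacer-adjacent
#' motifs whose blunt Cas9 cut site (between protospacer positions 17 and
#' 18) lies within `searchWindow` nt of the target codon midpoint, and
#' returns the candidate with the smallest cut-to-codon distance. Ties
#' are broken in favor of the + strand, then the leftmost genomic
#' coordinate. The spacer is reported 5' to 3' on the protospacer strand.
#'
#' @param gm A [GeneModel-class].
#' @param residuePosition 1-based residue index.
#' @param searchWindow Maximum cut-to-codon-midpoint distance in nt.
#' @param spacerLength Spacer length (default 20).
#' @return A list with `spacer`, `pam`, `pam_strand`, `cut` (0-based
#'   between-base coordinate), `proto_start`, `proto_end`, `pam_start`,
#'   `pam_end` (0-based half-open, + strand), `distance`; or `NULL` when
#'   no PAM lies within the window (a design failure for the variant).
#' @export
selectSpacer <- function(gm, residuePosition, searchWindow = 30L,
                         spacerLength = 20L) {
  seq <- as.character(gm@sequence)
  len <- nchar(seq)
  cr <- .codonRange(gm, residuePosition)
  mid <- unname(cr["start"]) + 1.5
  lo <- max(0L, as.integer(floor(mid - searchWindow - spacerLength - 3L)))
  hi <- min(len - 3L, as.integer(ceiling(mid + searchWindow + spacerLength + 3L)))
  cand <- list()
  for (p in lo:hi) {
    # + strand PAM: NGG at [p, p+3), protospacer [p-20, p)
    if (p >= spacerLength && p + 3L <= len &&
        substr(seq, p + 2L, p + 3L) == "GG") {
      cut <- p - 3L
      d <- abs(cut - mid)
      if (d <= searchWindow)
        cand[[length(cand) + 1L]] <- list(
          strand = "+", proto_start = p - spacerLength, proto_end = p,
          pam_start = p, pam_end = p + 3L, cut = cut, distance = d)
    }
    # - strand PAM: CCN at [p, p+3) on + strand, protospacer [p+3, p+23)
    if (p + 3L + spacerLength <= len &&
        substr(seq, p + 1L, p + 2L) == "CC") {
      cut <- p + 6L
      d <- abs(cut - mid)
      if (d <= searchWindow)
        cand[[length(cand) + 1L]] <- list(
          strand = "-", proto_start = p + 3L, proto_end = p + 3L + spacerLength,
          pam_start = p, pam_end = p + 3L, cut = cut, distance = d)
    }
  }
  if (!length(cand)) return(NULL)
  ord <- order(vapply(cand, `[[`, numeric(1), "distance"),
               vapply(cand, `[[`, character(1), "strand") != "+",
               vapply(cand, `[[`, numeric(1), "proto_start"))
  best <- cand[[ord[1L]]]
  protoPlus <- substr(seq, best$proto_start + 1L, best$proto_end)
  pamPlus <- substr(seq, best$pam_start + 1L, best$pam_end)
  if (best$strand == "+") {
    spacer <- protoPlus; pam <- pamPlus
  } else {
    spacer <- .rc(protoPlus); pam <- .rc(pamPlus)
  }
  list(spacer = spacer, pam = pam, pam_strand = best$strand,
       cut = best$cut, proto_start = best$proto_start,
       proto_end = best$proto_end, pam_start = best$pam_start,
       pam_end = best$pam_end, distance = best$distance)
}

# Is the chosen protospacer + NGG site still perfectly matched in `seq`?
.siteIntact <- function(seq, sp) {
  proto <- substr(seq, sp$proto_start + 1L, sp$proto_end)
  pam <- substr(seq, sp$pam_start + 1L, sp$pam_end)
  if (sp$pam_strand == "+") {
    proto == sp$spacer && substr(pam, 2L, 3L) == "GG"
  } else {
    .rc(proto) == sp$spacer && substr(pam, 1L, 2L) == "CC"
  }
}

# Exhaustive search for any perfect protospacer+NGG match on either strand.
.hasCutSite <- function(seq, spacer) {
  for (s in c(seq, .rc(seq))) {
    hits <- gregexpr(spacer, s, fixed = TRUE)[[1L]]
    for (h in hits) {
      if (h < 0L) next
      pam <- substr(s, h + nchar(spacer), h + nchar(spacer) + 2L)
      if (nchar(pam) == 3L && substr(pam, 2L, 3L) == "GG") return(TRUE)
    }
  }
  FALSE
}

.replaceRange <- function(seq, start0, repl) {
  # start0 is 0-based; repl replaces nchar(repl) bases
  paste0(substr(seq, 1L, start0), repl,
         substr(seq, start0 + nchar(repl) + 1L, nchar(seq)))
}

# Codon policy: most-used codon for the mutant amino acid; for synonymous
# controls, the most-used synonymous codon different from the wild type.
.chooseCodon <- function(currentCodon, mutAA, isControl) {
  alts <- codonsForAA(mutAA)
  if (isControl) alts <- setdiff(alts, currentCodon)
  if (!length(alts)) return(NULL)
  alts[1L]
}

#' Design a repair arm for one variant
#'
#' Builds the homology arm centered on the edited codon. The arm carries
#' (a) the mutant codon chosen by the codon-usage policy and (b) a
#' synonymous PAM-disrupting change: preferentially inside the NGG
#' itself, otherwise a synonymous seed-region change within 10 nt of the
#' cut site. When the amino-acid edit itself destroys the
#' protospacer/PAM match, no extra change is introduced and
#' `pam_disruption` is `"edit-overlaps-PAM"`. The edited CDS is
#' re-translated and must differ from wild type at exactly the intended
#' residue (nowhere, for controls).
#'
#' @param gm A [GeneModel-class].
#' @param variant One-row variant spec (`position`, `wt_aa`, `mut_aa`,
#'   `is_control`), e.g. a row of [enumerateVariants()] output.
#' @param spacerChoice Result of [selectSpacer()] for the same residue.
#' @param armLength Repair-arm length in nt.
#' @param codonOverride Optional explicit mutant codon (coding strand);
#'   used by the multi-codon design mode.
#' @return A list with `arm`, `edit_offset` (0-based offset of the codon
#'   within the arm), `pam_disruption`, `edited_segment`, `mut_codon`; or
#'   a character scalar giving the failure reason.
#' @export
designRepairArm <- function(gm, variant, spacerChoice, armLength = 142L,
                            codonOverride = NULL) {
  seq <- as.character(gm@sequence)
  len <- nchar(seq)
  p <- as.integer(variant$position)
  cr <- .codonRange(gm, p)
  armStart <- cr["start"] - (armLength - 3L) %/% 2L
  if (armStart < 0L || armStart + armLength > len)
    return("arm-out-of-bounds")
  wtProt <- as.character(geneProtein(gm))
  if (substr(wtProt, p, p) != variant$wt_aa)
    return("wt-aa-mismatch")
  curCodonCoding <- {
    cd <- substr(seq, cr["start"] + 1L, cr["end"])
    if (gm@strand == "-") .rc(cd) else cd
  }
  newCodon <- if (!is.null(codonOverride)) codonOverride else
    .chooseCodon(curCodonCoding, variant$mut_aa, isTRUE(variant$is_control))
  if (is.null(newCodon)) return("no-alternative-codon")
  newPlus <- if (gm@strand == "-") .rc(newCodon) else newCodon
  edited <- .replaceRange(seq, cr["start"], newPlus)

  disruption <- NULL
  if (!.siteIntact(edited, spacerChoice)) {
    disruption <- "edit-overlaps-PAM"
  } else {
    # candidate regions: the PAM footprint first, then seed bases within
    # 10 nt of the cut site
    pamRange <- c(spacerChoice$pam_start, spacerChoice$pam_end)
    seedLo <- max(spacerChoice$proto_start, spacerChoice$cut - 10L)
    seedHi <- min(spacerChoice$proto_end, spacerChoice$cut + 10L)
    regions <- list(c(pamRange, label = NA), c(seedLo, seedHi, label = NA))
    labels <- c("pam", "seed")
    nres <- (gm@cdsEnd - gm@cdsStart) %/% 3L
    for (ri in seq_along(regions)) {
      lo <- regions[[ri]][1L]; hi <- regions[[ri]][2L]
      if (hi <= lo) next
      # CDS codons (incl. stop) overlapping [lo, hi), excluding the edited one
      codIdx <- seq_len(nres)
      starts <- if (gm@strand == "+") gm@cdsStart + 3L * (codIdx - 1L)
                else gm@cdsEnd - 3L * codIdx
      overlap <- starts < hi & (starts + 3L) > lo & starts != cr["start"]
      for (ci in codIdx[overlap]) {
        cs <- starts[ci]
        curPlus <- substr(edited, cs + 1L, cs + 3L)
        curCoding <- if (gm@strand == "-") .rc(curPlus) else curPlus
        aa <- .codonAA(curCoding)
        alts <- setdiff(codonsForAA(aa), curCoding)
        for (alt in alts) {
          altPlus <- if (gm@strand == "-") .rc(alt) else alt
          # must change a base inside the candidate region and the arm
          changed <- which(strsplit(altPlus, "")[[1L]] !=
                           strsplit(curPlus, "")[[1L]]) - 1L + cs
          if (!length(changed)) next
          if (!any(changed >= lo & changed < hi)) next
          if (any(changed < armStart | changed >= armStart + armLength)) next
          trial <- .replaceRange(edited, cs, altPlus)
          if (!.siteIntact(trial, spacerChoice)) {
            edited <- trial
            disruption <- sprintf("%s:codon%d:%s>%s", labels[ri], ci,
                                  curCoding, alt)
            break
          }
        }
        if (!is.null(disruption)) break
      }
      if (!is.null(disruption)) break
    }
    if (is.null(disruption)) return("no-pam-disruption")
  }

  # the edit itself must sit inside the arm
  if (cr["start"] < armStart || cr["end"] > armStart + armLength)
    return("edit-outside-arm")
  # re-cut resistance: no perfect protospacer+NGG anywhere in the edit
  if (.hasCutSite(edited, spacerChoice$spacer))
    return("recut-site-persists")
  # translation check: exactly the intended protein change
  cdsEdited <- substr(edited, gm@cdsStart + 1L, gm@cdsEnd)
  if (gm@strand == "-") cdsEdited <- .rc(cdsEdited)
  # initiator rules on, matching geneProtein(): codon 1 is never edited here
  protEdited <- sub("\\*$", "",
                    as.character(translate(DNAString(cdsEdited))))
  expect <- wtProt
  if (!isTRUE(variant$is_control))
    substr(expect, p, p) <- variant$mut_aa
  if (protEdited != expect) return("unintended-protein-change")

  list(arm = substr(edited, armStart + 1L, armStart + armLength),
       edit_offset = unname(cr["start"] - armStart),
       pam_disruption = disruption,
       edited_segment = edited,
       mut_codon = newCodon)
}

#' Assemble a full 230-nt cassette
#'
#' Concatenates the layout segments:
#' `5' priming | repair arm | junction | spacer | 3' priming`.
#'
#' @param spacer 20-nt spacer (protospacer-strand sequence).
#' @param repairArm Repair arm from [designRepairArm()].
#' @param config Layout from [cassetteDesignConfig()].
#' @return Character scalar, the full cassette sequence (exactly
#'   `config$totalLength` nt).
#' @export
assembleCassette <- function(spacer, repairArm,
                             config = cassetteDesignConfig()) {
  if (nchar(spacer) != config$spacerLength)
    stop("spacer must be ", config$spacerLength, " nt")
  if (nchar(repairArm) != config$armLength)
    stop("repair arm must be ", config$armLength, " nt")
  full <- paste0(config$prime5, repairArm, config$junction, spacer,
                 config$prime3)
  stopifnot(nchar(full) == config$totalLength)
  full
}

#' Recover the spacer slot from a full cassette sequence
#'
#' @param full Full cassette sequence(s).
#' @param config Layout from [cassetteDesignConfig()].
#' @return Character vector of spacers.
#' @export
cassetteSpacer <- function(full, config = cassetteDesignConfig()) {
  start <- nchar(config$prime5) + config$armLength + nchar(config$junction)
  substr(full, start + 1L, start + config$spacerLength)
}

#' Design the full oligo pool for a target set
#'
#' Runs variant enumeration, spacer selection, repair-arm design and
#' cassette assembly over every targeted residue, collecting design
#' failures (no PAM in window, arm out of bounds, no synonymous
#' disruption, ...) into a log instead of failing. Residues assigned to
#' several sublibraries get a comma-joined `sublibrary` field (the
#' physical cassette is the same). Design is deterministic: identical
#' inputs and configuration give byte-identical pools.
#'
#' @param geneModels Named list of [GeneModel-class] objects.
#' @param targetSet A [TargetSet-class].
#' @param config Design configuration from [cassetteDesignConfig()].
#' @param mutationAlphabet,includeControls Passed to
#'   [enumerateVariants()].
#' @return An [OligoPool-class].
#' @export
designLibrary <- function(geneModels, targetSet,
                          config = cassetteDesignConfig(),
                          mutationAlphabet = NULL,
                          includeControls = TRUE) {
  specs <- enumerateVariants(targetSet, geneModels, mutationAlphabet,
                             includeControls)
  t <- targets(targetSet)
  subKey <- vapply(split(t$sublibrary, paste(t$gene, t$position)),
                   function(s) paste(sort(unique(s)), collapse = ","),
                   character(1))
  fails <- list(attr(specs, "control_unavailable"))
  fails[[1L]]$mut_aa <- fails[[1L]]$wt_aa
  rows <- list(); seqs <- character(0)
  spacerCache <- list()
  for (i in seq_len(nrow(specs))) {
    v <- specs[i, , drop = FALSE]
    gm <- geneModels[[v$gene]]
    key <- paste(v$gene, v$position)
    if (is.null(spacerCache[[key]]))
      spacerCache[[key]] <- list(sp = selectSpacer(gm, v$position,
                                                   config$searchWindow,
                                                   config$spacerLength))
    sp <- spacerCache[[key]]$sp
    fail <- function(reason) {
      data.frame(gene = v$gene, position = v$position, wt_aa = v$wt_aa,
                 mut_aa = v$mut_aa, reason = reason,
                 stringsAsFactors = FALSE)
    }
    if (is.null(sp)) {
      fails[[length(fails) + 1L]] <- fail("no-pam-in-window")
      next
    }
    codons <- if (config$multiCodon && !v$is_control)
      codonsForAA(v$mut_aa)
    else
      NA_character_  # single design with the policy codon
    for (cod in codons) {
      arm <- designRepairArm(gm, v, sp, config$armLength,
                             codonOverride = if (is.na(cod)) NULL else cod)
      if (is.character(arm)) {
        fails[[length(fails) + 1L]] <- fail(arm)
        next
      }
      id <- paste0(v$gene, "_", v$wt_aa, v$position,
                   if (v$is_control) "syn" else v$mut_aa,
                   if (config$multiCodon && !v$is_control)
                     paste0(".", arm$mut_codon) else "")
      rows[[length(rows) + 1L]] <- data.frame(
        cassette_id = id, gene = v$gene, position = v$position,
        wt_aa = v$wt_aa, mut_aa = v$mut_aa, is_control = v$is_control,
        spacer = sp$spacer, pam = sp$pam, pam_strand = sp$pam_strand,
        pam_disruption = arm$pam_disruption,
        sublibrary = unname(subKey[key]),
        stringsAsFactors = FALSE)
      seqs <- c(seqs, assembleCassette(sp$spacer, arm$arm, config))
    }
  }
  design <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cassette_id = character(0), gene = character(0),
               position = integer(0), wt_aa = character(0),
               mut_aa = character(0), is_control = logical(0),
               spacer = character(0), pam = character(0),
               pam_strand = character(0), pam_disruption = character(0),
               sublibrary = character(0))
  rownames(design) <- NULL
  failures <- do.call(rbind, lapply(fails, function(f)
    f[, c("gene", "position", "wt_aa", "mut_aa", "reason"), drop = FALSE]))
  if (is.null(failures))
    failures <- data.frame(gene = character(0), position = integer(0),
                           wt_aa = character(0), mut_aa = character(0),
                           reason = character(0))
  rownames(failures) <- NULL
  sset <- DNAStringSet(seqs)
  names(sset) <- design$cassette_id
  new("OligoPool", design = design, sequences = sset, failures = failures)
}

#' Write an oligo pool to FASTA + design TSV
#'
#' @param pool An [OligoPool-class].
#' @param fastaPath FASTA of full cassette sequences (ids = cassette ids).
#' @param tsvPath Design table TSV.
#' @param failPath Optional design-failure log TSV.
#' @return Invisibly, the paths written.
#' @export
writeOligoPool <- function(pool, fastaPath, tsvPath, failPath = NULL) {
  stopifnot(is(pool, "OligoPool"))
  if (nrow(cassetteDesign(pool)) == 0L) stop("empty pool")
  writeXStringSet(cassetteSequences(pool), fastaPath)
  utils::write.table(cassetteDesign(pool), tsvPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(failPath))
    utils::write.table(designFailures(pool), failPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, tsvPath, failPath))
}

#' Read an oligo pool written by [writeOligoPool()]
#'
#' @param fastaPath Cassette FASTA path.
#' @param tsvPath Design TSV path.
#' @param failPath Optional failure-log TSV path.
#' @return An [OligoPool-class].
#' @export
readOligoPool <- function(fastaPath, tsvPath, failPath = NULL) {
  seqs <- readDNAStringSet(fastaPath)
  design <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  design$position <- as.integer(design$position)
  design$is_control <- as.logical(design$is_control)
  if (!identical(names(seqs), design$cassette_id))
    seqs <- seqs[design$cassette_id]
  failures <- if (!is.null(failPath))
    utils::read.delim(failPath, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), position = integer(0),
                  wt_aa = character(0), mut_aa = character(0),
                  reason = character(0))
  new("OligoPool", design = design, sequences = seqs, failures = failures)
}

# Synthetic vector context flanking the cassette in the sequenced amplicon
# (110 nt each side of the 230-nt cassette -> 450-nt region).
.FLANK5 <- paste0(
  "AGTCCTGAACGGTACCTTAGCGATCGGTTACCAGTGCTTAGGCAACTCGT",
  "AGGCTTGACCATCGGAATTCGCTAGACCGGTTAACGTCCATGGCTTAGCA",
  "GACTGGTTCA")
.FLANK3 <- paste0(
  "TCAGGATCCGTTAACCGGTATGCCTTAGCTAACGGATCGTTCACCAGGTA",
  "CTTGAGCCATCGGTTAGCAAGCTTGACCGTACGGATCTTAGCAACTGGTC",
  "ATCCGGTACA")

#' Sequenced amplicon for each cassette
#'
#' The sequenced region is the cassette embedded in its fixed vector
#' context: `flank5 | cassette | flank3`. With the default 110-nt flanks
#' and 230-nt cassettes this is the ~450-nt region the read mapper and
#' the read simulator operate on.
#'
#' @param pool An [OligoPool-class] (or named `DNAStringSet` of
#'   cassettes).
#' @param flank5,flank3 Vector flank sequences.
#' @return Named `DNAStringSet` of amplicons.
#' @export
cassetteAmplicons <- function(pool, flank5 = .FLANK5, flank3 = .FLANK3) {
  seqs <- if (is(pool, "OligoPool")) cassetteSequences(pool) else pool
  out <- DNAStringSet(paste0(flank5, as.character(seqs), flank3))
  names(out) <- names(seqs)
  out
}
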