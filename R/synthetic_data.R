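# Synthetic screen generator: gene panels, selection with known fitness,
# and error-bearing barcoded paired-end amplicon reads with ground truth.

.BASES <- c("A", "C", "G", "T")

# deterministic random DNA using the current RNG stream
.randomDNA <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic gene panel with target residues
#'
#' Builds random gene models (ATG start, stop codon, no internal stops,
#' flanks long enough for repair-arm design) and picks target residues
#' whose wild-type amino acid has at least two codons (so every residue
#' can carry a synonymous control). Residues are assigned functional
#' categories cyclically and collected into a sublibrary panel mirroring
#' the screen layout (one sublibrary per category).
#'
#' @param nGenes Number of genes.
#' @param nResiduesPerGene Targeted residues per gene.
#' @param nCodons Codons per CDS (excluding the stop).
#' @param flank Flank length on each side of the CDS, in nt.
#' @param seed Optional RNG seed.
#' @return A list with `geneModels` (named list of [GeneModel-class]),
#'   `targetSet` (a [TargetSet-class]), and `panel` (the panel
#'   `data.frame` used).
#' @export
syntheticPanel <- function(nGenes = 3L, nResiduesPerGene = 5L,
                           nCodons = 60L, flank = 90L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(flank >= 75L)  # must host a 142-nt arm around edge codons
  cats <- siteCategories()
  geneModels <- list()
  rows <- list()
  for (g in seq_len(nGenes)) {
    gname <- sprintf("synGene%02d", g)
    repeat {
      body <- .randomDNA(3L * (nCodons - 1L))
      cds <- paste0("ATG", body, "TAA")
      aa <- .translateDNA(cds)
      if (!grepl("\\*", substr(aa, 1L, nCodons))) break
    }
    seqfull <- paste0(.randomDNA(flank), cds, .randomDNA(flank))
    gm <- GeneModel(gname, seqfull, flank, flank + nchar(cds))
    geneModels[[gname]] <- gm
    prot <- as.character(geneProtein(gm))
    elig <- which(!strsplit(prot, "")[[1L]] %in% c("M", "W"))
    elig <- elig[elig > 1L]  # keep the start codon intact
    pos <- sort(sample(elig, nResiduesPerGene))
    rows[[g]] <- data.frame(
      gene = gname, position = pos,
      category = cats[((seq_along(pos) - 1L) %% length(cats)) + 1L],
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  panel <- data.frame(
    sublibrary = c("G1", "G2", "G4", "G5"),
    category = c("active_site", "dna_binding", "dimerization", "predicted"),
    stringsAsFactors = FALSE)
  panel$genes <- rep(list(names(geneModels)), nrow(panel))
  proteins <- lapply(geneModels, function(g) as.character(geneProtein(g)))
  ts <- buildTargetSets(ann, panel = panel, proteins = proteins)
  list(geneModels = geneModels, targetSet = ts, panel = panel)
}

#' Skewed cassette abundances
#'
#' Log-normal relative abundances (normalized to sum 1), emulating the
#' uneven cassette representation of a cloned pool.
#'
#' @param ids Cassette ids.
#' @param sdlog Log-normal shape parameter; 0 gives a uniform pool.
#' @param seed Optional RNG seed.
#' @return Named numeric vector of fractions summing to 1.
#' @export
skewedAbundances <- function(ids, sdlog = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rlnorm(length(ids), meanlog = 0, sdlog = sdlog)
  p <- w / sum(w)
  names(p) <- ids
  p
}

#' Simulate multiplicative selection on a cassette pool
#'
#' Deterministic expectation: after `epochs` selection epochs, cassette
#' `i` with fitness `f_i` (log2-enrichment units per epoch) has
#' post-selection frequency `p_i * 2^(f_i * epochs)` renormalized over
#' the pool, so its expected log2-fold frequency enrichment relative to a
#' neutral (`f = 0`) cassette is exactly `f_i * epochs`. Observed counts
#' are multinomial draws of `depth` reads from the pre- and
#' post-selection frequencies.
#'
#' @param abundances Named pre-selection fractions (nonnegative, sum 1
#'   within 1e-9; see [skewedAbundances()]).
#' @param fitness Named fitness values in log2 units per epoch; cassettes
#'   absent from the map get `f = 0`.
#' @param epochs Number of selection epochs (serial transfers); `t >= 0`.
#' @param depth Sampling depth per timepoint (multinomial size).
#' @param seed Optional RNG seed.
#' @return A list with `counts_pre`, `counts_post` (named integer
#'   vectors) and `truth` (`data.frame`: `cassette_id`, `f`, `p_pre`,
#'   `p_post`, `count_pre`, `count_post`).
#' @examples
#' sim <- simulateSelection(c(a = 0.5, b = 0.5), c(a = 1), epochs = 1,
#'                          depth = 1000, seed = 1)
#' sim$truth$p_post  # expectation (2/3, 1/3)
#' @export
simulateSelection <- function(abundances, fitness = numeric(0), epochs = 1,
                              depth = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(abundances) > 0, all(abundances >= 0), epochs >= 0,
            depth > 0)
  if (sum(abundances) == 0) stop("all-zero abundances")
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", sum(abundances), ")")
  ids <- names(abundances)
  if (is.null(ids)) stop("abundances must be named by cassette id")
  f <- stats::setNames(numeric(length(ids)), ids)
  f[intersect(names(fitness), ids)] <-
    fitness[intersect(names(fitness), ids)]
  if (any(!is.finite(f))) stop("fitness values must be finite")
  w <- abundances * 2^(f * epochs)
  pPost <- w / sum(w)
  cPre <- as.integer(stats::rmultinom(1L, depth, abundances))
  cPost <- as.integer(stats::rmultinom(1L, depth, pPost))
  truth <- data.frame(cassette_id = ids, f = unname(f),
                      p_pre = unname(abundances), p_post = unname(pPost),
                      count_pre = cPre, count_post = cPost,
                      stringsAsFactors = FALSE)
  list(counts_pre = stats::setNames(cPre, ids),
       counts_post = stats::setNames(cPost, ids),
       truth = truth)
}

# i.i.d. substitution errors over a character vector of reads
.addErrors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  stopifnot(rate < 1)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  hit <- which(nerr > 0L)
  if (!length(hit)) return(reads)
  # event list: (read index, position); positions unique within a read
  ev <- do.call(rbind, lapply(hit, function(i)
    cbind(i, sample.int(lens[i], nerr[i]))))
  orig <- substr(reads[ev[, 1L]], ev[, 2L], ev[, 2L])
  # substitute with a uniformly chosen different base
  altTable <- t(vapply(.BASES, function(b) setdiff(.BASES, b),
                       character(3)))
  newb <- altTable[cbind(match(orig, .BASES),
                         sample.int(3L, nrow(ev), replace = TRUE))]
  # apply per within-read rank so each round touches a read at most once
  rank <- stats::ave(ev[, 1L], ev[, 1L], FUN = seq_along)
  for (r in seq_len(max(rank))) {
    sel <- rank == r
    i <- ev[sel, 1L]; p <- ev[sel, 2L]
    reads[i] <- paste0(substr(reads[i], 1L, p - 1L), newb[sel],
                       substr(reads[i], p + 1L, lens[i]))
  }
  reads
}

#' Simulate barcoded paired-end amplicon reads
#'
#' For each of the `counts[i]` molecules of cassette `i`, emits one read
#' pair from its amplicon: R1 is the sample barcode followed by the 5'
#' amplicon prefix, R2 is the reverse complement of the 3' amplicon
#' suffix, both of length `readLength`, with i.i.d. substitution errors
#' at `errorRate` per base (barcode included). Qualities are a constant
#' placeholder when written to FASTQ.
#'
#' @param amplicons Named `DNAStringSet` (or character vector) of
#'   amplicon sequences (see [cassetteAmplicons()]).
#' @param counts Named integer vector of molecule counts per cassette.
#' @param barcode Sample barcode sequence prefixed to R1.
#' @param readLength Read length in nt; reads must overlap
#'   (`2 * readLength >= amplicon length + barcode length`).
#' @param errorRate Per-base substitution error rate in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return A list with `r1`, `r2` (character vectors, names = read ids)
#'   and `truth` (`data.frame`: `read_id`, `cassette_id`).
#' @export
simulateAmpliconReads <- function(amplicons, counts, barcode,
                                  readLength = 250L, errorRate = 0.003,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amp <- stats::setNames(as.character(amplicons), names(amplicons))
  counts <- counts[counts > 0]
  if (!all(names(counts) %in% names(amp)))
    stop("counted cassette(s) lack an amplicon sequence")
  if (readLength <= nchar(barcode))
    stop("reads shorter than the sample barcode")
  alen <- nchar(amp[names(counts)])
  if (any(2L * readLength < alen + nchar(barcode)))
    stop("reads too short to overlap across the amplicon")
  ids <- rep(names(counts), counts)
  seqs <- amp[ids]
  n <- length(ids)
  r1 <- paste0(barcode, substr(seqs, 1L, readLength - nchar(barcode)))
  r2 <- as.character(reverseComplement(DNAStringSet(
    substr(seqs, nchar(seqs) - readLength + 1L, nchar(seqs)))))
  r1 <- .addErrors(r1, errorRate)
  r2 <- .addErrors(r2, errorRate)
  readId <- sprintf("read%07d", seq_len(n))
  names(r1) <- readId
  names(r2) <- readId
  list(r1 = r1, r2 = r2,
       truth = data.frame(read_id = readId, cassette_id = unname(ids),
                          stringsAsFactors = FALSE))
}

#' Write paired reads to FASTQ
#'
#' Constant placeholder base qualities (`I`, Q40) are used throughout:
#' the analysis stages are quality-agnostic.
#'
#' @param r1,r2 Named character vectors (or `DNAStringSet`s) of reads.
#' @param r1Path,r2Path Output FASTQ paths.
#' @return Invisibly, the paths written.
#' @export
writePairedFastq <- function(r1, r2, r1Path, r2Path) {
  for (side in list(list(x = r1, p = r1Path), list(x = r2, p = r2Path))) {
    x <- DNAStringSet(side$x)
    qual <- BStringSet(strrep("I", Biostrings::width(x)))
    writeXStringSet(x, side$p, format = "fastq", qualities = qual)
  }
  invisible(c(r1Path, r2Path))
}

#' Read paired FASTQ files
#'
#' @param r1Path,r2Path FASTQ paths (gzip allowed).
#' @return A list with `r1`, `r2` as named character vectors.
#' @export
readPairedFastq <- function(r1Path, r2Path) {
  r1 <- readDNAStringSet(r1Path, format = "fastq")
  r2 <- readDNAStringSet(r2Path, format = "fastq")
  list(r1 = stats::setNames(as.character(r1), names(r1)),
       r2 = stats::setNames(as.character(r2), names(r2)))
}

#' Simulate a complete pre/post selection screen
#'
#' End-to-end generator: skewed pre-selection pool, multiplicative
#' selection with the given per-cassette fitness, and barcoded
#' paired-end reads for the pre- and post-selection samples pooled into
#' one R1/R2 read set (demultiplexing splits them back). Optionally
#' writes FASTQ, the truth TSV and a YAML echo of the parameters.
#'
#' @param pool An [OligoPool-class].
#' @param fitness Named fitness vector (log2 units/epoch); unnamed
#'   cassettes are neutral.
#' @param barcodes Named character vector of sample barcodes; must
#'   contain entries `pre` and `post`.
#' @param epochs,depth See [simulateSelection()].
#' @param readLength,errorRate See [simulateAmpliconReads()].
#' @param sdlog Abundance skew (see [skewedAbundances()]).
#' @param outDir Optional directory for `reads_R1.fastq`,
#'   `reads_R2.fastq`, `truth.tsv`, `params.yaml`.
#' @param seed Optional RNG seed governing the full simulation.
#' @return A list with `r1`, `r2`, `truth` (selection truth table),
#'   `readTruth` (per-read cassette attribution), `counts_pre`,
#'   `counts_post`, `amplicons`, and (if written) `paths`.
#' @export
simulateScreen <- function(pool, fitness, barcodes = c(pre = "ACGTACGT",
                                                       post = "TGCATGCA"),
                           epochs = 1, depth = 1e5, readLength = 250L,
                           errorRate = 0.003, sdlog = 0.75, outDir = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("pre", "post") %in% names(barcodes)))
  ids <- cassetteDesign(pool)$cassette_id
  amp <- cassetteAmplicons(pool)
  p0 <- skewedAbundances(ids, sdlog = sdlog)
  sel <- simulateSelection(p0, fitness, epochs = epochs, depth = depth)
  rdPre <- simulateAmpliconReads(amp, sel$counts_pre, barcodes[["pre"]],
                                 readLength, errorRate)
  rdPost <- simulateAmpliconReads(amp, sel$counts_post, barcodes[["post"]],
                                  readLength, errorRate)
  rename <- function(x, s) stats::setNames(unname(x), paste0(s, "_", names(x)))
  r1 <- c(rename(rdPre$r1, "pre"), rename(rdPost$r1, "post"))
  r2 <- c(rename(rdPre$r2, "pre"), rename(rdPost$r2, "post"))
  readTruth <- rbind(
    data.frame(sample = "pre", read_id = paste0("pre_", rdPre$truth$read_id),
               cassette_id = rdPre$truth$cassette_id),
    data.frame(sample = "post", read_id = paste0("post_", rdPost$truth$read_id),
               cassette_id = rdPost$truth$cassette_id))
  out <- list(r1 = r1, r2 = r2, truth = sel$truth, readTruth = readTruth,
              counts_pre = sel$counts_pre, counts_post = sel$counts_post,
              amplicons = amp, barcodes = barcodes)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outDir, c("reads_R1.fastq", "reads_R2.fastq",
                                 "truth.tsv", "params.yaml"))
    writePairedFastq(r1, r2, paths[1L], paths[2L])
    utils::write.table(sel$truth, paths[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(list(epochs = epochs, depth = depth,
                          read_length = readLength, error_rate = errorRate,
                          sdlog = sdlog, seed = seed,
                          barcodes = as.list(barcodes)), paths[4L])
    out$paths <- stats::setNames(paths, c("r1", "r2", "truth", "params"))
  }
  out
}
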