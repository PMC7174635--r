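# Shared fixtures and independent brute-force oracles.

# Toy gene: 120-nt segment, 20-codon CDS (incl. stop) at [30, 90), + strand.
# Printed literally so spacer-selection tests have a fixed, inspectable
# substrate; flanks are too short for full-length arms, so arm tests use
# armLength = 60.
toyGeneSeq <- paste0(
  "AACGTTAGCCTAGGATCCAAGCTTGACGTA",                               # 5' flank
  "ATGGTTCTGAAAGGCTTCACCGAAGATCGTTGGCCGCAGAACTCTGTTCTGGCAGAATAA", # CDS
  "TCAGGATCCGTTAACCGGTATGCCTTAGCT"                                # 3' flank
)
toyGene <- function() GeneModel("toy", toyGeneSeq, 30L, 90L, "+")

# larger random panel used by several suites (fixed seed)
smallPanel <- function(seed = 101, nGenes = 2, nRes = 3) {
  syntheticPanel(nGenes = nGenes, nResiduesPerGene = nRes, seed = seed)
}

# --- oracles ---------------------------------------------------------------

# all-pairs distance scan: residues with any atom within radius of any
# ligand atom
oracleLigandScan <- function(atoms, radius) {
  lig <- atoms[atoms$is_ligand, , drop = FALSE]
  pol <- atoms[!atoms$is_ligand, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(pol))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((pol$x[i] - lig$x[j])^2 + (pol$y[i] - lig$y[j])^2 +
                (pol$z[i] - lig$z[j])^2)
      if (d <= radius) { keep <- c(keep, pol$residue_index[i]); break }
    }
  }
  sort(unique(as.integer(keep)))
}

# character-level Hamming distance
oracleHamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive-shift overlap merge: largest overlap in [minOverlap, min(n1,n2)]
# whose mismatch rate is within maxRate; merged = R1 + non-overlapping tail
# of revcomp(R2)
oracleMerge <- function(r1, r2, minOverlap, maxRate) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  n1 <- nchar(r1); n2 <- nchar(rc)
  for (o in seq(min(n1, n2), minOverlap)) {
    a <- substr(r1, n1 - o + 1, n1)
    b <- substr(rc, 1, o)
    if (oracleHamming(a, b) <= maxRate * o)
      return(list(merged = paste0(r1, substr(rc, o + 1, n2)), overlap = o))
  }
  NULL
}

# brute-force NGG scan on both strands; returns all candidate cut sites
# with their distance to the codon midpoint
oracleSpacerScan <- function(gm, residue, window = 30L) {
  seq <- as.character(gm@sequence)
  len <- nchar(seq)
  cds0 <- gm@cdsStart
  codonStart <- if (gm@strand == "+") cds0 + 3 * (residue - 1) else
    gm@cdsEnd - 3 * residue
  mid <- codonStart + 1.5
  out <- list()
  for (p in 0:(len - 3)) {
    tri <- substr(seq, p + 1, p + 3)
    if (substr(tri, 2, 3) == "GG" && p >= 20) {
      cut <- p - 3
      if (abs(cut - mid) <= window)
        out[[length(out) + 1]] <- data.frame(
          strand = "+", proto_start = p - 20, cut = cut,
          dist = abs(cut - mid))
    }
    if (substr(tri, 1, 2) == "CC" && p + 23 <= len) {
      cut <- p + 6
      if (abs(cut - mid) <= window)
        out[[length(out) + 1]] <- data.frame(
          strand = "-", proto_start = p + 3, cut = cut,
          dist = abs(cut - mid))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# random DNA string helper
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# substitute k distinct random positions of a sequence
mutateSeq <- function(s, k) {
  if (k == 0) return(s)
  pos <- sample.int(nchar(s), k)
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  s
}
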