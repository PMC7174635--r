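# Variant enumeration, spacer/PAM choice, repair arms, cassette assembly.

test_that("variant enumeration yields 19 substitutions plus a control", {
  gm <- toyGene()
  panel <- data.frame(sublibrary = "G1", category = "active_site",
                      stringsAsFactors = FALSE)
  panel$genes <- list("toy")
  mkTS <- function(pos) {
    buildTargetSets(
      data.frame(gene = "toy", position = pos, category = "active_site"),
      panel = panel,
      proteins = list(toy = as.character(geneProtein(gm))))
  }
  # residue 3 is Leu (6 codons): 19 + 1 control
  vl <- enumerateVariants(mkTS(3), list(toy = gm))
  expect_equal(nrow(vl), 20)
  expect_equal(sum(vl$is_control), 1)
  expect_equal(sort(unique(vl$wt_aa)), "L")
  # residue 11 is Trp (single codon): 19 specs, control logged
  vw <- enumerateVariants(mkTS(11), list(toy = gm))
  expect_equal(nrow(vw), 19)
  expect_equal(sum(vw$is_control), 0)
  log <- attr(vw, "control_unavailable")
  expect_equal(nrow(log), 1)
  expect_match(log$reason, "single-codon")
})

test_that("variant ordering is gene-major, position-minor, deterministic", {
  sp <- smallPanel(seed = 77)
  v <- enumerateVariants(sp$targetSet, sp$geneModels)
  key <- order(v$gene, v$position, v$mut_aa, v$is_control)
  expect_equal(key, seq_len(nrow(v)))
  v2 <- enumerateVariants(sp$targetSet, sp$geneModels)
  expect_identical(v, v2)
})

test_that("spacer choice equals the exhaustive brute-force scan", {
  gm <- toyGene()
  for (res in c(2, 5, 8, 12, 15)) {
    cand <- oracleSpacerScan(gm, res, window = 30)
    got <- selectSpacer(gm, res, searchWindow = 30)
    if (is.null(cand)) {
      expect_null(got)
      next
    }
    best <- cand[order(cand$dist, cand$strand != "+", cand$proto_start), ][1, ]
    expect_equal(got$distance, best$dist, tolerance = 1e-12)
    expect_equal(got$pam_strand, best$strand)
    expect_equal(got$proto_start, best$proto_start)
    # the reported spacer+PAM exist verbatim in the gene sequence
    seq <- as.character(gm@sequence)
    site <- if (got$pam_strand == "+") {
      substr(seq, got$proto_start + 1, got$pam_end)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(seq, got$pam_start + 1, got$proto_end))))
    }
    expect_equal(site, paste0(got$spacer, got$pam))
    expect_match(got$pam, "^.GG$")
  }
})

test_that("spacer ties break to the + strand", {
  # symmetric construct: CCN...NGG equidistant cut sites around the codon
  # cut(+): pam at p -> p-3 ; cut(-): CC at q -> q+6
  seq <- paste0(strrep("A", 25), "CCTAA", "ATG", "AAATTTGGG", "TAA",
                "AATGG", strrep("A", 25))
  # CDS at [30, 45): codons ATG AAA TTT GGG TAA; target residue 3 (TTT)
  gm <- GeneModel("tie", seq, 30L, 45L)
  got <- selectSpacer(gm, 3, searchWindow = 30)
  cand <- oracleSpacerScan(gm, 3, window = 30)
  best <- cand[order(cand$dist, cand$strand != "+", cand$proto_start), ][1, ]
  expect_equal(got$pam_strand, best$strand)
  expect_equal(got$distance, best$dist)
})

test_that("repair arms install exactly the intended protein change", {
  gm <- toyGene()
  wt <- as.character(geneProtein(gm))
  # residue 2: V -> W substitution
  v <- data.frame(gene = "toy", position = 2, wt_aa = "V", mut_aa = "W",
                  is_control = FALSE)
  sp <- selectSpacer(gm, 2)
  arm <- designRepairArm(gm, v, sp, armLength = 60)
  expect_type(arm, "list")
  cds <- substr(arm$edited_segment, 31, 90)
  prot <- sub("\\*$", "",
              as.character(Biostrings::translate(Biostrings::DNAString(cds))))
  diffs <- which(strsplit(prot, "")[[1]] != strsplit(wt, "")[[1]])
  expect_equal(diffs, 2L)
  expect_equal(substr(prot, 2, 2), "W")
  # synonymous control: protein unchanged, DNA changed
  vc <- data.frame(gene = "toy", position = 2, wt_aa = "V", mut_aa = "V",
                   is_control = TRUE)
  armc <- designRepairArm(gm, vc, sp, armLength = 60)
  cdsc <- substr(armc$edited_segment, 31, 90)
  protc <- sub("\\*$", "",
               as.character(Biostrings::translate(Biostrings::DNAString(cdsc))))
  expect_equal(protc, wt)
  expect_false(identical(armc$edited_segment, as.character(gm@sequence)))
})

test_that("edits overlapping the PAM need no extra disruption", {
  sp0 <- smallPanel(seed = 42, nGenes = 3, nRes = 5)
  pool <- designLibrary(sp0$geneModels, sp0$targetSet)
  d <- cassetteDesign(pool)
  overl <- d$pam_disruption == "edit-overlaps-PAM"
  expect_true(any(overl))
  expect_true(any(!overl))
  # for overlap cases the repair arm differs from wild type only at the
  # intended codon footprint (<= 3 contiguous bases)
  cfg <- cassetteDesignConfig()
  for (i in utils::head(which(overl), 5)) {
    gm <- sp0$geneModels[[d$gene[i]]]
    spc <- selectSpacer(gm, d$position[i], cfg$searchWindow)
    varnt <- d[i, c("gene", "position", "wt_aa", "mut_aa", "is_control")]
    arm <- designRepairArm(gm, varnt, spc, cfg$armLength)
    difs <- which(strsplit(arm$edited_segment, "")[[1]] !=
                  strsplit(as.character(gm@sequence), "")[[1]])
    expect_lte(max(difs) - min(difs), 2)
  }
})

test_that("cassette layout arithmetic and spacer round trip hold", {
  cfg <- cassetteDesignConfig()
  expect_equal(nchar(cfg$prime5) + cfg$armLength + nchar(cfg$junction) +
               cfg$spacerLength + nchar(cfg$prime3), 230)
  expect_equal(c(nchar(cfg$prime5), cfg$armLength, nchar(cfg$junction),
                 cfg$spacerLength, nchar(cfg$prime3)),
               c(15, 142, 20, 20, 33))
  spacer <- randSeq(20); arm <- randSeq(142)
  full <- assembleCassette(spacer, arm, cfg)
  expect_equal(nchar(full), 230)
  expect_equal(cassetteSpacer(full, cfg), spacer)
  expect_error(cassetteDesignConfig(armLength = 100), "layout")
})

test_that("designed cassettes are 230 nt, re-cut resistant, deterministic", {
  sp0 <- smallPanel(seed = 11, nGenes = 2, nRes = 4)
  pool <- designLibrary(sp0$geneModels, sp0$targetSet)
  seqs <- as.character(cassetteSequences(pool))
  expect_true(all(nchar(seqs) == 230))
  d <- cassetteDesign(pool)
  # exhaustive string search: no perfect protospacer+NGG in any cassette
  for (i in seq_len(nrow(d))) {
    expect_false(cassetteScreen:::.hasCutSite(seqs[i], d$spacer[i]))
    # wild-type gene still carries the protospacer+PAM verbatim
    gm <- sp0$geneModels[[d$gene[i]]]
    expect_true(cassetteScreen:::.hasCutSite(as.character(gm@sequence),
                                             d$spacer[i]))
  }
  # byte-identical on re-run
  pool2 <- designLibrary(sp0$geneModels, sp0$targetSet)
  expect_identical(cassetteDesign(pool), cassetteDesign(pool2))
  expect_identical(as.character(cassetteSequences(pool2)), seqs)
})

test_that("oligo pools round-trip through FASTA + TSV", {
  sp0 <- smallPanel(seed = 12, nGenes = 1, nRes = 2)
  pool <- designLibrary(sp0$geneModels, sp0$targetSet)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  fl <- tempfile(fileext = ".tsv")
  writeOligoPool(pool, fa, tsv, fl)
  back <- readOligoPool(fa, tsv, fl)
  expect_identical(cassetteDesign(back), cassetteDesign(pool))
  expect_equal(as.character(cassetteSequences(back)),
               as.character(cassetteSequences(pool)))
  fasta <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(fasta), nrow(cassetteDesign(pool)))
})

test_that("gene models round-trip through FASTA + coordinate TSV", {
  sp0 <- smallPanel(seed = 13, nGenes = 2, nRes = 2)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeGeneModels(sp0$geneModels, fa, tsv)
  back <- readGeneModels(fa, tsv)
  for (g in names(sp0$geneModels)) {
    expect_equal(as.character(back[[g]]@sequence),
                 as.character(sp0$geneModels[[g]]@sequence))
    expect_equal(as.character(geneProtein(back[[g]])),
                 as.character(geneProtein(sp0$geneModels[[g]])))
  }
})

test_that("minus-strand gene models design valid cassettes", {
  # reverse-complement the toy gene: CDS coordinates flip
  rcSeq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toyGeneSeq)))
  gmRC <- GeneModel("toyrc", rcSeq, 30L, 90L, "-")
  expect_equal(as.character(geneProtein(gmRC)),
               as.character(geneProtein(toyGene())))
  v <- data.frame(gene = "toyrc", position = 5, wt_aa = "G", mut_aa = "R",
                  is_control = FALSE)
  sp <- selectSpacer(gmRC, 5)
  arm <- designRepairArm(gmRC, v, sp, armLength = 60)
  expect_type(arm, "list")
  cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(arm$edited_segment, 31, 90))))
  prot <- sub("\\*$", "",
              as.character(Biostrings::translate(Biostrings::DNAString(cds))))
  expect_equal(substr(prot, 5, 5), "R")
})
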