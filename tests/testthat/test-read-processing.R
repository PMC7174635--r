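# Pair merging, demultiplexing, identity/mismatch mapping, efficiencies.

rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

test_that("pair merging handles partial and complete overlap", {
  # 10 + 10 nt with a true 6-nt overlap -> merged length 14
  amp <- "ACGTACGGTTCAGA"  # 14 nt
  r1 <- substr(amp, 1, 10)
  r2 <- rc(substr(amp, 5, 14))
  m <- mergePairs(r1, r2, minOverlap = 4)
  expect_true(m$ok)
  expect_equal(nchar(m$merged), 14)
  expect_equal(m$merged, amp)
  expect_equal(m$overlap, 6)
  # complete overlap: R2 = revcomp(R1) -> merged = R1
  m2 <- mergePairs(r1, rc(r1), minOverlap = 4)
  expect_equal(m2$merged, r1)
  expect_equal(m2$overlap, 10)
  # no legal overlap -> rejection, not error
  m3 <- mergePairs("AAAAAAAAAA", "CCCCCCCCCC", minOverlap = 4,
                   maxMismatchRate = 0)
  expect_false(m3$ok)
  expect_true(is.na(m3$merged))
})

test_that("overlap disagreements resolve in favor of R1", {
  amp <- randSeq(30)
  r1 <- substr(amp, 1, 20)
  r2seq <- substr(amp, 11, 30)
  substr(r2seq, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r2seq, 3, 3))[1]
  m <- mergePairs(r1, rc(r2seq), minOverlap = 5, maxMismatchRate = 0.2)
  expect_true(m$ok)
  # position 13 of merged comes from R1, despite the R2 disagreement
  expect_equal(substr(m$merged, 1, 20), r1)
})

test_that("merging agrees with the exhaustive-shift oracle", {
  set.seed(501)
  for (i in 1:100) {
    amp <- randSeq(sample(60:120, 1))
    rl <- sample(40:70, 1)
    r1 <- mutateSeq(substr(amp, 1, rl), rpois(1, 1))
    r2 <- mutateSeq(rc(substr(amp, nchar(amp) - rl + 1, nchar(amp))),
                    rpois(1, 1))
    got <- mergePairs(r1, r2, minOverlap = 10, maxMismatchRate = 0.15)
    ora <- oracleMerge(r1, r2, minOverlap = 10, maxRate = 0.15)
    if (is.null(ora)) {
      expect_false(got$ok)
    } else {
      expect_equal(got$merged, ora$merged)
      expect_equal(got$overlap, ora$overlap)
    }
  }
})

test_that("demultiplexing assigns within tolerance and strips barcodes", {
  bc <- c(pre = "AAAACCCC", post = "GGGGTTTT")
  reads <- c(paste0("AAAACCCC", "ACGT"),   # exact
             paste0("AAAACCCG", "ACGT"),   # 1 mismatch
             paste0("AAGGCCGG", "ACGT"))   # far from both
  d <- demultiplex(reads, bc, maxMismatches = 1)
  expect_equal(d$sample, c("pre", "pre", "unassigned"))
  expect_equal(d$sequence[1:2], c("ACGT", "ACGT"))
  expect_equal(d$sequence[3], reads[3])
  # collision at configuration time
  expect_error(demultiplex(reads, c(a = "AAAA", b = "AAAT"),
                           maxMismatches = 2), "collision")
})

test_that("mapping enforces the identity and mismatch-count rules", {
  set.seed(502)
  refs <- stats::setNames(vapply(1:3, function(i) randSeq(450),
                                 character(1)), paste0("c", 1:3))
  idn <- mappingConfig("identity")       # > 98.3 %
  mmc <- mappingConfig("mismatch")       # <= 3 mismatches
  for (k in c(0, 3, 7, 8)) {
    read <- mutateSeq(refs[["c2"]], k)
    h <- bestReferenceHits(read, refs)
    expect_equal(h$best_ref, "c2")
    expect_equal(h$mismatches, k)
    ctI <- mapReads(read, refs, config = idn)
    ctM <- mapReads(read, refs, config = mmc)
    # identity rule: 7 mismatches = 98.44 % passes, 8 = 98.22 % fails
    expect_equal(unname(cassetteCounts(ctI)["c2", 1]),
                 as.integer(100 * (450 - k) / 450 > 98.3))
    # mismatch rule: pass iff k <= 3
    expect_equal(unname(cassetteCounts(ctM)["c2", 1]),
                 as.integer(k <= 3))
  }
})

test_that("equal-best reads land in the ambiguous bin and counts conserve", {
  refA <- randSeq(60)
  refB <- mutateSeq(refA, 2)
  refs <- c(a = refA, b = refB)
  # a read halfway between the two references ties
  mid <- refA
  difs <- which(strsplit(refA, "")[[1]] != strsplit(refB, "")[[1]])
  substr(mid, difs[1], difs[1]) <- substr(refB, difs[1], difs[1])
  reads <- c(refA, refB, mid, randSeq(60))
  ct <- mapReads(reads, refs, config = mappingConfig("mismatch",
                                                     maxMismatches = 1))
  expect_equal(unname(ambiguousReads(ct)), 1)
  expect_equal(sum(cassetteCounts(ct)) + sum(unmappedReads(ct)) +
               sum(ambiguousReads(ct)), sum(totalReads(ct)))
})

test_that("mapper identity equals the brute-force Hamming oracle", {
  set.seed(503)
  for (i in 1:100) {
    L <- sample(50:200, 1)
    ref <- randSeq(L)
    read <- mutateSeq(ref, sample(0:10, 1))
    h <- bestReferenceHits(read, c(r = ref))
    d <- oracleHamming(read, ref)
    expect_equal(h$mismatches, d)
    expect_equal(h$identity, 100 * (L - d) / L)
  }
})

test_that("raising the identity threshold never increases mapped counts", {
  set.seed(504)
  refs <- stats::setNames(vapply(1:5, function(i) randSeq(450),
                                 character(1)), paste0("c", 1:5))
  reads <- vapply(sample(names(refs), 200, TRUE), function(id)
    mutateSeq(refs[[id]], rpois(1, 4)), character(1), USE.NAMES = FALSE)
  prev <- NULL
  for (thr in c(95, 97, 98.3, 99, 99.9)) {
    ct <- mapReads(reads, refs,
                   config = mappingConfig("identity", identityMin = thr))
    cur <- cassetteCounts(ct)
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("error-free simulated reads recover truth counts exactly", {
  sp0 <- smallPanel(seed = 41, nGenes = 1, nRes = 3)
  pool <- designLibrary(sp0$geneModels, sp0$targetSet)
  amp <- cassetteAmplicons(pool)
  p <- skewedAbundances(names(amp), seed = 41)
  sel <- simulateSelection(p, depth = 2000, seed = 41)
  rd <- simulateAmpliconReads(amp, sel$counts_pre, "ACGTACGT",
                              errorRate = 0, seed = 41)
  pr <- processReads(rd$r1, rd$r2, c(s1 = "ACGTACGT"), amp)
  got <- cassetteCounts(pr$counts)[names(amp), "s1"]
  expect_equal(unname(got), unname(sel$counts_pre[names(amp)]))
  expect_equal(unname(unmappedReads(pr$counts)), 0)
})

test_that("editing efficiency is the mutant fraction of total reads", {
  counts <- matrix(c(50L, 30L, 15L), ncol = 1,
                   dimnames = list(c("wt", "m1", "m2"), "s1"))
  ct <- new("CassetteCounts", counts = counts,
            unmapped = c(s1 = 5), ambiguous = c(s1 = 0), total = c(s1 = 100))
  expect_equal(editingEfficiency(ct, "s1", c("m1", "m2")), 0.45)
  expect_equal(editingEfficiency(ct, "s1", character(0)), 0)
  ct0 <- new("CassetteCounts", counts = counts * 0L,
             unmapped = c(s1 = 0), ambiguous = c(s1 = 0), total = c(s1 = 0))
  expect_warning(e <- editingEfficiency(ct0, "s1", "m1"), "zero")
  expect_true(is.na(e))
})

test_that("editing efficiency tracks the simulated mutant fraction", {
  sp0 <- smallPanel(seed = 42, nGenes = 1, nRes = 3)
  pool <- designLibrary(sp0$geneModels, sp0$targetSet)
  amp <- cassetteAmplicons(pool)
  d <- cassetteDesign(pool)
  mut <- d$cassette_id[!d$is_control]
  p <- skewedAbundances(names(amp), seed = 43)
  n <- 4000
  sel <- simulateSelection(p, depth = n, seed = 43)
  rd <- simulateAmpliconReads(amp, sel$counts_pre, "ACGTACGT",
                              errorRate = 0.003, seed = 43)
  pr <- processReads(rd$r1, rd$r2, c(s1 = "ACGTACGT"), amp)
  eff <- editingEfficiency(pr$counts, "s1", mut)
  truthFrac <- sum(sel$counts_pre[mut]) / n
  expect_lt(abs(eff - truthFrac),
            3 * sqrt(truthFrac * (1 - truthFrac) / n) + 0.01)
})

test_that("base-change frequencies use the perfect-read denominator", {
  ref <- randSeq(40)
  mut5 <- ref
  substr(mut5, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut5, 5, 5))[1]
  reads <- c(rep(ref, 40), rep(mut5, 10))
  bc <- baseChangeFrequencies(reads, ref)
  expect_equal(bc$frequency[5], 10 / 40)  # changed / perfect
  expect_equal(bc$frequency[-5], rep(0, 39))
  # all perfect -> all zero
  bc0 <- baseChangeFrequencies(rep(ref, 5), ref)
  expect_equal(bc0$frequency, rep(0, 40))
  # no perfect reads -> missing with warning
  expect_warning(bcNA <- baseChangeFrequencies(rep(mut5, 3), ref),
                 "missing")
  expect_true(all(is.na(bcNA$frequency)))
  # the 95 % retention threshold: reads below it are excluded entirely
  far <- mutateSeq(ref, 4)  # 36/40 = 90 % < 95 %
  bc2 <- baseChangeFrequencies(c(rep(ref, 10), far), ref)
  expect_equal(attr(bc2, "n_retained"), 10)
  # conventional denominator option
  bc3 <- baseChangeFrequencies(reads, ref, denominator = "retained")
  expect_equal(bc3$frequency[5], 10 / 50)
})

test_that("count tables round-trip through the long TSV format", {
  counts <- matrix(c(5L, 0L, 2L, 7L, 1L, 3L), nrow = 3,
                   dimnames = list(paste0("c", 1:3), c("pre", "post")))
  ct <- new("CassetteCounts", counts = counts,
            unmapped = c(pre = 2, post = 1), ambiguous = c(pre = 0, post = 1),
            total = c(pre = 9, post = 13))
  path <- tempfile(fileext = ".tsv")
  writeCountTable(ct, path)
  back <- readCountTable(path)
  expect_equal(cassetteCounts(back), counts)
  expect_equal(unmappedReads(back), unmappedReads(ct))
  expect_equal(totalReads(back), totalReads(ct))
  # conservation invariant enforced by the class
  expect_error(new("CassetteCounts", counts = counts,
                   unmapped = c(pre = 0, post = 0),
                   ambiguous = c(pre = 0, post = 0),
                   total = c(pre = 9, post = 13)), "total")
})
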