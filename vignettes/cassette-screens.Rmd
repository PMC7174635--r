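---
title: "Trackable editing-cassette screens: models, parameters and design choices"
author: "cassetteScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trackable editing-cassette screens: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassetteScreen)
```

## The screen in one paragraph

A trackable editing screen couples genome editing to barcoding: each
designed mutation is installed from a 230-nt synthetic cassette that
carries both the Cas9 guide (spacer + NGG PAM choice) and the homology
repair template encoding the codon edit. After pooled editing, the
population is subjected to selection (for example, sub-MIC antibiotic);
sequencing the cassette amplicon before and after selection yields
per-cassette read counts, and the log2 change of a cassette's relative
frequency is its fitness (enrichment) score. Synonymous-control
cassettes — whose edits change the DNA but not the protein — experience
the same editing, cloning and sequencing pipeline without a phenotypic
effect, so their score distribution is the experiment's own null.

This vignette documents the models and conventions each stage uses, the
parameters that matter, and the choices made where the design was
genuinely open.

## Target selection

Functional residues come from two sources:

* **Feature tables** (`parseFeatureTable()`): tabular annotations
  (gene, 1-based residue position, site-type text). Site-type strings
  are normalized onto a closed category set — `active_site`,
  `dna_binding`, `dimerization`, `predicted` — through a packaged
  synonym map; strings mentioning prediction, and any unrecognized
  string (with a warning), fall into `predicted`, the catch-all
  category. Exact duplicate records collapse; out-of-range positions
  are rejected with their row index.
* **Structures** (`readStructure()`, `ligandProximalResidues()`):
  PDB-format files are parsed with `bio3d`; hetero atoms are ligand
  atoms unless their residue name is on a solvent/buffer exclusion list
  (HOH, common ions, cryoprotectants). A residue is ligand-proximal
  when any of its atoms lies within the cutoff radius of any ligand
  atom. The default radius is **5 Å** and the boundary is **inclusive**
  (distance ≤ 5.0 selects): "within a radius" is conventionally read as
  closed, and an inclusive boundary is what a distance titration probes
  cleanly. Distances are Euclidean; the implementation is a vectorized
  squared-distance matrix with a small negative-cancellation guard, and
  it is property-tested against a brute-force all-pairs scan.

`buildTargetSets()` merges both sources and assigns each
(gene, residue, category) entry to every sublibrary of the panel whose
category and gene list match, mirroring the screen's G1–G5 layout
(`regulatorPanel()` packages that bookkeeping: five sublibraries,
23 genes in the union, 34,340 designed variants in total). Residue
positions are 1-based protein coordinates in every user-facing file;
internal arrays are 0-based.

## Cassette design

```{r layout}
cassetteDesignConfig()[c("armLength", "searchWindow", "spacerLength")]
```

* **Layout.** The hard constraint is the 230-nt oligo. The default
  partition is 15-nt 5' priming | 142-nt repair arm | 20-nt junction |
  20-nt spacer | 33-nt 3' priming (the start of the sgRNA scaffold);
  all segment lengths are configurable under the fixed total. The
  142-nt arm is the maximum left over after the handles, which
  maximizes homology on either side of the edit.
* **Spacer selection** (`selectSpacer()`): both strands are scanned for
  NGG; the candidate whose blunt cut site (between protospacer
  positions 17 and 18) is nearest the target codon midpoint wins, with
  ties broken + strand first, then leftmost coordinate. The search
  window (default ±30 nt between cut and codon midpoint) keeps the
  edit within efficient HDR range; widening it rescues PAM-poor
  regions at the cost of conversion efficiency.
* **Codon policy.** Substitutions use the most used *E. coli* codon
  for the target amino acid (packaged usage table) — deterministic and
  biased toward well-expressed codons. Synonymous controls use the
  most used synonymous codon *different from* the wild-type codon.
  Residues whose wild-type amino acid has a single codon (Met, Trp)
  cannot carry a control; they are logged, never silently dropped. An
  optional multi-codon mode emits one cassette per synonymous codon of
  each substitution; the default is one codon per substitution.
* **PAM disruption.** After the codon edit, the designer checks whether
  the chosen protospacer+NGG is still perfectly matched. If the edit
  itself destroyed it, the cassette records `edit-overlaps-PAM` and no
  further change is made. Otherwise a synonymous change is sought first
  inside the NGG, then in seed bases within 10 nt of the cut site;
  candidates are tried codon-by-codon in usage order and the first that
  breaks the match is kept. Every design is then verified by exhaustive
  string search: the edited cassette must contain no perfect
  protospacer+NGG match on either strand (re-cut resistance), and
  re-translation of the edited CDS must differ from wild type at
  exactly the intended residue (nowhere, for controls). Note that a
  PAM-only disruption legitimately leaves the literal 20-mer spacer
  sequence present in the repair arm as well as in the spacer slot; the
  meaningful uniqueness property is the absence of a cuttable site, and
  that is what is enforced.
* **Determinism.** Identical inputs and configuration yield
  byte-identical pools; failures (no PAM in window, arm out of bounds,
  no legal disruption) become rows of the design log.

Strand handling: all genomic sequences are reported on the + strand of
the provided `GeneModel`; the spacer is reported on its protospacer
strand with `pam_strand` recorded. Minus-strand CDSs are supported.

## The synthetic screen generator

The generator exists to give every downstream stage inputs with known
truth. It emulates:

* **Pool skew**: log-normal relative abundances (`sdlog = 0.75` by
  default — a realistically uneven cloned pool where the 90th/10th
  percentile cassettes differ several-fold; 0 gives a uniform pool).
* **Selection**: deterministic expectation
  \(p_i' \propto p_i \cdot 2^{f_i t}\), with fitness parameterized
  directly in log2-enrichment units per epoch so that the estimand of
  the analysis equals the planted parameter. Epochs correspond to the
  serial transfers of a selection experiment; since generations per
  transfer are not modeled, an epoch is an abstract unit of selection.
  One pre and one post timepoint by default. Observed counts are
  multinomial draws at the configured depth.
* **Sequencing**: one read pair per counted molecule of a ~450-nt
  amplicon (cassette plus fixed 110-nt vector flanks). R1 is the
  sample barcode plus the 5' amplicon prefix; R2 the reverse
  complement of the 3' suffix; i.i.d. substitution errors at the
  configured per-base rate (default 0.3%, typical of merged short
  reads) apply to all bases including the barcode. Qualities are a
  constant placeholder because the analysis is quality-agnostic.

Not modeled, deliberately: PCR amplification bias and chimeras, indel
or quality-dependent errors, growth dynamics within a transfer, and
editing failure modes (the pool is assumed already edited and
verified). Passing tests on this generator therefore demonstrate that
the statistical pipeline recovers parameters under multinomial and
substitution noise — not that it is robust to jackpot effects or
indel-rich platforms.

## Read processing

* **Merging** (`mergePairs()`): R2 is reverse-complemented and the
  largest overlap with mismatch rate ≤ `maxMismatchRate` (default 0.1)
  and length ≥ `minOverlap` (default 20) is taken; the search is
  exhaustive over shifts and is tested against an independent
  brute-force oracle. Overlap disagreements resolve in favor of R1 —
  with constant-quality input there is no basis for quality weighting,
  which remains a documented extension point. Pairs with no legal
  overlap are rejected with a reason, not an error.
* **Demultiplexing** (`demultiplex()`): reads are assigned to the
  unique barcode within `maxMismatches` (default 1) of their prefix;
  the configuration is rejected up front unless barcodes are
  equal-length with pairwise Hamming distance > 2·`maxMismatches`,
  which makes assignment unambiguous. Unmatched reads go to an
  `unassigned` bin.
* **Mapping** (`mapReads()`): merged reads are compared to every
  cassette amplicon end-gap-free and co-linearly; for equal lengths
  this is the Hamming alignment and identity = 100·matches/length.
  Two rules are implemented because the stated thresholds disagree
  numerically (3 mismatches over 450 nt is 99.33% identity, not
  98.3%): the default **identity mode** counts a read iff identity is
  strictly above 98.3% (i.e. up to 7 mismatches over 450 nt), and the
  selectable **mismatch mode** counts it iff mismatches ≤ 3. Both are
  behaviorally tested. Reads tied between two or more references go to
  an `ambiguous` bin rather than being assigned arbitrarily —
  trackability rests on unique assignment. The conservation invariant
  mapped + unmapped + ambiguous = total is enforced by the
  `CassetteCounts` class itself. Rare reads whose length matches no
  reference are scored by edit distance with indels counted as
  mismatches over the longer sequence.
* **Editing efficiency** is the mapped-mutant fraction of a sample's
  total reads. **Base-change frequencies** retain reads at ≥ 95%
  identity to the wild-type reference and report, per position, the
  number of retained reads substituted there divided by the number of
  retained reads with perfect identity. That perfect-read denominator
  is implemented as specified even though it can exceed 1; a
  conventional all-retained-reads denominator is available behind
  `denominator = "retained"`.

## Fitness and hit calling

The fitness score is

\[ f = \log_2 \frac{(c_{\text{post}} + \alpha)/N_{\text{post}}}
                   {(c_{\text{pre}} + \alpha)/N_{\text{pre}}} \]

with pseudocount α = 0.5 by default. Zero counts are otherwise
undefined at α = 0 (reported as missing with a warning, supported for
exactness checks); a half-count keeps strongly depleted or enriched
cassettes finite, which matters because realistic screens produce
near-zero pre- or post-counts at the scoring extremes. Totals are
per-sample mapped totals, making the score depth-invariant; it is also
antisymmetric under swapping the samples (α = 0), and fitness is
reported per screen (one pre/post pair per condition), not per
transfer.

The null model takes the synonymous controls' mean μ and sample (n−1)
SD σ — small control sets are the norm, hence the unbiased-variance
convention — and calls a variant a hit iff its fitness is strictly
greater than μ + 2σ. Controls are never reported as hits. No
multiple-testing correction is applied: the mean + 2×SD rule is the
method; an empirical-FDR diagnostic (`controlExceedance()`, the
fraction of controls above the cutoff) is reported but never alters
calls. Cross-condition pleiotropy (`pleiotropyMatrix()`) tabulates
hit/no-hit/not-assayed over the union of variants and lists variants
hit in two or more conditions.

Because selection renormalizes frequencies, every cassette's raw score
carries a common offset of −log2(total pool gain); the controls absorb
exactly that offset, so parameter recovery compares
(score − control mean) to the planted fitness. This is also why
calibrating cutoffs on controls rather than on zero is essential.

## Numerical and degenerate-input conventions

* Coordinates: 0-based half-open internally; 1-based inclusive in all
  user-facing tables. Residue numbers are always 1-based.
* Ties: spacer candidates break + strand first, then leftmost; mapper
  ties are never broken (ambiguous bin); merge search prefers the
  longest legal overlap.
* Degenerate inputs: empty structures, ligand-free structures,
  all-zero abundances, empty reference sets and sub-2 control sets are
  errors; zero-read samples make efficiency undefined (missing with a
  warning); conditions without a null are `not-assayed`, not silently
  dropped.
* The boundary cases of every threshold (distance exactly 5.0 Å,
  identity exactly at the cutoff, fitness exactly at μ + 2σ) are
  pinned by tests: ≤, strict >, and strict > respectively.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic panels:
toy libraries of 60–300 cassettes for design checks, and one
full-scale screen of 500 cassettes (50 synonymous controls, 10 planted
variants with fitness 2–5, one epoch, 10^5 multinomial counts and 10^5
read pairs per timepoint at 0.3% per-base error) for end-to-end
parameter recovery. Those sizes give per-cassette counts around 200,
where multinomial noise puts the fitness standard error near 0.1 log2
units — large enough to separate planted effects of ≥2 from the null
decisively, and representative of a well-covered amplicon screen.

## Known limitations

* The residue inventories of the original 23-regulator panel are not
  reconstructible from published bookkeeping alone; `regulatorPanel()`
  carries the sublibrary structure and sizes, not per-residue lists.
* The mapper is exact and co-linear by design; it is not a general
  aligner and does not handle structural variants, chimeras, or
  large indels.
* Editing itself (recombineering efficiency, gRNA activity
  differences) is outside the generative model; editing efficiency is
  measured, not simulated mechanistically.
* Quality scores are ignored throughout; quality-aware merging and
  mapping are extension points, not features.
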