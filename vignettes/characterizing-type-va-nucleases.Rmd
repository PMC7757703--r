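---
title: "Characterizing Type V-A CRISPR nucleases: models and methods"
author: "crisprVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing Type V-A CRISPR nucleases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprVA)
```

# The assay and what this package computes

Type V-A (Cas12a-like) CRISPR nucleases are characterized biochemically by
cleaving a plasmid library in which the 8 bases immediately 5' of a constant
protospacer are fully randomized (an "8N" library).  Molecules carrying a PAM
the nuclease recognizes are cut; the staggered double-strand break is blunted,
a double-stranded adapter is ligated onto the blunt end, and the products are
sequenced.  Two quantities fall out of the reads:

* **the PAM preference** — the base composition of the randomized region
  among cleaved molecules, summarized as a frequency matrix, an
  information-content logo and an IUPAC consensus (e.g. TTTV, TTN, YYN); and
* **the target-strand cut position** — the distance between the PAM and the
  ligated adapter, i.e. the blunt-end offset in PAM-distal protospacer
  bases.  For the nucleases this package models that offset is 22.

crisprVA implements the full read-analysis procedure, a synthetic-assay
generator with per-read ground truth so the procedure can be validated by
parameter recovery, a CRISPR direct-repeat stem-loop scanner with a universal
single-guide designer, and an amplicon editing-outcome quantifier.

# The simulator: what it emulates

`simulateLibrary()` lays each molecule out as
`anchor (28 bp) | 8N | protospacer (24 bp) | downstream (20 bp)`, drawing the
randomized bases uniformly (a skew matrix can emulate a biased input
library).  `simulateCleavageReads()` then applies a generative nuclease
model:

* **Cleavage probability.**  A position weight matrix over the randomized
  region scores each molecule's 8-mer; the product of per-position
  probabilities is rescaled so the best PAM cleaves with probability
  `maxCleavageProb` (default 0.9).  `pwmFromIUPAC()` builds such a matrix
  from a degenerate motif, right-aligned so the motif's last base abuts the
  protospacer — the convention in which Cas12a PAMs such as TTTV are
  written.  Its `fidelity` (default 0.97) is the total probability mass on
  the allowed bases of a constrained position; 0.97 reflects a strong but
  not absolute preference, as real PAM logos show.
* **Cut geometry.**  Cleaved molecules are cut on the target strand
  `cutSite` PAM-distal protospacer bases from the PAM (default 22).  Only
  the target-strand coordinate is observable after end repair, so the
  stagger between the two strand cuts (default 5) is resolved by blunting to
  the target-strand coordinate; `blunt = FALSE` exposes the pre-repair
  fragment end for geometry checks.
* **Background.**  With probability `backgroundRate` a cleavage event is
  placed at a uniformly random molecule position instead, emulating the low
  level of nonspecific cleavage a crude lysate produces.  Default 0.05,
  inside the 2–10% range typical of the assay.
* **Read formation.**  Sequencing starts in the ligated adapter and proceeds
  across the fragment toward the PAM and anchor, so a read is
  `adapter + reverse_complement(fragment)` truncated to `readLen` (default
  150, an Illumina-style length).  Whether the assay reads the target- or
  non-target-strand fragment is not observable downstream; the simulator
  models the target strand, and the caller accepts both presentations.
* **Noise.**  Substitution-only sequencing errors at rate 0.001 and per-base
  Phred scores from a clipped normal (mean 35, sd 4, range 2–41) — enough to
  exercise the quality filter and exact-match exclusions; indel sequencing
  errors are out of scope.

The generator deliberately does **not** model PCR amplification bias,
chimeras, paired-end reads, or adapter ligation failures.  Passing recovery
tests therefore demonstrates the correctness of the analysis procedure under
the assay's idealized geometry, not robustness to every artifact of real
libraries.

# The PAM caller

`callPam()` chains five stages, each exported for independent use:

1. **Quality filter** — a read passes when its *mean* Phred score is
   strictly greater than 20.  The threshold is stated as a per-read
   property; we interpret it as the read mean because per-base trimming
   would silently alter the exact-match semantics of the anchoring step.
2. **Anchoring** — the 28-bp backbone anchor must match exactly (forward or
   reverse-complement presentation; multiple matches are excluded as
   `ambiguous_anchor`); the 8 bases adjacent on the PAM side are the
   putative PAM; the adapter must match exactly; the cut offset is the
   number of protospacer bases between the PAM and the adapter junction.
   Exclusions are categorized (`no_anchor`, `no_adapter`, `bad_geometry` for
   junctions inside the PAM/anchor, as background cuts upstream of the
   protospacer produce).  No fuzzy matching is attempted.
3. **Cut-site filter** — offsets outside the modal offset ±2 are removed;
   ties in the mode break toward the smaller offset (a deterministic,
   documented choice).  The removed fraction is reported; it estimates the
   background fraction that survived anchoring.
4. **Profile** — per-position counts, column-stochastic frequencies
   (optionally divided by a supplied input-library composition and
   renormalized — off by default), and information content `2 - H` in bits
   without small-sample correction, appropriate for the large read sets the
   assay produces.
5. **Consensus** — each position is coded by the smallest IUPAC letter
   covering all bases at frequency ≥ `includeThreshold`, then N positions
   are trimmed from the PAM-distal side, leaving motifs like `TTTV`, `TTN`,
   `YYN` with the variable base adjacent to the protospacer.

**Why the inclusion threshold defaults to 0.15.**  Column frequencies sum
to 1, so all four bases can be ≥ 0.25 only in an exact four-way tie; with any
finite read count an unconstrained position would then never be coded N and
consensus strings like TTN could never be produced.  The threshold must sit
strictly below 0.25 (so uniform positions, whose empirical frequencies
scatter around 0.25, are coded N) and above the noise floor of constrained
positions (whose disallowed bases sit near 0.01–0.03 at fidelity 0.97).
0.15 is the midpoint of that safe band: at the ~500–12,000 retained reads
typical of a 50,000-molecule assay the nearest empirical frequency is many
standard errors from the threshold on both sides.  It is exposed as a
parameter for unusually noisy or shallow data.

**Coordinates.**  All cut offsets are 1-based PAM-distal protospacer
positions (the first protospacer base is 1); the blunt end lies 3' of the
reported base.  Every output file states this convention.

# Repeat scanning and guide design

Type V-A systems are recognizable from their CRISPR direct repeats: the 3'
end folds into a stem-loop whose stem is the short palindrome `TCTAC` /
`GTAGA` (RNA `UCUAC…GUAGAU`) separated by a 1–8 nt loop; a rare variant uses
`CCTGC`/`GCAGG`.  `scanRepeat()` finds `stem + N{loop} + revcomp(stem)` for
every loop length, reporting leftmost-first non-overlapping hits by default
(all overlapping occurrences on request; among hits sharing a start the
shortest loop wins — a deterministic tie-break).  Stems pair by exact DNA
reverse complement; G·U wobble is not considered because the search runs on
DNA repeats.  `classifyArray()` labels an array `VA_canonical`,
`VA_rare`, or `unclassified` and histograms the observed loop lengths;
4-nt loops dominate natural Type V-A repeats.

`designSgRNA()` builds the universal single guide: the 3' 20 nt of the
repeat (transcribed to RNA) as scaffold, followed by a 24-nt spacer — 44 nt
in total.  Natural guides use roughly 19–22 repeat nucleotides; 20 is the
universal choice and the length is exposed (`scaffoldLen`).  The stem-loop
is re-predicted inside the scaffold so a truncation that destroys the
hairpin is visible immediately.

# Editing-outcome quantification

`quantifyEditing()` re-implements the published quantification transparently
rather than wrapping an external tool:

* **Cut placement.**  The spacer must match the amplicon exactly once on
  either strand; the cut is placed `offset` bases from the spacer's 3' end
  (default −4), strand-aware, as a between-base coordinate.  The −4
  convention is inherited from the upstream tool's parameterization and is
  unusual for a Cas12a-style nuclease (which cuts PAM-distal); it is applied
  verbatim and recorded in the output metadata.
* **Window.**  The cut-adjacent base plus `window` bases each side (default
  10), i.e. 21 amplicon positions, clipped at amplicon ends.
* **Alignment.**  Global affine-gap alignment (match 2, mismatch −4, gap
  open 10, gap extend 1 — standard amplicon-calling weights, configurable);
  the better of the forward and reverse-complement alignments is used, which
  makes classification reverse-complement invariant.  Reads scoring below
  half their perfect-match score are `unaligned` and leave the denominator.
* **Events.**  Insertions and deletions are sized by gap-run length;
  consecutive mismatch columns merge into one multi-base mutation event —
  the operationalization needed for "≥2 bp mutations".  A read is
  `unedited` if no event overlaps the window, `small_indel_or_mut` if the
  largest overlapping event is 1 bp, `large_event` at ≥2 bp.
* **Frequency.**  `edited = (small + large) / aligned`; a mock-control
  edited fraction can be subtracted (clipped at 0) for background-corrected
  NHEJ estimates.

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand-built
reads from the documented geometry (string arithmetic, no simulator code);
an exhaustive substring-scan oracle for the motif scanner; closed-form
binomial/chi-square checks for the simulator's sampling behaviour; and full
round-trips in which the caller must recover the generating model's
consensus (TTTV, TTV, TTN, YYN, YTV) and cut site exactly from 50,000
simulated molecules at 5% background.  Read accounting is conserved
(`input = quality_failed + exclusions + cutsite_filtered + retained`) on
every run, and classification suites check reverse-complement invariance
end to end.  Fifty thousand molecules at the default cleavage efficiency
yield roughly 500–12,000 informative reads depending on the PAM's
degeneracy — comfortably enough for exact consensus recovery while keeping
a full validation run under a minute.

# Known limitations

* Depletion-style PAM analysis (reading the *uncleaved* library) is not
  implemented; the caller assumes enrichment of cleavage products.
* The consensus reducer reports a single motif; mixtures of distinct PAM
  classes in one read set will be summarized, not deconvolved.
* The edit classifier's window semantics and alignment weights are stated
  choices; other tools draw window boundaries slightly differently, so
  per-read categories can differ at window edges.
* Guide design predicts the stem-loop by motif, not by thermodynamic RNA
  folding; a scaffold can carry the motif yet misfold in contexts the motif
  search cannot see.
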