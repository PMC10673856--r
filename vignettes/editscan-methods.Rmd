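---
title: "Methods: CRISPR editing analysis for NCR peptide genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR editing analysis for NCR peptide genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## Scope and model

`editscan` implements the computational workflow of a CRISPR/Cas9 study of
the *Medicago truncatula* NCR (nodule-specific cysteine-rich) peptide gene
family, from candidate-gene selection through guide design to per-nodule
amplicon genotyping and Sanger-trace decomposition. Every input the pipeline
consumes can be simulated with recorded ground truth, so each analytic step
is testable for exact recovery. This vignette explains the models and the
parameters that matter, what the simulators do and do not emulate, and the
design choices made where the underlying procedures left the details open.

All coordinates are 1-based and fully closed; a Cas9 cut site is the index
of the last base 5' of the blunt cut (SpCas9 cuts 3 bp 5' of the NGG PAM,
between protospacer positions 17 and 18). We use 1-based coordinates
throughout, including internally, because that is the native convention of
R and Biostrings; reports therefore need no coordinate translation.

## Candidate selection

NCR peptides are short secreted peptides that drive the terminal
differentiation of rhizobial bacteroids in galegoid legume nodules. The
canonical family members share three features used as selection filters:

1. **Signal peptide** — an annotation input (e.g. from SignalP). The
   package never predicts signal peptides; when a record carries no signal
   peptide the whole sequence is treated as the mature peptide.
2. **Conserved cysteine motif** — four cysteines spaced
   C–X5–C–Xn–C–X4–C within the mature peptide: exactly 5 residues between
   cysteines 1 and 2, at least `gap2_min` (default 1) between 2 and 3, and
   exactly 4 between 3 and 4. The scanner reports the leftmost satisfying
   quadruple; further matches only as a count, so results are
   deterministic. By default peptides whose mature sequence does not contain
   exactly four cysteines fail (`require_exact_four_cys = TRUE`):
   six-cysteine NCRs are a distinct subfamily and "conserved positions"
   is read as excluding extra cysteines. Both choices are configurable.
3. **Expression** — genes are retained only when their total nodule read
   count strictly exceeds `min_total_reads` (default 10,000, matching the
   published cutoff's "more than 10,000 reads" wording; a gene at exactly
   10,000 is excluded). Genes with zero reads are reported as
   pseudogene-like.

The funnel report gives, in order, the input count, the signal-peptide
count, the motif count, and the retained count; these four stages are
nested, so each is at most the previous one. Within the motif stage the
zero-read and low-expression counts are disjoint diagnostic categories that
sum with the retained count to the motif count — they are not nested stages
themselves, which is why monotonicity is stated over the four stage counts
only.

**Isoelectric point.** The pI is the pH at which the Henderson–Hasselbalch
net charge is zero: positively ionizable groups (N-terminus, K, R, H)
contribute $n/(1+10^{\mathrm{pH}-pK_a})$ and negative groups (C-terminus,
D, E, C, Y) $-n/(1+10^{pK_a-\mathrm{pH}})$. Because the net charge is
strictly decreasing in pH, bisection on $[0, 14]$ to a bracket width of
$10^{-4}$ pH units finds the root; the suite verifies agreement with a
dense grid scan to $10^{-3}$. The pKa set matters: published pI values for
NCR peptides come from a precomputed catalogue whose pKa model is not
stated, so no published pI range is treated as a reference value here. The
package ships the EMBOSS pKa set as a named, versioned data file
(`inst/extdata/pka_emboss.tsv`) and records the set name with every pI.

**Charge classes.** Mature peptides are classed anionic (pI ≤ 6.5),
neutral, or cationic (pI ≥ 7.5). No boundary values have been published
for this classification; the defaults span the neutral range symmetrically
around pH 7 and are configurable (`charge_boundaries()`), with both
boundaries inclusive toward their extreme class.

## Guide design

`enumerate_protospacers()` returns every 20-mer adjacent to an NGG PAM on
either strand, with plus-strand coordinates. `apply_constraints()` ranks
candidates by three keys:

1. **Cut upstream of the fourth conserved cysteine codon** (strict: a cut
   immediately before the codon's first base does not count). Disrupting
   the peptide before its last conserved cysteine is what makes an edit
   reliably function-destroying, because the conserved cysteines are
   required for NCR function in planta. Failing candidates are flagged,
   not dropped.
2. **5' base G > A > other.** U6-family RNA polymerase III promoters
   initiate best on G (tolerably on A); constructs whose protospacer began
   with C were observed to edit poorly or not at all, so the 5'-base class
   outranks position.
3. **Distance of the cut from the mature-peptide start** (ascending), with
   ascending start coordinate as the documented final tie-break, making
   the ranking a total order.

`min_offtarget_mismatches()` computes the minimum Hamming distance between
a protospacer and every PAM-adjacent 20-mer in a genome, excluding the
on-target site; `passes_offtarget_rule()` applies the "at least two
mismatches at every potential off-target site" predicate. Only NGG PAMs are
scanned by default — NAG scanning is a refinement of dedicated off-target
tools and can be enabled with `include_nag = TRUE`. Gapped ("bulge")
off-targets are not considered: the rule is stated in terms of mismatches.
Results are invariant to contig order and to splitting the genome across
FASTA records, since candidate sites never span record boundaries.

## Amplicon genotyping

Per-nodule genotyping mirrors the amplicon deep-sequencing workflow
(roughly 200-bp amplicons around the target site, about 10,000 reads per
sample, analysed with a CRISPResso2-like procedure):

* **Alignment.** Reads are aligned globally (Needleman–Wunsch with affine
  gaps) to the amplicon: match +2, mismatch −3, and a gap of length $L$
  costs $8 + L$. The implementation delegates to
  `Biostrings::pairwiseAlignment`; the test suite checks score equality
  against an exhaustive Gotoh dynamic-programming oracle on short pairs.
  Reads below 60% alignment identity are discarded (counted, never
  silently dropped).
* **Allele calling.** Only edits intersecting the quantification window
  (cut site ± 10 bp by default) enter a read's edit signature; adjacent
  same-kind operations are merged. The window mimics default amplicon
  quantification practice — no window setting was published, so the value
  is an explicit, configurable package choice recorded in the reference
  object. Because alleles are defined by their in-window signature only,
  PCR or sequencing noise far from the cut cannot split an allele into
  spurious sub-alleles.
* **Allele table.** Reads collapse by identical signature; rows below
  `min_allele_frequency` (default 1%) are pooled into an `other` row that
  counts toward totals but not classification, suppressing error-derived
  pseudo-alleles. Retained frequencies sum to 1 and
  retained + discarded = input reads, both enforced by tests.
* **Classification.** With defaults: *fully mutant* at wild-type fraction
  ≤ 0.05 (split into indel-only versus with-mismatch by the retained
  mutant alleles), *mutant-majority* at ≤ 0.50 (the "max. 50% WT allele"
  convention, boundary inclusive), *heterozygous/chimeric* when a
  wild-type majority coexists with at least one retained mutant allele —
  expected on hairy roots, where a nodule can descend from multiple
  founder cells — and *wild type* otherwise. The published analysis states
  only that fully mutant nodules carried "very few" wild-type reads
  attributable to contamination; 5% is this package's declared,
  configurable ceiling for that notion.
* **Summary.** `summarize_editing()` reproduces the editing-efficiency
  table layout: per construct (and per phenotype where scored), nodules
  sequenced, nodules at ≤ 50% wild type, fully mutant counts, and the
  percentage of nodules carrying only indel alleles, rounded half-up to
  integer percent (7/15 → 47%).

**Consequence prediction.** The edited CDS is rebuilt from the signature,
translated with the standard genetic code to the first stop, and compared
to the wild-type protein: frameshift iff the net indel is not a multiple
of 3; the identical-prefix length gives the gene-specific residues before
divergence and the remainder the novel residues before termination (the
chimera structure typical of frameshift alleles). A wild-type residue is
deemed retained iff it lies in the common prefix or common suffix of the
two proteins; conserved cysteines outside both are reported lost. Clean
in-frame deletions additionally report the deleted residues in
mature-peptide numbering (e.g. a 3-bp deletion removing a single
glutamate). Edits touching the start codon are flagged `start_lost` and
not translated.

## Trace decomposition

Downstream of a Cas9 cut, a Sanger chromatogram of a mixed template
population is a superposition of mutually shifted copies of the control
signal. For shifts $k \in [-K, K]$ the control's four channels over the
decomposition window are stacked into design columns $A_k$, and
non-negative least squares (Lawson–Hanson active set, via
`pracma::lsqnonneg`) solves $\min_{w \ge 0} \lVert A w - b \rVert^2$
against the edited trace $b$. Weights are rounded at $10^{-6}$ (so solver
noise cannot make results platform-dependent) and normalized to fractions;
fit quality is reported as $R^2 = 1 - SS_{res}/SS_{tot}$. The window
defaults to 50 positions starting 5 bp downstream of the cut — skipping
the heterogeneous junction at the break site, as decomposition tools do —
and is clipped so every shifted copy stays inside the trace. The spectrum
is invariant to a common intensity rescaling of both traces.

## The simulators, and what passing tests mean

The generators are pure functions of their specification and seed:

* **Peptide families** (`gen_ncr_family()`): motif-positive mature
  peptides embed exactly four cysteines in the required spacing;
  negatives either violate the first gap while keeping four cysteines or
  carry too few cysteines. Synthetic "signal peptides" are 15–25 residues
  drawn at least 70% from A/L/V/I/F/M/W — a generator convenience only,
  since the analytic modules read the annotation and never infer signal
  peptides from sequence.
* **Expression tables** (`gen_expression_table()`): negative-binomial
  counts (size 5) around per-zone means for the four nodule zones (IID,
  IIP, IZ, ZIII). The default "high" profile used in tests has a 50,000
  total-read mean, comfortably above the 10,000-read cutoff; "low"
  profiles sit well below it; "zero" yields pseudogene-like rows.
* **Amplicon read sets** (`gen_amplicon_reads()`): a multinomial draw over
  allele fractions, each read being its allele's edited sequence passed
  through the error model — substitutions uniform over the three
  alternative bases, indel errors of exactly 1 bp at uniform positions,
  both with per-base rates in [0, 0.1]. The truth table records every
  read's allele. This is the simplest model that stresses the
  allele-collapsing logic; it does not emulate realistic Illumina error
  spectra, quality-score structure, homopolymer-length biases, or chimeric
  PCR reads, so passing recovery tests demonstrate correctness of the
  genotyping logic under the stated error model, not robustness to every
  real-world artefact.
* **Chromatograms** (`gen_trace()`): one peak value per channel per
  position (no peak-shape convolution), the edited trace being exactly
  the fraction-weighted shifted-control sum plus truncated Gaussian noise.
  This is sufficient for the shift-decomposition math and deliberately
  nothing more; base-caller artefacts, dye blobs and mobility shifts are
  out of scope.
* **Nodule panels** (`gen_nodule_panel()`): 100 nodules by default, each
  with its own random 200-bp amplicon, 5,000 reads, and per-base error
  rates of 0.001, spanning all five genotype classes. Designed wild-type
  fractions keep a margin from the classification boundaries (fully
  mutant ≤ 0.03, mutant-majority 0.15–0.45, chimeric 0.6–0.9) and every
  mutant allele receives at least 5% of reads, mirroring the
  few-allele structure of per-nodule read pies; the intended genotype is
  computed from the realized multinomial draw, not the nominal fractions.
  Recovery scores allele frequencies after renormalizing over the true
  alleles' signatures, because the uniform error model depletes every
  allele by the same expected factor and relative allele ratios are what
  per-nodule pies report.

The study's published selection funnel (679 genes → 248 with signal
peptide and motif → 172 well-expressed) depends on an unpublished peptide
catalogue and an external expression table, and the published per-gene pI
ranges depend on an unstated pKa model; neither is therefore a
reproduction target. What is reproduced exactly is the editing-efficiency
percentage row from its published per-construct count rows, and all
behavioural claims (motif logic, threshold strictness, guide rules,
genotype classification, decomposition recovery) on synthetic data with
known truth.

## Numerical choices and degenerate inputs

* pI bisection tolerance $10^{-4}$ pH; display rounding to 2 decimals is
  left to reports, the full-precision value is returned.
* Alignment tie-breaks follow the alignment engine's deterministic
  traceback; in repetitive contexts an indel's placement (not its size)
  can differ from the nominal position, which is why recovery tests map
  truth alleles to signatures by aligning each allele's pure sequence.
* Guide ranking is a total order with ascending start as final tie-break;
  shuffled input yields identical output.
* NNLS weights are rounded at $10^{-6}$ before normalization; an all-zero
  control window or an out-of-coverage window is an error, not a silent
  zero spectrum.
* Empty read sets, fractions not summing to 1, edits out of amplicon
  bounds, unknown zone labels and non-amino-acid characters all raise
  immediate errors naming the offending input.
* Problem sizes in the shipped tests (5,000-read nodules, 100-nodule
  panels, 10,000-peptide scans, 1,000 alignment-oracle pairs) were chosen
  so the whole suite completes in a few minutes on one CPU while keeping
  every statistical check well-powered.

## Known limitations

* Signal-peptide status is an input; no predictor is bundled.
* Off-target assessment counts mismatches only — no CFD/MIT efficiency
  scores, no bulge alleles, NAG PAMs off by default.
* Reads are treated as single-end and pre-merged; no paired-end merging,
  UMI handling, or base-quality-aware calling.
* Trace decomposition reports no per-shift significance tests, and reads
  TSV traces rather than AB1 files.
* The chromatogram and read-error models are intentionally minimal (see
  above); conclusions about real sequencing data require the usual
  caution.
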