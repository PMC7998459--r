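---
title: "Genome-guided discovery of MSDIN cyclic peptides"
author: "msdinmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-guided discovery of MSDIN cyclic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdinmine)
```

## The biological problem

Lethal *Amanita* mushrooms synthesize their cyclic peptides — including the
amatoxins and phallotoxins — ribosomally. Each peptide is encoded by a gene
of the MSDIN family (named after the five residues that begin most
precursors). The precursor is 25–60 amino acids long and has a fixed
architecture:

* a **leader peptide** of 10 residues ending in Pro,
* a **core peptide** of 7–11 residues, usually ending in Pro,
* a **recognition sequence** making up the remainder, typically starting
  with Cys or Ser.

The prolyl oligopeptidase POPB cleaves the precursor at the two Pro anchors
and transpeptidates the core into a head-to-tail macrocycle. Mature toxins
additionally carry hydroxylations, a Trp–Cys tryptathionine cross-bridge
and (for amatoxins) a sulfoxide; many other MSDIN products are plain
macrocycles. Because each sequenced genome holds dozens of MSDIN genes but
only a couple of dozen *Amanita* cyclic peptides were ever characterized,
the family is a promising reservoir of unknown peptides. The
peptidogenomic strategy implemented here goes from genome sequence to
confirmed cyclic peptides: mine precursors, predict candidate masses,
match them in high-resolution MS1 data, and confirm sequences in MS/MS
spectra.

## Mass model

All masses are monoisotopic, computed from integer elemental compositions
over C, H, N, O, S (sufficient for the 20 standard residues) and
principal-isotope masses. For a core $c_1 \dots c_n$:

$$M_\text{linear} = \sum_i M(c_i) + M(\mathrm{H_2O}), \qquad
  M_\text{cyclic} = \sum_i M(c_i),$$

since head-to-tail cyclization condenses out one water (18.010565 Da).
Modification states shift the composition only: each hydroxylation adds one
O (+15.994915 Da), sulfoxidation adds one O, and tryptathionine formation
removes two H (−2.015650 Da). Sulfoxidation and the bridge are only
enumerated for cores containing both Cys and Trp. Singly charged adducts
use fixed cation masses:

$$m/z = M + m_\text{cation}, \quad m_\mathrm{H^+} = 1.007276,\;
  m_\mathrm{Na^+} = 22.989218,\; m_\mathrm{K^+} = 38.963158.$$

The proton mass (not the hydrogen-atom mass) is used for
$[\mathrm{M+H}]^+$: it reproduces the published value 1109.6394 for
cyclo(TFLPPLFVPP) from the neutral 1108.6321, where the hydrogen-atom mass
would give 1109.6399. Mass discrepancies are reported as
$|\text{measured} - \text{theoretical}|/\text{theoretical} \times 10^6$ ppm.

Full double precision is kept internally; rounding happens only at report
time (4 decimals for m/z, 2 for ppm). Reported ppm discrepancies are
computed against the 4-decimal theoretical m/z, i.e. against the number a
reader of the output tables actually sees; this is also the convention that
reproduces the published discrepancy columns from their printed inputs.

Isotope envelopes (`isotopic_distribution()`) are computed by element-wise
convolution of per-element isotope distributions, aggregated in 0.01 Da
bins and renormalized. Only monoisotopic masses feed the pipeline; the
envelope function exists for inspection and cross-checks, and its binned
convolution is not intended to replicate any particular polynomial
implementation digit-for-digit.

## Precursor mining

Mining replaces homology search with a deterministic degenerate-motif
scan, which needs no aligner parameters and is reproducible by
construction. The leader motif is a per-position residue-set pattern of
length 10: positions 1 and 10 are fixed (M and P), and positions 2–9 allow
the residues observed at that position in the built-in reference set of 86
published precursors (`msdin_reference()`). Deriving the sets from the
data rather than hard-coding them matters in one detail: position 5 is
usually Asn or His, but one published leader (MSDIDTTRLP) carries Asp
there, so a hand-written N/H rule would silently miss a real gene. The
pattern is exposed in `mining_config()` and can be loosened or rebuilt
from any leader collection with `leader_pattern_from()`.

After each leader match the following tail is truncated at the first stop
codon (or at 11 + 25 residues — the longest allowed core plus a recognition
cap slightly above the longest published recognition sequence of 23
residues). Core extraction then emits **one candidate per Pro** whose
position lies in the allowed core-length range (POPB cleaves at Pro). When
several Pro anchors are possible, published cores are not explained by any
single "first Pro" or "last Pro" rule, so all candidates are kept and
ranked by cues with clear biological readings:

1. the recognition sequence begins with C or S (the near-universal pattern
   in published rows),
2. the core ends with Pro,
3. longer cores win remaining ties.

When no Pro lies in range, full-window candidates for every allowed length
are emitted and flagged `non_canonical_core` (a handful of published rows
have cores not ending in Pro). The top-ranked candidate populates the
precursor record; the full ranked list is available via
`extract_core_candidates()`.

Genome mining six-frame-translates every sequence (stops as `*`, N-codons
as `X`) and reports 0-based half-open nucleotide coordinates on the
forward strand. Expression checking is an exact-substring test of the full
precursor against the three forward-frame translations of each transcript;
read alignment and intron-aware gene models are deliberately out of scope,
so genes whose coding sequence is interrupted by an intron in the genome
assembly would be missed — a documented limitation of contiguous-ORF
mining.

## Candidate enumeration and MS1 matching

Which modifications occur on a given core, and how many, cannot be known
in advance, so every combination is enumerated: 2 topologies × 0–4
hydroxylations, times sulfoxide and bridge toggles for Cys+Trp cores (10
or 40 states per core), each with H/Na/K adduct m/z. Epimerization is
mass-neutral and therefore not enumerated. Duplicate genes with identical
cores collapse to one candidate row whose provenance lists every gene.

MS1 matching reports every (candidate, adduct, peak) pair within the ppm
tolerance whose theoretical m/z lies in the instrument scan range
(500–1700 m/z by default). The default tolerance of 5 ppm sits above the
largest published match discrepancy (3.43 ppm) while excluding nominal-mass
coincidences; it is a config field, not a constant. No uniqueness is
imposed at this stage — ambiguity is resolved by MS/MS.

## MS/MS assignment

Fragment annotation follows the practice that works for these compounds:
y- and b-series of the core in its written orientation plus
residue-diagnostic immonium ions ($m/z$ = residue − CO + proton). A
principled cyclic alternative — the union of b-series over all ring
openings (`ring_b`) — is also available, since ring opening at an
arbitrary amide would produce exactly that ion set; both interpretations
are supported rather than guessing which the instrument favours.

Matching is nearest-first greedy and one-to-one within a fragment
tolerance of 0.02 Da (a typical Q-TOF centroid accuracy; configurable).
The verbal acceptance rule "most or all amino acids explained" is
quantified as:

* a residue is **covered** when it is flanked by consecutively matched
  y-ions (their mass differential identifies it; y1 alone identifies the
  C-terminal residue) or when an immonium ion of its residue type matched;
* a candidate is **confirmed** when coverage ≥ 0.8 and at least one
  immonium ion matched.

The 0.8 threshold encodes "most or all": with the y2…y9 + immonium
evidence pattern reported for the decapeptide cycloamanides, coverage is
0.9 and the assignment is confirmed, while fragmentary evidence (a couple
of y-ions) is rejected. Both knobs are config fields. Ile/Leu are
isobaric, so assignments are provably identical under I↔L substitution;
results carry an `il_ambiguous` flag instead of pretending to resolve
them.

## What the synthetic data emulates

The generator (`sim_config()` defaults) produces:

* **genomes**: i.i.d. background at GC 0.46 (the GC content of sequenced
  lethal *Amanita* genomes), with precursor coding sequences plus stop
  codon embedded non-overlapping on random strands. Real genomes have
  repeats, introns and gene clusters; none of these are simulated, so
  mining recovery on synthetic genomes demonstrates correctness of the
  scanning arithmetic, not robustness to assembly artefacts.
* **precursors**: leaders and C/S-initial recognition sequences sampled
  from the published templates; sampled cores are 7–11 residues ending in
  Pro, with residue frequencies biased towards Pro, Phe and Ile as in the
  known cyclic peptides.
* **transcriptomes**: `round(fraction × n)` genes expressed, full coding
  sequence flanked by random UTRs. The default fraction 18/22 mirrors the
  observed transcription rate of MSDIN genes.
* **MS1 peak lists**: one peak per emitted adduct with multiplicative mass
  error drawn from Normal(0, 1.5 ppm) truncated at ±3σ, clipped to the
  500–1700 m/z scan range, plus uniform noise peaks. The 1.5 ppm σ was
  chosen so simulated discrepancies span the published 0.00–3.43 ppm
  range; truncation guarantees simulated true peaks stay inside the 5 ppm
  matching tolerance, so recovery failures indicate real defects rather
  than sampling accidents.
* **MS/MS spectra**: all y-ions (y2…y(n−1) guaranteed), b- and immonium
  ions with configurable emission probabilities, optional Gaussian jitter
  and noise peaks, exponential-rank intensities. Default spectra are clean
  (no jitter, no noise): intensity models of real collision cells are not
  attempted, and no test depends on intensities.

Everything is driven by one integer seed; generators restore the global
RNG state, and repeated calls with the same configuration are
bit-identical.

## Numerical and design choices

* Composition subtraction refuses to go negative — a negative atom count
  always indicates a logic error upstream.
* Modification states are composition-level; hydroxylation sites are not
  tracked, because site-resolved masses are identical and site assignment
  is not derivable from MS1/MS2 mass lists alone.
* Candidate deduplication keys on the exact core string; I/L variants are
  kept separate (their masses are identical anyway) and only collapsed
  conceptually at the assignment stage via the ambiguity flag.
* Greedy fragment matching is globally nearest-first with per-ion and
  per-peak uniqueness, making results independent of input peak order;
  ties are broken by ion then peak position for determinism.
* The published mass tables are reproduced to ±0.0005 Da rather than
  exactly: the tables' own last printed digit is not always consistently
  rounded (several entries are truncations of the exact value, and two
  equal-composition rows differ in their last digit), so sub-0.0005
  agreement is the strongest claim those tables support.
* Test and example problem sizes — 1 Mbp genomes with 20 genes, a few
  thousand simulated peaks — were chosen as the smallest sizes at which
  every pipeline stage (both strands, all adducts, noise, decoys) is
  exercised; they run in seconds to a couple of minutes on one CPU.

## Limitations

* Mining operates on contiguous ORFs in protein space: intron-containing
  genes and alternative splicing are out of scope.
* Charge states above 2, negative-ion mode and average masses are not
  supported; the element table is CHNOS only.
* The assignment rule confirms amino acid *composition and combination*
  consistency with a genomic core — like the manual practice it automates,
  it cannot distinguish I from L, nor prove macrocycle connectivity;
  definitive structure confirmation still requires synthetic standards or
  NMR.
* De novo sequencing, database search engines and retention-time modelling
  are intentionally not reimplemented.
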