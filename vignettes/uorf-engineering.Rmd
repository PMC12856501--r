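---
title: "Engineering upstream ORFs in 5' leaders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering upstream ORFs in 5' leaders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfkit)
```

## The biological problem

Upstream open reading frames (uORFs) are short ORFs that begin at an ATG
within the 5' leader of an mRNA, upstream of the main coding sequence
(mORF). Scanning ribosomes engage these starts first, which typically
represses translation initiation at the main ATG (mATG). Knocking out
uATGs with CRISPR therefore de-represses translation of the main protein
without touching the promoter or the transcript level — an attractive
strategy for boosting enzyme abundance in metabolic engineering, for
example to raise diterpenoid (tanshinone) yields in *Salvia miltiorrhiza*
by editing the leader of the diterpene synthase gene *SmCPS1*.

`uorfkit` implements the computational side of such a program: uORF
annotation and classification, prediction of how an indel allele
reshapes the uORF landscape, uATG-proximal SpCas9 guide design,
genotyping of edited lines from cloned amplicon sequences, and the
downstream quantitative summaries (2^-ddCt expression, dual-luciferase
translational efficiency, metabolite fold changes).

## The uORF model

A transcript is modelled as `leader + CDS` (a `leader_context`); the
mATG sits at position `length(leader) + 1`. Every ATG strictly upstream
of the mATG seeds a uORF; its reading frame is walked in codon steps
across the *whole* transcript and the first stop codon (TAA/TAG/TGA)
closes it. Classification follows the position of that stop:

* **Type 1 (non-overlapping)** — the stop lies entirely upstream of the
  mATG. About 85% of known uORFs are of this type.
* **Type 2 (out-of-frame overlapping)** — the uATG is out of frame with
  the mORF and the stop falls inside the mORF coding region.
* **Type 3 (N-terminal extension)** — the uATG shares the mORF's frame
  and no stop intervenes before the mATG, so the uORF shares the mORF's
  stop codon.
* **INCOMPLETE** — an out-of-frame uORF that never meets a stop before
  the transcript ends. Excluded from reports by default
  (`scan_config(include_incomplete = TRUE)` retains them).

Conventions fixed by decree, stated here because the field uses both:

* **Coordinates are 1-based inclusive everywhere** — in the R API, in
  TSV/JSON reports (headers say so), and in this vignette. This is the
  native convention of R and of Bioconductor's IRanges/Biostrings stack;
  half-open 0-based intervals buy nothing inside a single-language
  toolkit and invite off-by-one bugs at the interface.
* **uORF length includes the stop codon** (uATG through the last stop
  base). Published uORF lengths are divisible by 3 under either
  convention, so this is not observable from printed data; the package
  states its choice in every report.
* **N is inert**: a codon containing N is neither a start nor a stop.
* An out-of-frame stop whose span crosses the mATG classifies by its
  end: a stop ending before the mATG means Type 1, otherwise Type 2. An
  in-frame stop cannot straddle the mATG (frame arithmetic forbids it).
* `min_length_nt` defaults to 6 nt (start + stop, no intervening
  codon), so even a 15-nt uORF — the shortest reported in the motivating
  system — is retained under any plausible threshold.

## Predicting edit outcomes

Edits (DEL/INS/SUB) are expressed in reference coordinates and applied
as if simultaneous; overlapping edits are an error, not a merge —
CRISPR lesions in sequenced alleles are discrete. `apply_edits` also
returns a coordinate map from surviving reference positions to edited
positions. A reference uATG *survives* when its three bases map
consecutively into the edited allele and still spell ATG; consequently
a substitution that rewrites a uATG base but leaves it reading ATG does
not count as destruction — only the resulting sequence matters.

`predict_edit_outcome` recomputes the mATG through the coordinate map,
re-annotates, and reports a delta: per-type counts before/after, uATGs
destroyed (no surviving image) and created (no reference preimage),
type transitions for surviving uATGs, and the relative change in the
total number of complete uORFs,
`100 * (total_after - total_before) / total_before`. The identity
`destroyed - created = n_before - n_after` holds by construction and is
enforced by property tests. Edits may not touch the CDS unless
explicitly allowed, since leader engineering is the use case; either
way the edited allele must retain a valid main ORF.

Two consequences of the frame arithmetic are worth knowing. Deleting a
non-multiple-of-3 stretch of leader changes the frame *relative to the
mATG* of every uORF upstream of the lesion (their positions stay, the
mATG moves), which is how a Type 1 uORF can become Type 2 after losing
its stop. And deleting the in-frame stop(s) of a uORF that shares the
mORF's frame converts it into a Type 3 N-terminal extension — the
`convert_to_type3` simulation profile does exactly this.

## Guide design

`enumerate_protospacers` reports every 20-mer immediately 5' of an NGG
PAM on either strand. The blunt SpCas9 cut is placed between
protospacer bases 17 and 18 (3 nt 5' of the PAM) — the standard SpCas9
geometry. Candidates are ranked by `|cut_pos - nearest uATG|`, a simple
monotone proxy for "PAM adjacent to the uATG domain"; ties break by
cut position and then plus strand before minus, so rankings are
deterministic. Defaults: GC fraction within [0.30, 0.80], cut within
50 nt of a uATG; both configurable. Off-target scoring is out of scope
(practitioners use dedicated genome-wide tools); the report leaves room
for external scores.

## Genotyping edited lines

Cloned amplicon sequences are aligned globally to the reference
(Needleman–Wunsch with affine gaps, via Biostrings; match +2, mismatch
-3, a gap run of length L costs 5 + L). Alignment columns become
DEL/INS/SUB calls; indels are left-aligned within repeat context so
equivalent alignments produce one canonical edit set, and adjacent
mismatch columns merge into a single substitution. Applying the called
edits to the reference reproduces the clone exactly — a round-trip the
test suite checks on hundreds of simulated alleles and that the scoring
checks against an independent exhaustive-alignment oracle on short
pairs.

Zygosity is reconstructed from clone signatures. The category
definitions are a reconstruction — the source literature names the
categories without defining thresholds — and are deliberately simple:
after noise filtering, all-wild-type clones mean **wild-type**, one
non-empty signature **homozygous**, two signatures **heterozygous**,
three or more **chimeric** (mosaic regeneration). Signatures carried by
fewer than `min_support` clones (default 2) are discarded; if nothing
survives, the call errors rather than guessing.

The noise model matters. Per-base Sanger read errors are
substitutions, and with n clones of an L-nt amplicon at error rate e,
the expected number of *coincident* errors — two clones hitting the
same base the same way — grows like (ne)^2/L and is no longer
negligible at n = 16, L = 250, e = 0.005. A substitution is therefore
treated as allelic only when it recurs in at least a quarter of the
clones (never fewer than `min_support`); real heterozygous or chimeric
substitutions ride in one-half or one-third of clones and pass easily.
Indels are never filtered, because substitution-type read noise cannot
fabricate them. Clone counting cannot distinguish homozygous from
hemizygous lines, so homozygous calls carry an explicit
`hemizygous_possible` flag.

`summarize_cohort` turns per-line calls into the cohort efficiencies:
transformation efficiency = transgenic events / explants, editing
efficiency = edited lines / transgenic events, and per-category
percentages over transgenic events. Percentages are rounded half away
from zero to 2 decimals (base R's `round` is banker's rounding, which
would print 43.33% as 43.33 but 32.255 as 32.25).

## Quantitative summaries

**2^-ddCt.** Technical replicates are averaged per sample and gene
before any differencing; dCt = Ct(target) − Ct(reference gene) per
biological sample; ddCt subtracts the calibrator-condition mean; the
relative quantity is 2^-ddCt. Per-sample relative quantities provide
the dispersion. Replicate handling is a decree (the method's defining
formula says nothing about it); averaging technical replicates first
and letting biological replicates carry the variance is the standard
practice this package follows. No amplification-efficiency correction
is attempted.

**Translational efficiency.** For a dual-luciferase construct,
TE = (LUC/REN activity) / (LUC/REN mRNA); the relative TE divides
treatment by control, so transcriptional effects cancel exactly.

**Tanshinones.** Total tanshinone accumulation (TTA) is the exact sum
of the four quantified analytes (Tan I, Tan IIA, cryptotanshinone,
dihydrotanshinone; mg/g dry weight); fold versus the control line is
reported to 2 decimals, per-analyte percent changes to 1.

**t tests.** `two_sample_t` is pooled-variance Student's t by default
(Welch on request) via `stats::t.test`, with explicit degenerate-case
handling: two constant samples with equal means give t = 0, p = 1.

## The synthetic-data generator

No machine-readable sequence for the motivating 192-nt leader exists
(it appears only as a figure), so the generator *emulates its published
summary statistics, not its bases*. `plant_leader` is a rejection
sampler with a constrained left-to-right filler: planted uATGs and, for
Type 1, their in-frame stops are fixed first; every free base is then
drawn only from letters that create neither an unplanned ATG (sense
strand; uORFs are a sense-strand phenomenon) nor a premature in-frame
stop inside a planted uORF. Attempts whose fixed bases collide are
re-drawn, and — crucially — *truth is defined as the scanner's output
on the final sequence*, re-verified against the plant plan before the
bundle is returned, so incidental sequence interactions can never
desynchronise truth from sequence.

The control emulation (`plant_ck_leader`) plants five Type 1 uORFs of
57, 15, 30, 54 and 84 nt in a 192-nt leader. Their lengths sum to
240 nt, so overlap is forced — the only reading consistent with the
published numbers. The CDS filler is a fixed-length 60-nt main ORF
(ATG ... TAA) with no internal ATG, no internal in-frame stop, and stop
codons planted in both shifted frames so out-of-frame uORFs terminate
inside the main ORF.

Edit-pattern profiles reproduce the study's allele archetypes and are
*verified before return* (`predict_edit_outcome` must confirm the
profile; unsatisfiable profiles raise an infeasibility error):
`disrupt_k_uatg` (3-bp deletions spanning k chosen start codons,
destroying exactly k uATGs, creating none), `preserve_all_uatg`
(default lesions: one 29-bp deletion plus one 4-bp insertion, net
−25 nt, with every uATG intact), `convert_to_type3`, and free-form
`lesion_sizes`. Clone simulation draws from an allele mixture and
applies independent per-base substitution noise (Sanger-like; default
16 clones per line, 0.5% ceiling on the error rate). Expression tables
plant folds under the 2^-ddCt model (Gaussian Ct noise, default sd 0.1
cycles, 3 biological x 3 technical replicates); metabolite tables draw
lognormal replicates around per-line analyte means whose totals
reproduce the published TTA values (the per-analyte split of the
control total is a synthetic stand-in — per-analyte absolutes are not
published).

What the generator does **not** emulate: Kozak context and initiation
strength, RNA secondary structure, realistic Cas9 repair-outcome
spectra, chromatogram-level sequencing artefacts, and the real leader's
base composition. Tests passing on planted data therefore demonstrate
algorithmic correctness (the scanner, the delta logic, the genotyper's
recovery under its stated noise model), not biological predictivity on
real leaders.

## Numerical choices and problem sizes

* Rejection-sampling budgets: 5000 attempts for `plant_leader` (the
  five-uORF control fixture typically succeeds within ~100), 200 for
  edit-pattern verification.
* Alignment scoring: match +2, mismatch −3, gap open 5, gap extend 1
  (a length-L gap run costs 5 + L); deterministic output; sequences are
  capped at 20 kb by default as a guard.
* Reported rounding: percentages and folds half-up to 2 decimals,
  per-analyte percent changes to 1 decimal; raw values are kept
  unrounded in the underlying objects wherever a report rounds.
* The test suite sizes its simulations to run in minutes on one core:
  100 random transcripts (leaders up to ~1.8 kb) for the scanner
  oracle, 200 simulated alleles for the variant-call round trip, 500
  clone-set simulations for zygosity recovery (observed ≥ 98%), 50
  seeds per planted fold for ddCt recovery, and 10 000 null replicates
  for the t test's type-I error.

## Known limitations

* Zygosity thresholds are a reconstruction; lines sequenced with very
  few clones (2–3) cannot express heterozygosity reliably at
  `min_support = 2`, and sub-only alleles within one indel group are
  collapsed if carried by fewer than a quarter of clones.
* The edit engine predicts the consequence of a *given* allele; it does
  not model which alleles Cas9 repair will produce.
* qPCR analysis assumes perfect amplification efficiency (pure
  2^-ddCt); no Pfaffl-style correction, no multiple-testing adjustment
  by default (a Benjamini–Hochberg step can be applied downstream with
  `p.adjust`).
* Minus-strand ORFs, CDS-internal ORFs and reinitiation/leaky-scanning
  models are out of scope.
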