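---
title: "Methods: peptide-to-transcript mapping for glycine-rich antifreeze proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-to-transcript mapping for glycine-rich antifreeze proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpscan)
```

## The inference

Antifreeze proteins (AFPs) of springtails are small secreted proteins
whose mature chains are built from tandem Gly-aa2-aa3 tripeptide repeats
("tracts") folded as polyproline type II helices, linked by short turns
and stabilized by disulfide bonds. When such a protein is purified by ice
affinity and its tryptic fragments are sequenced by tandem MS, the
peptide strings constitute a fingerprint that can single out the encoding
mRNA from an unassembled EST collection — no genome, assembly or homology
search required. `afpscan` formalizes that chain of evidence:

* six-frame translation of every EST, with exact substring search for
  the peptide strings under Ile/Leu collapse;
* extraction of the open reading frame (ORF) containing the hits;
* signal/mature partition of the encoded precursor;
* in-silico tryptic digestion and mass prediction, matched against the
  observed fragment masses and the MALDI whole-protein peaks;
* composition and repeat-tract profiling of the mature chain;
* deterministic ranking of all ESTs carrying hits.

The package treats each stage as an independently testable operation, and
ships a seeded generator that emulates the study's data shapes so the
whole pipeline is verifiable offline.

## Conventions and models

**Coordinates and frames.** All intervals are 0-based half-open. Frames
1–3 are forward offsets 0–2; frames 4–6 are the same offsets on the
reverse complement. ORF coordinates are reported on the forward strand of
the EST regardless of frame.

**Translation.** Standard genetic code; the trailing partial codon is
dropped; stops become `*`. Codons containing `N` translate to `X` rather
than being skipped, so every downstream amino-acid offset maps exactly
back onto the EST — essential for hit self-verification. `X` never
matches any query.

**Ile/Leu collapse.** Collision-induced dissociation cannot distinguish
the isobaric residues Ile and Leu, so both query and translation are
mapped through `I, L -> J` before matching. Near-isobars such as Lys/Gln
(Δ ≈ 0.036 Da) are *not* collapsed: they are resolvable by fragment mass
at the accuracy of modern instruments. Matching is exact; no mismatch
tolerance is offered, because the evidence the pipeline is designed to
reproduce is exact correspondence, and polymorphic near-matches belong to
manual review, not automated ranking.

**ORFs.** An ORF is a maximal stop-free run of a frame translation,
trimmed to its first ATG-encoded Met when one exists; runs without a Met
are kept from the run start, because ESTs are single-pass partial cDNAs
that may be 5′-truncated. The default minimum of 30 codons suppresses
incidental micro-ORFs in decoys while retaining anything plausibly
protein-coding.

**Masses.** Residue masses are the standard IUPAC/Unimod monoisotopic and
average tables, water 18.010565/18.01528 Da, proton 1.007276 Da. Peptide
\[M+H\]+ is monoisotopic (electrospray fragment convention); the whole
chain is reported as the *average* mass of the *reduced* chain, matching
linear-mode MALDI of an intact protein. Each disulfide would subtract
2 × 1.008 Da and is available via the `disulfides` argument, but the
default is reduced: at ±5 Da peak tolerance the distinction (−4.03 Da for
two bonds) is below the resolution the matching operates at. Peptide-mass
matching uses a ±0.02 Da default tolerance — residue-table arithmetic and
values printed in the literature commonly disagree in the second decimal,
so exact equality would be spurious precision.

**Trypsin.** Cleavage after Lys/Arg except before Pro, no other
exceptions. Missed cleavages default to 0; `missed_cleavages = m` adds
all concatenations of up to `m + 1` adjacent fragments.

**Signal peptide.** When no explicit cleavage index is supplied, the
heuristic scans candidate cut points 15–35, requires small residues
(A, G, S, C, T) at −3 and −1 — the classic (−3,−1) rule — and picks the
candidate maximizing the mean Kyte–Doolittle hydropathy of the ten
residues preceding −3 (the hydrophobic h-region). This is deliberately
simple and always overridable; it is a screening device, not a trained
predictor. In the full pipeline a candidate whose ORF offers no valid
site is reported with the whole ORF as mature (`signal_method = "none"`)
rather than dropped, so ranking still covers every EST with hits.

**Charge satellites.** A peak at m/z *s* is accepted as the z-charged
version of a neutral parent *M* when |z·(s − 1.007276) − M| ≤ z·tol.
Note this is a *check*, not an assumption: the operation reports the
implied neutral mass and delta so inconsistent satellite assignments
(e.g. a supposed +2 peak whose implied neutral is hundreds of Da off)
surface as `consistent = FALSE` with the discrepancy attached.

**Composition.** The profile follows the amino-acid-analysis reporting
convention: ten categories (Asx = Asp+Asn, Ser, Gly, Thr, Ala, Pro, Val,
Lys, Arg, Other = Met+Leu+Ile+Glx+Tyr+Phe+His), computed as mol% of the
chain with Cys excluded from numerator and denominator (Cys is destroyed
or modified in standard hydrolysis). Trp, typically absent or undetected
in such analyses, is excluded the same way by default; `include_trp =
TRUE` counts it in Other. Unrounded values sum to exactly 100; display
values are rounded half-up to integers and therefore need not.

**Tracts.** A tract is a maximal run of ≥ 2 consecutive in-frame
triplets each beginning with Gly. Candidates from all three phases are
collected and the longest non-overlapping ones kept greedily (ties:
leftmost, then lowest phase). A tract is "GG-type" when more than half
its triplets carry Gly at position 2. The definition is an explicit
formalization of a pattern usually described informally; `min_repeats`
is exposed because reasonable analysts draw the minimum differently, and
a published tract count should be checked against its own definition
rather than assumed to match this one.

**Alignment.** `global_align()` is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` — BLOSUM62, gap open 10, gap extend 0.5,
end gaps penalized (the EMBOSS-needle convention, which is the de facto
dialect for published identity/similarity percentages). Identity and
similarity are percentages of the alignment length; "gaps" counts
maximal gap runs (openings) across both rows. Because co-optimal
tracebacks can differ between argument orders, the alignment is computed
in a canonical order and the rows swapped back, making all reported
statistics invariant under argument swap.

**Dot plots.** Every pair of 0-based window starts (i, j) is scored by
percent identity of the two windows (defaults: 20 bp window, strict
> 50 % threshold; `N` never matches). Coordinates, not pixels, are the
contract; `plot()` renders them. `diagonal_coverage()` summarizes a
region pair as the fraction of window starts lying within ±3 bp of the
region diagonal, separating conserved segments (continuous diagonals,
coverage near 1) from divergent ones (scatter, coverage near 0).
Windowed percent identity was chosen over the raw-substitution-score
dialect of classic dotmatcher because it makes the threshold
interpretable and the oracle trivially checkable.

## The synthetic study generator

`afp_generator_params()` fixes the emulated study conditions; a single
integer seed fully determines every output, and all randomness is drawn
in private streams so global RNG state is untouched.

| parameter | default | rationale |
|---|---|---|
| `n_decoys` | 500 | search-space scale at which ranking is exercised |
| `decoy_length_range` | 300–900 bp | typical single-pass EST lengths |
| `utr_gc_target` | 30 % | AT-rich UTRs (observed range ~23–40 %) |
| `cds_gc_target` | 55 % | coding GC (observed range ~46–61 %) |
| `n_tracts` | 6 | tract count of the characterized small isoform |
| `repeats_per_tract_range` | 4–6 | yields ~90–110-residue mature chains at ~40–45 mol% Gly, matching the Gly-dominated (>35 mol%) composition of this protein family |
| `turn_length_range` | 3–4 aa | short inter-helix turns |
| `aa2_gly_fraction` | 0.5 | about half the tracts GG-type |
| `n_cys` | 4 | two disulfides' worth, placed in turns |
| `detection_prob` | 0.8 | realistic per-peptide MS/MS detection |
| `mass_noise_sd` | 2 Da | linear-MALDI accuracy; tolerance floor 5 Da |
| `isoform_mass_offsets` | 0/51/74/594 Da | isoform peak-series spacing |

Construction guarantees that make the ground truth exact rather than
probabilistic:

* turns contain no Gly, so detected tract count equals the planted count;
* turns end alternately in Lys/Arg, giving a known tryptic fragment
  structure with every fragment ≥ 3 residues;
* cysteines go only into turn interiors;
* the signal peptide is a Leu core with an Ala-Pro-Ala (−3,−2,−1) motif,
  which makes the true cleavage the unique maximizer of the stripping
  heuristic's score;
* codons are chosen greedily to steer the running CDS GC to its target
  (infeasible targets are rejected with the achievable range);
* the 5′UTR is resampled until the ORF in the CDS frame is exactly the
  designed precursor — i.e. no upstream in-frame ATG is left open, as in
  a clean full-length cDNA;
* decoys are i.i.d. nucleotide draws, rejection-checked to contain no
  true peptide's coding string in any frame, so any hit on a decoy is
  impossible by construction, not merely unlikely.

What the generator deliberately does **not** emulate: sequencing-error
profiles (Ns, chimeras, vector, poly-A tails), shared homologous decoys,
isotope envelopes, intensity models, or peptide polymorphisms between
isoforms. Passing tests therefore demonstrate the correctness of the
inference machinery under clean planted-truth conditions, not robustness
to every artifact of real EST archives; on real data the exact-match
scan is conservative (polymorphic fragments simply do not hit).

## Validation strategy and problem sizes

Every non-trivial operation is tested against an independent oracle:
digestion against a position-by-position scanner, the six-frame scan
against an exhaustive (frame, offset) loop on collections of ≤ 30 ESTs,
dot plots against the double loop on ≤ 200 bp sequences, translation
against the Bioconductor translator, tract selection against an
independent run enumerator plus greedy-completeness checks. Identity
checks (digest reconstruction, mass additivity within 1e−6 Da,
hit re-translation) run on randomized chains under fixed seeds.
End-to-end recovery is measured over 20 seeded studies at the default
conditions (1 planted transcript, 500 decoys), requiring the planted EST
to be the unique top candidate in ≥ 95 % of runs; the suite and the
acceptance script each complete in about a minute on a single core.
These sizes were chosen as the smallest at which every claim is
exercised at full fidelity; all of them scale with parameters if larger
runs are wanted.

## Known limitations

* Exact substring matching cannot recover transcripts whose peptides all
  differ from the queried isoform (paralog/isoform polymorphism); such
  fragments are evidence for *additional* isoforms and are out of scope
  for automated ranking.
* The signal-peptide heuristic is a (−3,−1) + hydropathy screen; for
  borderline precursors supply `signal_cleavage` explicitly.
* The tract count of a published sequence depends on the tract
  definition; compare definitions before comparing counts.
* Whole-mass matching at ±5 Da cannot distinguish reduced from
  disulfide-bonded chains; both predictions are available.
* BLAST-style similarity search and EST assembly are intentionally
  absent: the pipeline consumes pre-assembled FASTA and relies on the
  peptide scan, which is reproducible without external databases.
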