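---
title: "Biogenesis-guided miRNA curation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biogenesis-guided miRNA curation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircurate)
```

## The problem

Small RNA sequencing libraries contain far more than miRNAs: turnover
fragments of tRNAs, rRNAs and snoRNAs, repeat-derived reads, and artifacts
of library preparation all accumulate on loci that can superficially
resemble miRNA genes. Canonical miRNA biogenesis, however, leaves a highly
characteristic footprint. Drosha excises a 60--100 nt stem-loop precursor
from the primary transcript and Dicer cleaves it into a ~22-nt duplex with
2-nt 3' overhangs; one strand (the mature miRNA) loads into Argonaute while
its partner (the miRNA*) is degraded. In read space this produces two
sharp, ~22-nt read peaks spaced 10--20 nt apart on the precursor, with
homogeneous 5' ends, and in structure space a hairpin whose two read peaks
pair into a duplex with the RNase-III-characteristic overhangs. `mircurate`
operationalizes these observations as an auditable accept/reject decision
tree over candidate precursor loci.

## The workflow

1. **Inputs.** Candidate precursors (FASTA + BED6), pooled collapsed reads
   (sequence/count TSV or `_x<count>` FASTA), an optional ncRNA annotation
   track (BED6 with the class in the name column), optional per-precursor
   EST evidence flags, and optionally a genome FASTA from which each
   precursor is re-extracted with 100 nt of flanking context
   (`flank_nt`). The flanks matter: they expose expression irregularities
   and let the star arm be found even when the annotated precursor is
   drawn too tight.
2. **Alignment** (`align_reads`). Each collapsed read is placed on each
   precursor by semi-global alignment at up to `max_errors = 2` unit-cost
   edits -- the budget that accommodates non-templated 3' A/U additions and
   A-to-I editing read as G-to-A. Only the forward strand is searched
   because the library protocol is directional. Reads mapping to several
   precursors are assigned to all precursors achieving their minimal error
   count, with the full count credited at each tied location
   (`resolve_multimap`); fractional allocation is deliberately avoided
   because the decision tree reasons about per-locus evidence and rejects
   high-copy loci outright.
3. **Arm calling** (`call_arms`). Peaks are defined by modal 5' start
   rather than coverage maxima: 5' processing is precise while 3' ends
   jitter, so the start mode is the sharpest statistic available. The
   second peak is sought among reads overlapping the first by at most half
   their length. The verdict is geometric -- both widths within
   `22 +/- 4` nt and spacing within 10--20 nt -- and not inferential; no
   statistical bimodality test is attempted because the criterion in use
   by curators is geometric.
4. **Structure** (`fold_hairpin` / `check_duplex`). The window spanning the
   called peaks plus 10 nt is folded; the 5' arm must pair into the 3' arm
   (`duplex_min_paired = 0.6` of its positions), a real loop
   (>= `min_loop_nt = 3`) must separate the arms, and both duplex strands
   must show a 3' overhang of `2 +/- 1` nt. G--U wobbles count as pairs.
5. **Decision tree** (`decide`). Fixed rule order, first failure wins:
   insufficient pooled reads (< 50), too few distinct reads (< 5), more
   than 30 genomic copies without cistron membership, ncRNA
   overlap/tRNA signature, reverse-complement artifact, missing
   pattern-or-foldback, missing expression evidence (cistron or EST), then
   acceptance. Cheap count filters run first and expression evidence last;
   a fixed order is a prerequisite for any single-reason tally, so the
   order is part of the public contract.
6. **Organization** (`assign_designations`, `build_families`,
   `build_clusters`, `tally_expression`). Arms become mature/star products
   when one arm holds strictly more than 80% of the arm-assigned reads,
   else 5p/3p. Accepted matures are grouped into seed families and
   precursors into genomic cistrons; expression is tallied per sample as
   relative frequencies with a log2 layer.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `max_errors` | 2 | edits/read | alignment error budget |
| `flank_nt` | 100 | nt | genomic context per side |
| `min_read_count` | 50 | reads | pooled support floor |
| `min_nonredundant` | 5 | sequences | distinct-read floor |
| `max_genomic_locations` | 30 | loci | repeat filter (cistron-exempt) |
| `peak_width_nt` (+/- `peak_width_tol_nt`) | 22 +/- 4 | nt | accepted peak width |
| `peak_spacing_min_nt`..`peak_spacing_max_nt` | 10..20 | nt | loop clearance window |
| `overhang_nt` (+/- `overhang_tol_nt`) | 2 +/- 1 | nt | duplex 3' overhang |
| `arm_dominance` | 0.80 | fraction | mature/star vs 5p/3p (strict >) |
| `cluster_distance_nt` | 5000 | nt | cistron chaining gap |
| `family_max_mismatch`, `family_max_5p_offset` | 1, 1 | -- | family allowance |
| `seed_start`..`seed_end` | 2..8 | position | seed region |

All of them live in `curation_config()`; no other function hard-codes a
threshold. The "~22 nt" and "sharp" qualifiers of the biological
description required explicit operationalization: the width tolerance of
+/- 4 nt spans the 19--24 nt size selection window of the library
protocol with a margin, and "sharp" is recorded as an advisory
`FUZZY_FIVE_END` diagnostic when fewer than half of the 5'-arm reads share
the modal start -- advisory because no published threshold exists, so it
must not silently reject.

## Folding backends

Two engines sit behind one adapter, and everything downstream consumes
only the resulting pair table, so they are interchangeable:

* **`rnafold`** shells out to ViennaRNA's `RNAfold` for a
  minimum-free-energy structure. This is the default when the executable
  is on the PATH (`engine = "auto"`), matching the thermodynamic folding
  that curators use in practice.
* **`nussinov`** is the built-in, dependency-free fallback: Nussinov-style
  base-pair maximization over {AU, GC, GU} with a minimum loop of 3 nt and
  deterministic tie-breaking (the 5'-most position pairs its lowest
  admissible partner). It is exact as a pair-count maximizer -- the test
  suite pins it against an independent memoized recursion -- but pure
  count maximization has no notion of helix stacking, so on sequences with
  many near-tied registers (G--U wobbles create a lot of them) it can
  report a shifted register with the same pair count and thereby distort
  the measured overhangs by a few nucleotides. That is a property of the
  objective, not a bug; it is why the thermodynamic engine is preferred
  when available, and why the folder's own correctness tests use designed
  duplexes whose non-core positions cannot pair at all.

The fold window (called peaks +/- 10 nt) is itself a design choice: wide
enough to expose the full duplex plus overhangs, narrow enough that
flanking sequence cannot dominate the structure. The loop size reported in
the final verdict is measured between the innermost *inter-arm* pair, so a
spurious mini-hairpin in a flank cannot masquerade as the loop.

## Decision-tree specifics

Two orderings deserve comment. The tRNA signature (most frequent read
ending in a CCA that is not genome-templated at its aligned position) is
folded into the ncRNA rule rather than standing alone, since both identify
the same failure mode -- turnover products of an abundant structured RNA.
And the unimodality call distinguishes three spacing failures: candidate
peaks that overlap (one smeared mode, as under uniform tRNA-style tiling)
are `UNIMODAL`; non-overlapping peaks closer than 10 nt lack room for a
loop (`NO_CLEARANCE`); peaks farther than 20 nt apart are
`SPACING_OUT_OF_RANGE`. A literal "second disjoint mode" reading would
label uniform tiling bimodal with negative spacing, which is biologically
meaningless; the overlap test resolves that degeneracy deterministically.

The complement-artifact rule screens each candidate's dominant read
against the matures accepted so far, so candidates are processed in
descending read support; the better-supported locus always wins the
palindrome tie.

## The family rule

Published practice permits "no more than one symmetric mismatch or G--U
wobble base pair or a 1-nt 5' offset" between family members, motivated by
the seed (positions 2--8) determining shared targets. Applied over the full
mature length this would split known families whose members diverge 3' of
the seed (miR-1 vs miR-206 differ at four 3' positions yet share a family),
so `mircurate` evaluates compatibility over the 5' region through the seed
end (positions 1..`seed_end`). The single allowance is strict by default
(one mismatch OR one wobble OR one offset -- `family_strict = TRUE`);
wobble-equivalent substitutions are counted exactly like mismatches since a
single-stranded comparison cannot distinguish them. Families are connected
components (single linkage) of the compatibility graph -- cliques would
split let-7-like series -- and are named after their naturally-ordered
lowest member, `sf-<member>(<n>)`. Natural ordering compares digit runs
numerically so that mir-9 sorts before mir-21 and mir-125.

Cistrons chain precursors whose loci lie within 5 kb on one
chromosome+strand (single linkage; a gap of exactly 5000 nt merges, 5001
splits), then merge clusters sharing a multi-copy miRNA -- operationalized
as an identical mature sequence, the condition that makes copies
indistinguishable in read space.

## The simulator

`make_cohort()` generates the labeled cohorts the tests and the acceptance
script run on: 100 prototypical hairpins, 50 tRNA-like decoys, 25
under-sequenced loci, 25 repeat-derived loci, embedded on a synthetic
chromosome with realistic spacing (half the prototypical loci sit in
cistron pairs within 5 kb). Prototypical stacks draw `depth = 500` reads
split 90/10 between arms, with 5' jitter (1 nt, 5%) rarer than 3' jitter
(up to 2 nt, 30%), 10% non-templated 3' A/U additions, and 2% internal
G-to-A changes; matures carry an 80% U/A bias at position 1. tRNA decoys
tile a ~73-nt transcript uniformly and their top read ends in a partially
non-templated CCA (the genomic template ends in C; a fully non-templated
CCA could not map within the 2-edit budget at all). Repeat decoys carry
their copy number in the BED score column rather than materializing >30
genome copies, keeping fixtures small while exercising the same rule.

Hairpin loops and loop-adjacent overhang bases are drawn from non-pairing
alphabets (all-A loops; no U/T in the 5'-arm overhang) so that the designed
2-nt overhangs survive folding. This is the one place the generator is
cleaner than biology: real loops pair partially, real stems bulge. The
simulator also does not model sequencer-specific error profiles, piRNAs,
adapter artifacts, or non-canonical biogenesis (mirtrons and
Drosha/Dicer-independent miRNAs are explicitly outside the decision tree's
scope). Passing the closed-loop tests therefore demonstrates that the
detector recovers the canonical signature it was built for under realistic
noise levels -- not that it would sweep a real library at a known error
rate.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based closed
  appears only in rendered views. One convention prevents off-by-one
  drift.
* T and U are equivalent on input; the canonical internal alphabet is DNA,
  converted to RNA only for folding.
* Alignment ties within one precursor resolve to the leftmost start, then
  the shortest span; mode ties resolve to the smaller position; traceback
  preference is fixed. Identical inputs always give identical outputs.
* Empty read stacks refuse arm calling (precondition error); fold windows
  under 40 nt refuse folding (`TOO_SHORT`); a zero-read sample yields a
  flagged all-zero expression column; log2 profiles floor zero frequencies
  at 1e-6.
* The simulator threads a single seed through every draw; cohorts are
  byte-identical across runs with the same parameters.

## Problem sizes

The default validation cohort is 200 candidates at depth 500 (about 7,000
distinct pooled reads), which the full pipeline processes in well under a
minute on a single core. The aligner is cross-checked against a
brute-force window scan on 1,000 random read/precursor pairs, the folder
against exhaustive pair-count maximization on 50 windows of up to 60 nt,
and arm recovery on 50 independent simulations at depth 150. These sizes
were chosen so the entire closed loop -- generator, pipeline, oracles --
runs comfortably as an ordinary test suite while still estimating each
rate from enough draws to be stable.

## Known limitations

* Non-canonical miRNAs (mirtrons, Dicer- or Drosha-independent loci) fail
  the decision tree by design and need different methods.
* The built-in folder's pair-count objective can misplace duplex ends on
  wobble-rich stems (see above); prefer the thermodynamic engine for real
  data.
* Multi-sample thresholding is pooled: the 50-read floor applies to the
  pooled stack, with per-sample abundance available through the expression
  matrix rather than through per-sample re-curation.
* EST evidence is a per-precursor input flag, not a live genome-browser
  lookup; cistron membership is computed from the candidate loci
  themselves.
* The expression module emits matrices only; heatmap rendering and sample
  clustering belong to downstream tooling.
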