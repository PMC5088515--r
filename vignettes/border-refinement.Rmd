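---
title: "Refining synteny block borders with identity profiles and a threshold FSM"
author: "csbRefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining synteny block borders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csbRefine)
```

## The problem

Whole-genome comparison tools report conserved blocks (computational
synteny blocks, CSBs) as chains of high-scoring alignment fragments. The
chained borders are approximate: they stop at the last fragment boundary,
tens of nucleotides short of — or past — the biological junction, and the
region between two blocks flanking a rearrangement (the breakpoint, BP) is
left as one undifferentiated stretch. When the junctions carry mobile
elements, as bacterial inversion junctions typically do, the space between
two blocks actually decomposes into five parts on each genome:

    block A | BP | repeated element(s) | BP | block B

`csbRefine` takes two genome sequences, an adjacent pair of CSBs and the
repeat records between them, and refines the block borders to nucleotide
resolution while reporting each breakpoint as an explicit interval (or
point — the method does not force either). It also extracts two families
of control intervals: the PRASB (the stretch of the adjacent refined block
with exactly the paired breakpoint's length) and the gap (the region
strictly between the two breakpoints of one junction), which downstream
annotation analyses compare against the breakpoints themselves.

## The procedure

Refinement of the X and Y genome runs in two independent, symmetric
branches whose results are combined at the end (x coordinates from the X
branch, y from the Y branch). One branch junction proceeds in five steps.

**1. Region of interest (ROI).** On the branch axis the ROI runs from
`min(A_end, B_start, repeat starts) - offset` to
`max(A_end, B_start, repeat ends) + offset`. The `offset` padding
(default 100 nt, required to exceed the identity half-window `N`)
guarantees that the ROI begins inside genuinely homologous block-A
sequence and ends inside block B, so every difference signal starts and
ends on a high plateau and each block profile has a *known* plateau zone
and a known background zone — both facts the later normalization relies
on.

**2. Virtual blocks.** Every element (both blocks, every repeat record) is
stretched or trimmed so its branch interval equals the ROI, and its
partner-axis interval is shifted by the same signed amounts
(`alpha_L = start - ROI_start`, `alpha_R = ROI_end - end`). For a
reverse-strand element the alignment runs antidiagonally, so the left
branch extension maps to the right partner end and vice versa. Because the
alpha shifts anchor the partner window through the element's *far* border,
any coordinate error in the input tables displaces the window off the true
alignment diagonal by the same amount; a `partnerSlack` margin (default
100 nt) on both partner ends keeps the diagonal inside the window when
borders are only approximate.

**3. Identity profiles.** Each virtual block's two subsequences are
aligned (reverse-strand partners reverse-complemented first) and the
alignment is reduced to a binary match vector — 1 where the residues are
identical and neither is a gap or `N`. Columns that are gaps in the branch
sequence carry no branch coordinate and are dropped, so every profile of
one run has exactly the ROI's length and profiles are comparable position
by position. The match vector is then smoothed by a weighted bank of box
filters: scales `i = 1..N` (window width `2i+1`, default `N = 50`) are
each averaged in linear time via prefix sums and combined with weights
summing to 1 (default uniform), rescaled to 0–100. Small windows track
high-frequency identity changes, large windows the smooth trend; the
mixture responds to transitions at every frequency at once.

Two design choices here deserve their own paragraphs, because both were
forced by failure analysis rather than taste.

*Alignment mode.* The virtual windows are oversized approximations that
deliberately contain non-homologous margins. Forcing those margins through
a strict end-to-end alignment manufactures a 45–60% spurious match
background (optimal global alignment of random DNA picks up matches at
well above the per-site random rate), and the smoothed fluctuations of
that background sit exactly where the FSM thresholds need clean separation.
The pipeline therefore aligns virtual blocks in *local* mode: the
alignment covers the maximal-scoring contiguous segment — in practice the
homologous stretch, whose boundary falls within a nucleotide or two of the
true junction — and uncovered branch positions contribute zeros. Strict
global alignment remains the contract mode of `nwAlign()` (and is used for
block-identity metrics); only the virtual-block profiles use local mode.
For the trimming to work, alignment of non-homologous sequence must score
net-negative; the default scoring (match +4, mismatch −4, gap of length L
costing 8 + 5L) is chosen so a gap–gap column pair costs more than a
mismatch, which guarantees that property.

*Normalization.* Profiles are compared by difference, so each is mapped
affinely onto a common 0–100 scale. Plain min–max anchoring is fragile
twice over: the extremes of a sliding mean are single fluctuation points
(pinning the background floor about two standard deviations above zero),
and when the plateau or the background occupies a small fraction of the
ROI — a 3 kb repeat cluster leaves the block plateau at 4% of the ROI —
global quantiles land in the wrong regime entirely. The default
`"quantile"` mode instead anchors on *structural* zones that the ROI
construction guarantees: block A's plateau is the first `offset` positions
and its background the last `offset` (block B mirrored; the consensus
profile is high over the repeat span and background outside it). The high
anchor is the median over the plateau zone, the low anchor the median over
the background zone, and values are clamped to [0, 100]. `"minmax"` and
`"none"` remain available for sensitivity analysis.

**4. Repeat consensus.** When repeat records are present, their projected
match vectors are combined into a consensus: each vector is masked to the
repeat's own branch-axis span (outside it, a virtual repeat's matches are
alignment background, not repeat coverage), summed into the sum match
vector, and thresholded — a position is consensus-covered when at least
25% of the records match there (inclusive, so one record in four
qualifies). Before summation each vector receives a 1 nt match-tolerance
dilation: every record covering a branch position reuses the same branch
residue, so a single substitution in the branch repeat copy would knock
the position out of all records simultaneously and punch correlated holes
in the consensus plateau. The consensus binary vector is then smoothed and
normalized exactly like a block profile.

**5. Difference signals and the FSM.** With repeats, two signals are
scanned independently: `|I_A − V_CI|` for the block-A/repeat junction side
and `|V_CI − I_B|` for the repeat/block-B side; without repeats, the
single signal `|I_A − I_B|`. Each signal is high where exactly one profile
is locally similar to its partner and dips where the two transitions
cross. A six-state finite-state machine scans left to right with two
inclusive thresholds (defaults `u1 = 80`, `u2 = 20`): states 1–3 find the
breakpoint start (the last index at or above `u1` before the signal
reaches `u2`), states 4–6 mirror them for the end (the first index back at
`u1`), and the scan then resumes, so several dips yield several pairs.
A dip still open when the signal ends is discarded; so is any breakpoint
longer than `maxBpLength` (default 5000 nt) — discarded, not truncated,
because truncation would fabricate an unobserved boundary.

Refined coordinates follow the shared-endpoint convention visible in the
output tables: the left block's refined end *is* the breakpoint start, the
repeat cluster's refined start *is* the breakpoint end, and breakpoint
length is `end − start`, so a sharp transition gives length 0–1. A
junction side with no complete transition is flagged `unresolved` (its
border keeps the input value); when only one branch resolves, the record
is flagged `partial`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `offset` | 100 nt | ROI padding; must exceed `N`; fixes the plateau/background zones |
| `N` | 50 | largest half-window of the filter bank |
| `weights` | uniform | per-scale weights, sum to 1 |
| `normalize` | `"quantile"` | profile normalization mode |
| `u1`, `u2` | 80, 20 | FSM thresholds on the 0–100 difference signal |
| `consensusThreshold` | 0.25 | inclusive repeat-coverage fraction |
| `maxBpLength` | 5000 nt | breakpoint size cap (discard, not truncate) |
| `match`, `mismatch` | +4, −4 | substitution scores (`N` always mismatches) |
| `gapOpen`, `gapExtend` | 8, 5 | gap of length L costs `8 + 5L` |
| `partnerSlack` | 100 nt | partner-window margin absorbing border error |
| `dpGuard` | 1e8 cells | refuse larger single alignments |

## The simulator, and what passing it does and does not show

`simulatePair()` builds the study condition end to end: a random
AT-rich backbone (default 50 kb, GC 0.30), one implanted inversion
(default 10 kb), and transposon-like repeat clusters at both junctions of
both genomes (default two tandem 1.5 kb copies per genome per junction,
four copies per junction overall). The two genomes carry *different*
repeat templates at the same junction — swapped between genomes across the
two junctions — mirroring real rearrangement junctions where each genome
hosts its own mobile element while every element still has homologs in the
partner genome. Each copy is mutated independently (so the 25% consensus
rule is genuinely exercised), both genomes then diverge by independent
per-site substitutions (default 2%) and optional short indels, and every
*CSB* border in the emitted tables is jittered uniformly by ±30 nt so
refinement has work to do. Repeat records are emitted with exact extents
and with the merged-diagonal structure a dotplot of two tandem arrays
actually produces (one full-length diagonal record plus the off-diagonal
single-copy records): repeat records are alignment products in real
pipelines, and per-copy records with jittered borders would fabricate
coverage seams no aligner would emit. Ground truth (junction coordinates
on both genomes, repeat spans, applied jitter, indel maps) is returned
alongside.

What the simulator does **not** model: transposition machinery (target
site duplications, inverted terminal repeats), compositional
heterogeneity, selection gradients between coding and non-coding sequence,
or large indels. Passing the recovery study therefore shows that the
signal machinery localizes clean junctions under realistic divergence and
border noise — not that the method handles every genomic pathology; on
real data the identity plateaus are rougher and transitions can be
genuinely gradual, which is why breakpoints are reported as intervals.

With the defaults, 100 seeded replicates recover about 95-98% of
breakpoint midpoints within ±20 nt of truth (median error ~1 nt), every
replicate keeps the block ≤ BP ≤ repeat ≤ BP ≤ block partition intact, and
re-refining a refined result moves no border by more than the smallest
window scale. Those numbers are recomputed, not quoted, by the test suite
and by `scripts/acceptance.R`.

## Numerical and degenerate-input choices

- Edge windows are clamped with actual-size divisors so profiles keep the
  full ROI length; the `edge_valid` attribute records where the largest
  window is complete. The offset keeps the informative region interior.
- A constant (flat) profile normalizes to all zeros with a warning; the
  affected junction side comes out `unresolved` rather than erroring —
  identical sequences are a reportable condition, not a crash.
- ROIs are clamped to the sequence ends with a warning; clamping can
  shorten the guaranteed plateau, which the warning says explicitly.
- Threshold comparisons (`u1`, `u2`, consensus 25%) are inclusive.
- Alignments are deterministic (fixed traceback in the backend), so the
  whole pipeline is a function of its inputs; the only randomness lives in
  the simulator behind a single seed.
- Blocks whose metric alignment would exceed `dpGuard` are scored by
  chunked alignment in successive proportional 5 kb windows; this is an
  approximation used only for the reported identity percentage of large
  refined blocks, never for border placement.

## Problem sizes used in the checks

The bundled tests exercise the full pipeline on 12 kb pairs (400 nt repeat
copies) for speed and run the complete study condition — 100 replicates of
the 50 kb / 10 kb-inversion / 1.5 kb-repeat configuration — in the
acceptance suite and in `scripts/acceptance.R`. A single replicate refines
in a few seconds; the full study takes on the order of ten minutes.

## Known limitations

- The combination rule for the two branches (x from X, y from Y) assumes
  the branches agree on which junctions exist; when they disagree the
  resolved branch wins and the record is flagged `partial`.
- A junction cluster is treated as one consensus signal, yielding exactly
  two breakpoints per sequence per junction; nested or interleaved repeat
  families inside one junction are not decomposed further.
- Border placement inherits the smoothing kernel's resolution: with the
  default bank the practical localization floor is a few nucleotides, and
  threshold crossings shift by tens of nucleotides when divergence pushes
  plateau identity toward `u1`.
- The breakpoint-size cap discards, rather than flags-and-truncates,
  implausibly wide transitions; the affected border stays unresolved.
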