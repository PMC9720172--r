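---
title: "Designing oligonucleotide sets for gene assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing oligonucleotide sets for gene assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligodesign)
```

## The problem

Chemical DNA synthesis is limited to oligonucleotides of roughly 60 bp,
so a gene of hundreds to thousands of base pairs is assembled from a set
of overlapping oligos by polymerase chain reaction (PCR) or ligase chain
reaction (LCR). During assembly, every pair of adjacent oligos must
anneal through its shared overlap at a single reaction temperature. If
the overlaps' melting temperatures (Tm) are scattered, some junctions
hybridize weakly or mis-hybridize, and assembly errors accumulate. The
design problem is therefore: cut the target sequence into overlap
regions whose Tm values are as uniform as possible, and emit the
corresponding oligos and amplification primers.

`oligodesign` implements a three-stage pipeline:

1. **Initial split** — the sequence is cut into `L` near-equal segments
   (each segment is one overlap region; the two terminal segments double
   as the PCR primer regions).
2. **Iterative boundary refinement** — segment boundaries are shifted to
   reduce the standard deviation of the segment Tm vector until the
   per-sweep improvement drops below a threshold.
3. **Depth-first end-shrink search (gapped mode)** — each overlap may
   lose up to `B` bases from its ends; a branch-and-bound depth-first
   search finds the shrink assignment minimizing the overlap-Tm standard
   deviation. Excised bases become short single-strand gaps that the
   polymerase fills during cycling, so this output is for *gapped* PCR
   assembly; the unshrunk output is for gapless PCR or LCR.

## Melting-temperature model

Duplex formation enthalpy and entropy are computed with the
nearest-neighbor model using the SantaLucia (1998) unified parameter set
(shipped as a plain-text table in `inst/extdata`, with provenance in its
header): dH and dS are sums over the n−1 adjacent dinucleotide stacks,
plus initiation terms for each terminal base pair (A·T vs G·C) and a
symmetry correction for self-complementary duplexes. The two-state Tm at
1 M Na⁺ is

    Tm[K] = 1000 * dH / (dS + R * ln(CT / x)),   R = 1.9872 cal/(mol K)

with total strand concentration `CT` and symmetry factor `x` (4 for
non-self-complementary duplexes, 1 otherwise, detected automatically).
Monovalent salt is corrected on the reciprocal temperature with the
Owczarzy (2004) quadratic-in-ln[Na⁺] formula. Among the published
monovalent corrections we chose this one because it corrects 1/Tm (the
form the underlying reference works in) and is the current standard in
primer-design software; the engine matches an independently coded
implementation to better than 1e-9 °C, and agrees with Biopython's
`Tm_NN` (same table, same correction) to ~2e-3 °C, the residual being
Biopython's use of R = 1.987.

Defaults are `na_molar = 0.05` M and `ct_molar = 1e-6` M — conventional
assembly-buffer conditions; both are configurable everywhere and are
recorded in every report footer. Mg²⁺ and mismatch/dangling-end
thermodynamics are out of scope. Ambiguity codes are rejected: synthesis
needs a fully specified sequence.

## Segmentation and the overlap-length band

`initial_split()` chooses the segment count `L` as `round(n /
target_len)` whenever the resulting near-equal lengths (differing by at
most 1 bp, remainder distributed from the left) stay inside the
overlap-length band `[seg_min, seg_max]` (defaults 20 and 30 bp), and
otherwise the nearest count that does. The band encodes the rule of
thumb that splitting at 20–30 bp yields overlaps of 20–30 bp and oligos
of 40–60 bp; without it, refinement drifts segment lengths far enough
(15–40+ bp) that roughly a third of oligos leave the 40–60 bp envelope
the downstream chemistry expects.

`refine()` sweeps the internal boundaries left to right. Each boundary
moves to the position, within `max_shift` bases and the band, that
minimizes the standard deviation of the full segment-Tm vector; only
strictly improving moves are accepted (ties prefer staying put, then the
smaller displacement, then leftward — full determinism). Sweeping stops
when the drop in standard deviation between sweeps falls below
`var_threshold` (default 0.001 °C, which converges in a handful of
sweeps) or at `max_iter`.

Two design points deserve a note:

* **Move width.** With unit moves (`max_shift = 1`) the refiner stalls
  in strong local minima: on a 500 bp uniform-random gene it stops at a
  segment-Tm std of 4.4 °C with *no* single ±1 bp move improving, while
  wider moves reach 2.7 °C and the end-shrink search then reaches
  1.5 °C. The default is therefore `max_shift = Inf` (exact coordinate
  descent over each boundary's feasible window); `max_shift = 1`
  restores the minimal move set.
* **Merge-then-resplit.** An alternative reading of the iteration step
  merges the two segments with closest Tm and re-splits them. With the
  full-window move set this is subsumed: relocating one boundary
  anywhere between its neighbors *is* a merge of the two adjacent
  segments followed by an optimal re-cut, so no separate flag is
  provided.

The refiner is greedy and guarantees only a local optimum (monotone
non-increasing history, termination, idempotence at convergence — all
asserted in the test suite), not global optimality; the problem has no
known efficient exact solution and the published approach makes the same
trade.

## The end-shrink search

For overlap `i` with boundaries `[b_{i-1}, b_i)`, a shrink pair
`(a_i, b_i')` moves the effective duplex to `[b_{i-1}+a_i, b_i-b_i')`,
subject to `a_i + b_i' ≤ B` (default budget 3) and a residual length of
at least `min_overlap_len` (default 15 bp, hard floor). The oligo whose
end sits on a shrunk flank is trimmed to the effective overlap, so every
excised base is a gap on exactly one strand, strictly inside the
opposite-strand oligo that templates its fill-in. The two terminal
flanks (5' of the first overlap, 3' of the last) carry no oligo end; no
opposite strand could fill a gap there, so their shrinks are pinned to
zero and the PCR primers stay anchored on the template termini.

The search is depth-first over overlaps, left to right, candidates per
overlap ordered by total shrink then left shrink. The objective is the
*population* standard deviation (divide by `L`) of the effective overlap
Tm vector — the convention used everywhere in this package, including
reports; exact ties are broken toward the smaller total shrink (fewer
gap bases), then the lexicographically smaller assignment, making the
optimizer bit-deterministic.

Pruning uses the identity that the sum of squares about the mean is the
minimum over μ of the sum of squares about μ. Given a fixed prefix, the
best achievable final sum of squares is

    min over μ of [ SS_prefix(μ) + Σ_{remaining i} min_c (t_ic − μ)² ]

because, given μ, the remaining overlaps decouple. This is piecewise
quadratic in μ and minimized in closed form per breakpoint interval from
precomputed suffix tables, so the "bound" is in fact the exact optimal
completion value; a branch is cut when it exceeds the incumbent (with a
1e-12 relative slack so floating-point noise can never discard an exact
tie). The incumbent is seeded by the same identity applied to the full
problem — a one-dimensional scan of `F(μ) = Σ_i min_c (t_ic − μ)²`.
Seeding and pruning never change the returned optimum (asserted against
a prune-off exhaustive run and an independent enumeration oracle);
empirically they keep explored nodes growing like ~N^1.7 over 200–3000
bp (58 → 6469 nodes, about 2 s at 3 kb), comfortably inside the
quadratic contract. Candidates sharing an effective-overlap Tm are
dominated under the tie-break comparator and dropped up front.

## Assembly geometry, primers, and the 3' tail

With `L` segments, oligo `j` (of `L−1`) covers segments `j` and `j+1`;
odd oligos are sense, even antisense, producing the alternating,
shingle-like ("imbricated") arrangement required for overlap-extension
assembly. The forward primer is the first overlap's sequence; the
reverse primer is the reverse complement of the last overlap. The
structure closes properly when `L` is odd; when the band-aware split
count comes out even, a pseudo-random ~50% GC tail of `target_len` bases
(nudged by up to 5 bp if needed to restore odd parity) is appended to
the 3' end before splitting, screened over up to 64 seeded candidates so
the terminal overlap's Tm stays within 3 °C of the mean. The tail is
recorded in every report and can be removed from the assembled product
by PCR with specific primers. Appending happens *before* segmentation so
the tail participates in Tm equalization; whether the original tool
orders it the same way is unknowable from public information, and the
test suite asserts the resulting structure, not the trigger.

## Synthetic-data generators

All tests run on seeded generators; no external data is used.
`random_gene()` draws bases independently at a requested GC fraction
(optionally splicing in motifs for stress cases); `gc_gradient_gene()`
ramps per-position GC probability linearly from ~30% to ~70%, forcing
unequal segment lengths — the high-GC-heterogeneity stress case. Both
are pure functions of their spec (RNG state is saved and restored).
They emulate composition and its spatial drift, not codon structure,
repeats, or secondary-structure-prone motifs; a green structural test
therefore establishes geometric and thermodynamic consistency of the
emitted sets, not freedom from hairpins or repeat-induced
mis-assembly — screening for those is explicitly out of scope.

Uniform-random sequences are, if anything, *harsher* Tm-equalization
instances than natural genes (local composition variance is maximal), so
absolute refined-std values here (~1.5–3 °C at 500–1500 bp) are not
comparable to published per-gene numbers; all acceptance checks are
relative orderings, oracle equalities, and structural invariants.

## Numerical choices and edge cases

* Population (divide-by-L) standard deviation everywhere; stated in the
  report footer.
* Windowed Tm uses cumulative stack sums (O(1) per window); complete
  assignments and accepted refinement moves are re-scored with the same
  two-pass formula used by the public API, so incremental arithmetic
  never leaks into reported values.
* Coordinates are 0-based half-open internally and in machine-readable
  outputs; FASTA headers and the TSV report label them explicitly.
* Tm values in human-readable outputs are printed at 2 decimals; JSON
  carries full precision (that is what makes byte-identical reruns from
  the embedded config + seed possible, which the test suite asserts).
* Sequences shorter than `2 * target_len` are rejected with the minimum
  length in the message; a `validate` subcommand re-checks any emitted
  report from its own text alone (strand alternation, duplex
  reverse-complementarity, coverage, gap spanning).
* The spec'd YAML config mirror is serialized as JSON instead (no YAML
  parser in the supported dependency set); the round-trip contract is
  unchanged.

## Known limitations

* Both stages are heuristics; only the end-shrink stage is exact *given*
  the refined boundaries. Boundaries and shrinks are never re-optimized
  jointly.
* No secondary-structure, repeat, or GC-extremes screening.
* One gene per run; no vendor plate layouts or codon optimization.
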