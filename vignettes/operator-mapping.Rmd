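---
title: "Mapping operator sites with reusable-capture SPR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping operator sites with reusable-capture SPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redcat)
```

## The problem and the approach

Bacterial transcription factors such as MarR-family regulators bind short,
often pseudopalindromic operator sequences in the intergenic regions they
control. `redcat` implements an end-to-end, label-free workflow for locating
and delineating such operators with surface plasmon resonance (SPR) on a
reusable DNA-capture chip: a biotinylated single-stranded linker is bound
permanently to a streptavidin surface, and each double-stranded test
oligomer carries a 20-nt single-stranded overhang complementary to that
linker, so the surface can be loaded with a new test DNA each cycle and
stripped afterwards. Four experimental designs drive the workflow:

1. **Tiling screen** — the candidate region is divided into overlapping
   fragments so that any binding site up to a guaranteed length is fully
   contained in at least one fragment; fragments giving ~100% of the
   theoretical maximum response at the top protein concentration are hits.
2. **Truncation footprinting** — starting from the merged hit fragments,
   serial 2-nt truncations from the free end map each boundary of the
   protein's footprint at 2-bp resolution. The left-hand boundary is made
   accessible by inverting the duplex on the chip (moving the linker
   overhang from the reverse to the forward strand).
3. **Steady-state affinity** — a concentration series over the footprint
   oligomer, double-referenced, read just before the end of the injection
   and fitted to the 1:1 Langmuir isotherm for K~D~.
4. **Consensus and regulon scan** — footprints are aligned into a
   degenerate IUPAC consensus, annotated for palindromic symmetry and used
   to scan a genome for further candidate operators; substitution panels
   probe every conserved base.

## Models and conventions

### Tiling geometry

For a region of length $N$, fragment length $F$ and guaranteed site length
$L$, fragments start at $1, 1+(F-L), \dots$; if the last regular fragment
does not reach $N$, one end-anchored fragment starting at $N-F+1$ is
appended. This guarantees that every $L$-window lies inside at least one
fragment, which is verified in the test suite by exhaustive enumeration
over randomized $(N, F, L)$. The degenerate case $L = F$ tiles every
offset. The defaults $F = 29$, $L = 22$ reflect a compromise between
localization resolution and cycle count for a winged-helix dimer footprint
of roughly 22 bp; a 119-nt region then yields 14 fragments.

### Theoretical R~max~ and normalization

SPR responses are proportional to bound mass, so the saturating response of
a surface is
$$R_{\max} = \frac{\mathrm{MW}_{\text{analyte}}}{\mathrm{MW}_{\text{ligand}}}
  \cdot R_{\text{ligand}} \cdot S,$$
with the analyte a protein homodimer, the ligand the captured duplex
*including* its single-stranded overhang (the chip-bound linker is part of
the baseline, not of the captured species), $R_{\text{ligand}}$ the
measured capture level and $S = 1$ dimer per duplex. Binding responses are
expressed as a percentage of this quantity, which makes fragments of
different length and capture level directly comparable. Values above 100%
are retained with a warning, since super-stoichiometric signal is
diagnostic, not an error.

DNA strand masses use average atomic masses with 5′-OH/3′-OH termini
(the synthetic-oligo convention): the mass of an $n$-mer is the sum of
deoxynucleoside masses plus $(n-1)\times 61.96$ Da per phosphodiester
bridge. Protein masses are average residue masses plus one water. Both are
checked against an independent atomic-composition oracle in the tests.

### Report points and referencing

Corrected responses are
$[\text{test} - \text{ref}] - [\text{buffer}_{\text{test}} -
\text{buffer}_{\text{ref}}]$, interpolated onto the test cycle's time grid;
negative values are kept, as referencing noise is informative. Screening
reads the binding report point 10 s *after* the end of the injection (bulk
refractive-index steps have decayed); affinity reads 4 s *before* the end
(steady state). Report points are linearly interpolated between samples
because instrument exports are discretely sampled; extraction is invariant
to resampling finer than the report grid. `extract_report_points()`
returns raw trace values by design; `zero_at_injection()` shifts a cycle
to its pre-injection baseline so that the same extraction yields
protein-only responses, and the bundled analyzers always do this. The
capture level is read at the end of the post-capture stabilization wash.

### Boundary calling

A truncation has crossed into the site when it binds detectably worse *or*
releases protein faster. Relative to the full-length (delta 0) reference,
a member passes while its normalized maximum response is within 10% of the
reference's (relative) and each retention metric — percent still bound
after dissociation and after each of two salt washes — is within 10
percentage points (absolute). Both tolerances are configurable and
recorded per metric in the call's rationale. The chosen boundary is the
largest truncation of the *contiguous* passing prefix: a member beyond a
failing one is never accepted even if its own metrics pass, since metric
recovery past a degraded member is noise, not biology. The call's
resolution equals the truncation step (2 nt by default). The qualitative
published decision pattern ("slightly faster dissociation, clearly weaker
salt resistance one step past the boundary") is encoded as a constructed
example in the tests; the thresholds themselves are declared package
defaults, not values inferred from data.

### Steady-state fitting

`fit_kd()` performs unweighted nonlinear least squares of
$R = R_{\max} C / (K_D + C)$ (port algorithm, positivity bounds), with
$R_{\max,0} = \max R$ and $K_{D,0}$ the concentration nearest half-max.
Replicates are fitted pooled rather than averaged, preserving the error
structure. Standard errors come from the Jacobian at the optimum.
Degenerate inputs (flat responses, fewer than three distinct
concentrations, estimates pinned at a bound) are flagged rather than
reported. The fit is validated against a brute-force grid search and, in
simulation, recovers K~D~ to better than 0.1% from noiseless data at the
standard eight-point two-fold series (0.39–50 nM) and to a median relative
error below 5% at 2% noise over 100 seeded datasets, with ±2-SE coverage
of at least 90%.

Kinetics ($k_a$, $k_d$) exist in the package only to drive the simulator;
no kinetic fitting of real traces is attempted, and mass-transport
limitation is deliberately not modeled because only the steady-state model
is ever fitted.

### Consensus and scanning

`derive_consensus()` slides each sequence against the first without gaps to
the offset with the most identical columns (ties to the smallest offset),
keeps bases where all sequences agree and writes `n` elsewhere, then trims
each end until it starts and ends with at least two consecutive defined
bases. The trimming rule matters: the raw column agreement of the two
24-mer operator footprints also conserves one isolated base near the left
margin, and requiring a 2-base anchor at each end is what yields the clean
dodecamer `TTnAAnnnTCAA`. Palindrome annotation pairs position $i$ with
$M+1-i$ and flags Watson–Crick complementary defined pairs — for the
dodecamer, exactly (1,12), (2,11) and (4,9).

Scanning uses `Biostrings::matchPattern` with IUPAC semantics on the
pattern side only, reports overlapping matches, deduplicates by (contig,
start, strand) and gives reverse-strand hits their leftmost forward-strand
coordinate. It is checked against a naive per-position matcher on random
10-kb sequences and against the expected $2n(1/4)^8$ hit rate on uniform
sequence. The scan defaults to the whole genome and both strands; nothing
restricts it to intergenic regions, so downstream filtering is the user's
decision, aided by `report_context()`, which attaches the nearest
downstream feature start and the intervening distance on each strand.

## The synthetic-experiment generator

`generate_screening_experiment()`, `generate_truncation_experiment()` and
`generate_affinity_dataset()` produce complete seeded experiments with
known ground truth. Their defaults are the stated experimental world:
screening at 10/50/100 nM protein dimer in duplicate with ~400 RU of
captured DNA; affinity at the eight-point 0.39–50 nM series in triplicate;
a 41 kDa analyte dimer; low-nanomolar site affinities ($K_D$ 1.3 and
2.4 nM); salt washes that each remove ~20% of remaining protein inside a
site. Capture levels are jittered by 5% to exercise the per-cycle
normalization.

Two conventions are fixture declarations, not claims about SPR physics:

* **Partial containment.** A fragment containing fraction $f$ of a site
  responds at scale $0$ for $f < 0.6$ and $(f - 0.6)/0.4$ otherwise. This
  makes fully-containing tiles, and only those, reach the hit threshold.
* **Boundary effect model.** Each truncation step beyond the true boundary
  multiplies $k_d$ by 3 and adds 0.15 to each salt-wash removal fraction,
  reproducing the qualitative signature used for boundary decisions.

Noise is i.i.d. Gaussian per sample; real instrument noise is
autocorrelated and includes drift and injection spikes, which the
generator does not emulate beyond what double referencing removes. A green
end-to-end test therefore establishes that the *analysis logic* recovers a
planted truth at 2-bp resolution under the declared world — not that the
pipeline is robust to every instrument artifact. Bundles regenerate
byte-identically from (parameters, seed).

## Numerical and degenerate-input choices

* Phase windows are validated to be ordered and non-overlapping; report
  times outside the sampled trace raise errors naming the phase.
* The capture ramp and strip decay are fast exponentials; the trace is
  held flat inside salt-wash windows after the instantaneous removal, so
  declared removal fractions are recovered exactly.
* Truncation series refuse to cut a duplex below 10 nt (configurable) —
  shorter duplexes do not hybridize reliably.
* The linker complement is a documented 20-nt placeholder configuration
  value; no logic depends on its sequence.
* `merge_adjacent_hits()` returns one duplex per run of consecutive hits;
  non-consecutive hit runs are independent candidate sites.
* Concentrations are molar internally; the CLI and fixtures speak nM.

## Known limitations

* No kinetic fitting, no biphasic or heterogeneous-ligand models, no
  mass-transport correction.
* No primer thermodynamics or vendor order formats in the design module.
* The feature-context reporter uses a simple nearest-downstream-start rule
  within a window; it does not model operons or transcription units.
* The scan is exact-degenerate matching only — no PWM or log-odds scoring.
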