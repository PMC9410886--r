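---
title: "Quantifying B-to-A DNA deformation and integration-site A-philicity"
author: "dnaform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying B-to-A DNA deformation and integration-site A-philicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaform)
```

## The problem

Retroviral intasomes capture host target DNA (tDNA), bend it sharply, and
join the two processed viral DNA (vDNA) 3′ ends to tDNA phosphates that
are staggered by 4–6 bp depending on the virus; the stagger equals the
target-site duplication (TSD) created upon repair. Around the joining
sites the tDNA departs from the canonical B-form toward the A-form, which
exposes the scissile sugar–phosphate backbone. `dnaform` measures this
deformation structurally (from atomic coordinates) and predicts its
sequence preference (from aligned integration sites). This vignette
records the models, conventions, parameter choices and limitations.

## Structural route

### Base reference frames

Each base's observed ring atoms (nine for purines, six for pyrimidines)
are superposed by least squares onto the embedded idealized base geometry
expressed in the standard nucleic-acid reference frame (the Tsukuba
convention: x toward the major groove, y along the C1′–C1′ axis toward
the strand carrying the base, z in the 5′→3′ helix sense). The fitted
rigid transform *is* the base frame; the fit RMSD is reported so
deformed or mismodeled bases can be flagged. Exocyclic atoms are
deliberately excluded from the fit — they carry substituent and
tautomer variability that degrades the frame on modified bases. A pair
frame is the geodesic mid-rotation of the two base frames after
z/y-flipping the complementary base.

### Step parameters

For the step between pairs i and i+1 both pair frames are rotated by
half the hinge angle onto a common z-axis; twist is the signed angle
between the resulting x-axes, roll and tilt are the components of the
hinge rotation along the mid-frame y and x axes, and shift/slide/rise
are the frame-to-frame displacement expressed in the mid-step frame.
The inverse construction is implemented exactly, and a property test
drives random parameter vectors through build→extract at 1e-6
tolerance. Angles are reported in degrees in (−180, 180], distances in
Å; near-parallel z-axes (hinge norm < 1e-9) short-circuit to a pure
twist/displacement step to avoid numerically undefined hinges.

### Z_p and its sign convention

Z_p for a dinucleotide step is the mean z-elevation of the two bridging
phosphorus atoms in the mid-step frame, *each measured in the reading
sense of its own strand* (the strand-II dimer frame is the z-flipped
mid-step frame, so its projection enters with opposite sign). The
strand-sense convention matters: projecting both phosphates in one
common frame is antisymmetric under the step dyad and therefore
identically zero on any ideal duplex, which would make the classical
fiber reference values (≈ +2.2 Å for A-DNA, ≈ −0.3 Å for B-DNA)
unreachable. With the strand-sense convention the package's ideal
fibers reproduce those values, and the A/B bands (≥ 1.5 Å, ≤ 0.5 Å)
apply as published.

### Form calls

A step is called "A" when Z_p ≥ 1.5 Å *and* the mean glycosidic torsion
of its 3′-side nucleotides is ≤ −120°; "B" when Z_p ≤ 0.5 Å and the mean
chi is ≥ −120°; otherwise "intermediate". Slide and twist are carried as
features but do not gate the call: clear-cut A-DNA is rare in complexes
and the Z_p/chi plane is the most reliable two-dimensional discriminant,
so a conservative two-feature rule minimizes false A calls on bent but
B-like steps. Thresholds are exposed via `form_thresholds()`.

### Groove widths and contacts

Groove widths are raw cross-strand P–P distances at fixed index offsets
(strand-II partner at i+3 for the major groove, i−4 for the minor
groove). The offsets were chosen once as the separations that realize
the canonical direct-distance widths on an ideal B duplex (≈ 17.2 and
11.7 Å); no phosphate-radius subtraction is applied, so a B-form major
groove reads ≈ 16–17 Å. A fixed-offset convention is deliberately
simple — it is exactly reproducible and matches raw phosphate-distance
reporting — but it underestimates the depth asymmetry of strongly
A-form regions, where the true closest approach shifts by one or two
steps. Protein–DNA contacts enumerate all heavy-atom pairs within
3.9 Å (covering Van der Waals and donor–acceptor hydrogen bonds), with
the DNA atom partitioned into base/sugar/phosphate by atom name and a
groove-side annotation from the sign of the protein atom's x-coordinate
in the nearest pair frame (|x| < 1 Å or > 12 Å from the pair: "none").

### Fiber references

Ideal duplexes are generated by global helical symmetry: every pair
carries the standard base-pair geometry placed at x-displacement dx from
the axis, inclined by η about the pair x-axis, rotated by the helical
twist Ω and translated by the helical rise h per residue. Parameters are
the fiber-diffraction values — B: Ω 36.0°, h 3.38 Å, dx 0, η 0; A:
Ω 32.7°, h 2.56 Å, dx −4.5 Å, η 19.1° — under which the *local* step
parameters emerge (not imposed): A-form local twist ≈ 31° < 32.7°
because of the inclination, slide ≈ −1.6 Å, roll ≈ +10.6°, rise ≈
3.2 Å. O4′ is built at the canonical glycosidic torsion (B −102°, A
−157°), and the phosphorus position in the base frame (one constant per
form) was calibrated once against canonical phosphate observables —
intra-strand P–P spacing 7.0/5.9 Å (B/A), Z_p −0.3/+2.2 Å, and the
direct cross-strand groove widths — then frozen
(`scratch/calibrate_fiber.R` documents the derivation). Because the
builder never touches the mid-step-frame algebra, fiber → analysis is a
genuine oracle for the extraction code. The generator emits the minimal
atom set (ring, C1′, O4′, P); sugar ring puckering and the remaining
backbone torsions are not modeled.

## Sequence route

### Trinucleotide ΔG(B→A) scale

A-philicity is scored per trinucleotide with the free-energy cost of
the B→A transition (kcal/mol; low = A-philic). The embedded table is a
**synthetic stand-in** (`R/dg-table-synthetic.R`): the experimentally
derived published scale could not be bundled, so the package ships 32
unique values constructed to preserve the properties profiling actually
uses — exact reverse-complement symmetry, G/C-rich trimers most
A-philic (GGC/GCC lowest), A/T tracts most B-philic (AAA/TTT highest),
a ~0.04–1.32 kcal/mol spread, and a genome-composition (41% G+C)
average of ≈ 0.71, the flat background level expected of random
genomic sequence. Conclusions that depend on exact per-trimer values
rather than on ordering/symmetry/scale should substitute a measured
table via the `table` arguments; every profile-level test in this
package depends only on the structural properties.

### Alignment conventions and the joining spacing

Windows are anchored so relative position 0 is the first joined tDNA
base (the base whose 5′-phosphate receives the vDNA 3′-OH) on the
sequenced strand. Only one provirus–host junction is sequenced in
practice; the partner joining event is inferred from the TSD. The
package models the partner signal **tsd bp downstream of position 0**:
the two scissile phosphodiesters are separated by exactly tsd bp (that
separation *is* the TSD length), so the two A-philic minima of a
profiled site set fall at positions 0 and tsd and their spacing equals
the TSD — 6 bp for an MMTV-like enzyme, 5 for a 5-bp TSD, 4 for a 4-bp
TSD. An alternative convention anchors the partner junction *base*
(position tsd−1, one less); it describes the duplicated bases rather
than the joining chemistry and yields spacings of tsd−1, which does not
match the joining-spacing phenomenology this package is built around.
`revcomp_sites()` exposes both remappings (`partner = "phosphate"` for
profiling, `partner = "base"` for base-level matrices, whose mirror
symmetry is exact about the duplication midpoint).

Each trinucleotide's value is tallied at its central base by default
(keeping profiles symmetric under reverse complementation);
`assign = "start"` is available for compatibility with start-anchored
tallies. Trinucleotide windows containing N are skipped individually —
the rest of the site still contributes, which maximizes usable data and
matches a running-average implementation. Peak detection takes strict
local minima inside [−radius, tsd+radius] (default radius 10 bp) and
returns the two deepest; flat or monotone profiles raise an error
rather than fabricating a spacing. Ties between equal-depth minima are
resolved by position order; with planted signals at both junctions the
two deepest minima are well separated from the background in all tested
regimes.

### Site statistics

Frequency matrices cover a window (default 50 bp, the conventional logo
stretch) centered on the duplication midpoint (tsd−1)/2; per-column
probabilities exclude N, and information content is reported as
2 + Σ p log2 p bits without small-sample correction (rendering is left
to any plotting layer). The consensus reports the plurality base where
its probability exceeds a threshold, else N, with "/" marking the
junction; the default threshold 0.30 is intentionally low because
integration-site preferences are marginal — a stringent threshold
returns all-N strings. YR/RY usage is reported per step with an
explicit "other" class summing to 100%; note that reverse
complementation maps YR steps to YR steps (5′-CA pairs 5′-TG), so the
YR percentage is *mirrored*, not swapped, under revcomp — the YR↔RY
swap arises under coordinate reversal, and the tests assert both forms.
The 3′-processing rule requires the invariant CpA immediately before
the terminal dinucleotide and returns the recessed CA-3′ product; the
branched-substrate validator checks strand complementarities, the CA
register, and that the palindromic segment between the joining points
has length tsd.

## Synthetic data

`simulate_site_set()` draws i.i.d. background bases (default 29.5/20.5%
per A:T/G:C base, mammalian-like), then layers three signals: a 10-bp
cosine A/T bias outside the TSD (a proxy for nucleosomal periodicity), a
YR replacement at the central TSD step, and — with probability
`aphilic_strength` per junction — a low-ΔG trinucleotide centered at
each joining position, drawn from the bottom quartile of the table with
softmax(−ΔG/τ) weights, τ = 0.2 kcal/mol (a smooth bias rather than a
hard motif). The default study condition used in the acceptance
checks is n = 10,000 sites, 41-bp windows, TSD 6, strength 0.8.
What the generator does *not* emulate: linkage between positions
(real sites have correlated flanks), sequencing/mapping artifacts,
restriction-fragment ascertainment, chromatin structure beyond the A/T
cosine, and virus-specific base preferences at individual positions.
Passing tests therefore demonstrate that the analysis recovers planted
signals of realistic shape and size — not that any particular real
dataset will show them.

`simulate_genome()` plants strand-aware windows into a random contig
and emits the matching BED, enabling end-to-end plant-and-recover tests
of the BED+FASTA loader (0-based junction coordinates, minus-strand
windows reverse complemented, duplicates removed).

## Numerical choices and degenerate inputs

* Round-trip tolerance for the step algebra: 1e-6 (tested); frame
  orthonormality enforced to 1e-6.
* Hinge norms < 1e-9 are treated as parallel axes (pure twist step);
  rotation logs near 0°/180° use guarded branches.
* Altlocs resolve to highest occupancy, ties to file order; hydrogens
  and waters are dropped before any computation.
* Duplexes shorter than the groove offsets yield an empty groove
  profile, not an error; missing bridging phosphates yield NA Z_p with
  a warning (or an error from the scalar `zp()`).
* All simulation randomness flows through one integer seed with the
  caller's RNG state restored afterwards.

## Problem sizes

The test suite and the acceptance script run on 20-bp fiber duplexes,
toy contact systems of ≤ 500 atoms, and simulated site sets of
4,000–10,000 windows of 41 bp — sizes chosen so each statistical check
has comfortable Monte-Carlo margins (assertions use 2.5–4 standard
errors) while the whole suite completes in well under a minute.

## Known limitations

* The geometry engine targets Watson–Crick duplex DNA; non-canonical
  pairs are accepted only through an explicit pairing map, and sugar
  pucker / backbone torsions beyond chi are out of scope.
* Groove widths use fixed index offsets calibrated on B-form geometry;
  they are comparative, not groove-tracing, measurements.
* The ΔG table is synthetic (above); absolute profile levels are
  calibrated, per-trimer values are not experimental.
* Structure parsing keeps the first model of multi-model files and
  standard residue names only (DA/DC/DG/DT/DU plus ribo variants).
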