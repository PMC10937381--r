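---
title: "Methods: simulated chromatin, insulation analysis and bead-model reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated chromatin, insulation analysis and bead-model reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

nucfold analyses nucleosome-resolution chromosome-conformation (Micro-C
style) data: chimeric ligation pairs are classified by read orientation,
shifted to nucleosome dyads, filtered, binned into contact matrices, and
interrogated for chromatin domains via diamond insulation scores. In
parallel, MNase-seq style fragments yield dyad-coverage profiles from which
linker lengths and nucleosome-free-region (NFR) widths are measured. A
coarse-grained bead model reconstructs 3D structure from nucleosome-binned
contacts by simulated annealing.

Every stage is validated against a synthetic chromatin generator that plants
the structure the analysis is supposed to find: phased, regularly spaced
nucleosome arrays around NFRs of preset width at transcription-factor (TF)
binding sites. Because the ground truth is known, recovery of linker length,
NFR width, boundary positions and domain structure can be asserted
quantitatively.

# The synthetic chromatin model

## Nucleosome positions

Each TF site carries an NFR of width $w$ centered on the site. The first
dyads sit at $\pm(w/2 + 73)$ bp from the site — 73 bp being half the 147 bp
nucleosomal footprint, so the first nucleosome's edge touches the NFR
border. Subsequent dyads follow at steps of the nucleosome repeat length
$\mathrm{NRL} = 147 + \ell$ (linker $\ell$), with Gaussian noise of sd
`spacing_sd_bp` applied *per step*. Step noise (rather than independent
positional jitter) makes consecutive gaps $\mathrm{NRL} \pm$ jitter and lets
phasing decay with distance from the alignment site, as it does in real
arrays. Arrays from neighbouring sites stop at the midpoint between them.
With `phased = FALSE`, each inter-NFR segment receives a uniformly random
lattice phase instead.

Built-in remodeler presets encode the measured rulers: INO80 (41 bp linker,
126 bp NFR), ISW2 (29, 68) and Chd1 (22, 92); RSC keeps an NFR open without
regular spacing, and "none" mimics sequence-driven (salt-gradient-dialysis)
chromatin with neither phasing nor NFRs.

## Contacts

A nucleosome pair $(i, j)$ is sampled with probability

$$P(i, j) \propto s_{ij}^{-\alpha} \prod_{\text{NFRs between}} \beta(w),
\qquad \beta(w) = e^{-w / w_0},$$

where $s_{ij}$ is the dyad separation (shortest arc on circular contigs),
$\alpha = 1$ by default, and $w_0 = 150$ bp. The attenuation $\beta(w)$ is a
modeling choice — no quantitative relation between NFR width and contact
attenuation is established experimentally — so tests assert only its
monotone consequence: wider planted NFRs give deeper insulation minima. The
bounded power law deliberately replaces a polymer simulation; it reproduces
the diagonal banding, phasing grid and insulation patterns the analysis
consumes while remaining analytically checkable.

Each sampled pair is emitted as two ligation junctions at dyad $\mp 80$ bp
with read directions drawn from the orientation mix (uniform by default;
orientation is independent of distance because no empirical model exists for
it), so the downstream 80 bp dyad shift inverts the offset exactly. A
configurable fraction of sub-147 bp "undigested" pairs (default 5%)
exercises the minimum-distance filter. Restriction cuts are modelled as
incomplete digestion: a fraction `f_cut` of molecules is severed at the cut
sites, restricting those molecules' pairs to the resulting linear segments
with linear path distances.

## MNase fragments

Fragment midpoints are planted dyads plus $N(0, 5)$ bp of trimming noise;
lengths are $N(160, 25)$ truncated to [100, 260] bp so the 125–205 bp
analysis filter removes material on both sides. These defaults are fixed
study conditions, not tuning knobs.

## What the generator does not emulate

No DNA sequence (and hence no MNase sequence bias), no histone-octamer
thermodynamics, no polymer physics beyond the distance power law, no
replicate-to-replicate batch effects. Passing tests therefore demonstrate
that the *analysis machinery* is correct and sensitive at realistic depths —
not that real chromatin obeys the generator's model.

# Analysis conventions

**Pair processing.** Directions are recorded as downstream/upstream of the
ligation junction (encoded +/− in pairs-text files). After ordering the two
sides by coordinate, the direction combination maps to inward / outward /
tandem entry / tandem exit; which tandem combination is "entry" versus
"exit" is a documented package convention, as the underlying datasets do not
fix it. The junction is shifted 80 bp toward the interior of the nucleosome
each read enters; same-contig pairs closer than 147 bp (strictly) and
interchromosomal pairs are then removed. The pipeline is idempotent on its
own output, and counts are conserved at every stage with explicit discard
tallies.

**Matrices.** Raw counts only; no balancing. $\log_{10}(1 + x)$ is applied
for display and replicate correlation (computed within 5 kbp separation by
default, the plasmid-interaction scale). Nucleosome binning assigns each
pair end to the nearest dyad (ties to the leftmost; ends farther than 100 bp
discarded and counted). Distance-decay curves use 20 log-spaced bins per
decade; power-law fits should use distances above roughly ten repeat
lengths, where the discrete dyad lattice no longer aliases the bins, and can
divide counts by the per-distance pair availability $n - s/\mathrm{NRL}$ of
a finite array — with that correction the generator's $\alpha = 1$ is
recovered to about 2% at $10^6$ pairs.

**Insulation.** For bin $i$ and window $w$ bins, the diamond statistic is
the mean count over cells $(a, b)$ with $i - w \le a < i < b \le i + w$; the
score is $\log_2$ of that mean over its contig-wide average. Diamonds that
do not fully fit on a linear contig are NaN; on circular contigs they wrap.
Boundaries are local minima ranked by topographic prominence (saddles from
the nearest strictly deeper values; profile ends cap at the side maximum;
plateau ties report the leftmost bin); "strong" boundaries exceed the Li
minimum-cross-entropy threshold of the prominences, applied on a linear
scale by default (`li_log` switches to log1p scale).

One behaviour deserves emphasis: because the diamond counts only cells
*strictly crossing* bin $i$, a bin containing a dyad excludes that
nucleosome's own nearest-neighbour contacts and is locally depressed. On
synthetic chromatin, whose lattice is phase-coherent within each domain, the
deepest minima therefore sit on the first-nucleosome bins flanking an NFR —
typically one to two 80 bp bins from the planted center — rather than on the
center bin itself. Boundary-recovery assertions use a 160 bp (two-bin)
matching slack accordingly. In real data, genome-wide phase decoherence
averages this lattice effect away.

**Nucleosome metrics.** Dyad coverage keeps 125–205 bp fragments, places a
50 bp footprint on each midpoint and smooths with a centered 20 bp rolling
mean (edges truncated; interior mass-preserving). Composites normalize each
window by its own mean before averaging. Peak calling excludes ±50 bp
around the anchor (masking the TF footprint), reports flat-topped peaks at
their plateau center (the footprint-plus-smoothing trapezoid would otherwise
bias positions by 15 bp), and enforces a 120 bp minimum separation
greedily by height. Linkers are consecutive peak gaps minus 147 bp (first
three per side); the border-to-TF distance is the first peak offset minus
73 bp; the NFR width is the *sum* of the two border distances, so the TF
footprint lies inside the NFR. Per-side borders are averaged across
replicates before summing.

# The bead model

A nucleosome is four histone beads (3 nm radius) on the superhelical axis
plus 23 wrapped DNA beads (5.88 bp each) on a left-handed superhelix of 1.65
turns, radius 4.18 nm, pitch 2.39 nm; linker DNA contributes
`round(linker_bp / 5.88)` beads with a 2.0 nm bond rest length (5.88 bp
times the standard B-DNA rise of 0.34 nm/bp — an external constant).
Restraints come from nucleosome-binned counts with weight $\ln(1 + c_{ij})$
and a flat-bottom harmonic active beyond 11 nm; inward-tagged restraints act
between entry/exit-proximal DNA beads, others between histone-center beads
(a simplified stand-in for orientation-aware treatments; switchable off).

Reconstruction is Metropolis simulated annealing with single-bead Gaussian
moves and geometric cooling — deterministic per seed — over an energy of
harmonic bonds, harmonic bending on linker beads (stiffness from the 50 nm
DNA persistence length), soft-core repulsion, and the restraints. The
default schedule (T from 5 to 0.05 reduced units over 1200 sweeps, 0.3 nm
moves, restraint constant 3) was chosen so the optimizer demonstrably
converges on a two-domain test system: shorter, colder schedules froze far
from the restraint minimum. Metropolis acceptance skips the exponential for
uphill moves beyond 50 kT (probability < 2e-22), which also avoids
slow extreme-argument libm paths. The models are descriptive — no
thermodynamic-sampling claims are made — and are validated by property
tests: exact wrap geometry at initialization, energy descent, bit-level seed
reproducibility, separation of restrained domains, and rank agreement
between input weights and model contacts.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
the sizes the recovery statements refer to: $10^6$ fragments per preset for
parameter recovery (typically recovering the planted 41/22/29 bp linkers
within 2 bp and 126/92/68 bp NFR widths within 4 bp), $10^6$ pairs per seed
across five seeds for boundary recovery on a 20 kbp contig with five planted
NFRs, and a 50-nucleosome toy for annealing. Flatness of unphased
composites is assessed at genome scale (4 Mbp, ~1900 anchors), mirroring
composite analyses pooled over many sites; with few anchors, sampling
extremes of the realized coverage dominate. Li iteration converges at
1e-6; insulation oracles agree with brute force to 1e-12; structure files
round-trip at 3 decimals (nm).

Degenerate inputs are errors, not silent results: empty dyad lists,
overlapping expanded NFRs (named sites), windows exceeding contigs,
all-equal Li inputs, zero-variance correlations, unoriented anchors where
orientation matters, and bp-binned matrices where nucleosome binning is
required.

# Known limitations

The contact model has no polymer excluded volume, so attenuation strengths
are only ordinally meaningful. Orientation classes carry no distance
dependence by default. The boundary-localization bias on coherent lattices
(above) caps localization accuracy at about two bins. The annealer is a
single-bead Metropolis scheme: it reconstructs domain-scale organization but
not fine-grained fiber geometry, and its restraint functional form is a
package convention, not an experimentally derived force field.
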