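---
title: "Methods: analysing LND-endosomal membrane fusion trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing LND-endosomal membrane fusion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lndfusion)
```

This vignette is the package's account of its methods: the models and rules
each analysis stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where more than one
reasonable convention exists.

## The system and its representation

The object of study is a lipid nanodroplet (LND) — a ~100-lipid droplet of
ionizable lipid (IL), cholesterol and DSPC at molar ratio 50:40:10,
mimicking an RNA-free lipid nanoparticle — fusing with a planar endosomal
membrane bilayer in a periodic box. Conventional fixed-protonation CG MD
assigns each IL molecule's protonation state for the whole run, encoded
here in the residue name (e.g. `ALCP` vs `ALCD`): the pH environment enters
only through the fraction of protonated molecules. Coordinates are in nm
throughout (the native unit of the GRO format); boxes are orthorhombic, and
triclinic cells are rejected at read time — every system of interest is
rectangular, and supporting triclinic minimum-image conventions would add
complexity without a use case.

A trajectory is a fixed atoms table (molecule id, residue name, bead name,
origin) plus a coordinate array over frames. The *origin* of a bead
(LND / MEMBRANE / SOLVENT) is assigned once from the topology and never
re-derived from geometry: cholesterol occurs on both sides, so the topology
carries an explicit list of LND molecule ids (written by the generator,
supplied by the user for real systems). Molecule identity is the (residue
number, residue name) pair of the coordinate file, re-indexed monotonically
across the GRO format's five-digit wrap so ids stay unique in large
systems.

## Protonation design

The Henderson–Hasselbalch relation treats the protonated IL as the acid HA:

$$f = \frac{1}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a}}, \qquad
  \mathrm{pH} = \mathrm{p}K_a + \log_{10}\frac{1-f}{f}.$$

With apparent pKa 6.09 (ALC-0315) and 6.44 (MC3), the early-endosome pH
window 6.8–5.9 and the late-endosome window 5.5–5.0 map to protonated
fraction ranges of 16.3–60.8% and 79.6–92.5% for ALC-0315 and 30.4–77.6%
and 89.7–96.5% for MC3 (percents rounded half-away-from-zero to one
decimal). Two published conventions are worth noting explicitly: the
ALC-0315 early-endosome upper endpoint is sometimes quoted as 60.6% and the
late-endosome lower endpoint as 79.5%, and the MC3 pH values for the 60%
and 70% cases sometimes appear as 6.19 and 6.02 where the inverse formula
gives 6.26 and 6.07. This package always reports the formula values and
does not force agreement with rounded or transcribed figures.

`build_design_matrix()` pairs each grid case (0–100% in 10% steps) with a
compartment: cases at or below the EEM fraction range go to EEM, cases at
or above the LEM range to LEM, and a case in the gap between the ranges
goes to the nearer endpoint — or to *both* compartments when its distances
to the two endpoints differ by at most 1.5 percentage points. That
tolerance is the one genuinely open constant in the construction: it is the
smallest round value that reproduces the asymmetric treatment of the two
ambiguous cases (ALC-0315 at 70%, distances ≈ 9.2 vs 9.6, goes to both;
MC3 at 80%, distances 2.4 vs 9.7, goes to EEM only) without hard-coding
either case. Every case additionally pairs with the simplified bilayer,
giving 12 + 11 + 22 = 45 complexes and 135 runs at three replicas.

## Fusion onset

The depth series is $\Delta Z(t) = h_L(t) - h_u(t)$ with $h_L$ the minimum
z over **all** LND beads of every residue type and $h_u$ the mean z of
**upper-leaflet POPC PO4 beads only** (DOPE and POPS phosphates are
excluded from the average even though they decorate the same sheet). Onset
is the earliest stored frame where $\Delta Z < 0$ strictly — an exact zero
does not trigger — and every stored frame for the next 1 ns is also
negative.

Numerical choices:

- **Recentring.** Every frame is first shifted so the wrap-aware centre of
  the membrane PO4 beads sits at half the box height, then wrapped into
  `[0, Lz)`. Absolute z comparisons are meaningless under barostat drift or
  periodic wrapping; after recentring, ΔZ is invariant to whole-box z
  shifts (a tested property).
- **Leaflet orientation.** The "upper" leaflet is the one facing the LND
  centroid in frame 1, with membership assigned by the sign of z minus the
  membrane PO4 median and then held fixed per molecule. Re-assigning per
  frame would let fusion disorder flip labels mid-run.
- **Persistence on stored frames.** The 1 ns rule is evaluated on stored
  frames only, with no interpolation, and the window must be fully covered
  by data: a sign change too close to the end of the trajectory is
  reported *censored* rather than detected. The criterion cannot be
  evaluated at a resolution finer than the trajectory's own.
- **Entry ranking.** At the onset frame, LND molecules are ordered by their
  per-molecule minimum z minus $h_u$; ties break by molecule id. The rank
  of the best-placed ionizable lipid is reported (rank 1 in the typical
  IL-first scenario).

## Leaflet migration (flip-flop)

An IL's position in the membrane is read from its head-terminal bead — OH
for ALC-0315, NC3 for MC3 (configurable in the topology). The bead belongs
to a leaflet if its minimum-image distance to any POPC PO4 bead of that
leaflet's sheet is ≤ 1.2 nm; beads within the cutoff of *both* sheets take
the nearer one, an exact tie is MIDPLANE, and beads within neither cutoff
are MIDPLANE. That last rule deliberately sweeps heads that have detached
into solvent into the MIDPLANE class — the rule as stated admits no other
deterministic reading — so a separate diagnostic (`mean_detached`, heads
farther than twice the cutoff from both sheets) is reported to make such
events visible.

Sheet coordinates are rebuilt from the current frame, but sheet *labels*
are inherited from frame-1 membership tracked per POPC molecule: a POPC
that itself flips does not churn the reference. Fractions use the species'
whole-system molecule count as denominator, so inner + outer + midplane
sums to one exactly in every snapshot; species absent at the 0% and 100%
extremes report `NA`. Replica aggregation uses the arithmetic mean and the
*sample* standard deviation (n − 1) — the standard reporting convention at
three replicas — with a single replica passed through flagged, SD 0.

The default analysis window is 1500–2000 ns at 200 ps stride: the regime
where complete fusion is established, late enough that occupancies are
stationary. Both are ordinary config keys.

## Clustering

Two analyses quantify the observation that deprotonated ILs stay clustered
while protonated ILs disperse:

- **Head-group RDFs**: the standard three-dimensional pair correlation of
  the ILs' NC3 beads, normalised per frame by shell volume, reference
  count and the partner species' box density, averaged over frames, with
  self pairs excluded for same-species selections. The RDF bead is NC3 for
  *both* ILs — including ALC-0315, whose leaflet classification uses OH —
  because the head-group nitrogen bead is the shared, comparable site; the
  bead is a topology field, not code. Default bins of 0.02 nm up to 3.0 nm
  resolve the ~0.5 nm clustered peak from the ~0.9 nm dispersed peak. The
  reported peak is the global maximum with ties broken toward smaller r. A
  3-D (not in-plane 2-D) convention is used: midplane-clustered ILs form a
  three-dimensional blob, not a sheet.
- **Single-linkage maximum clusters**: molecules are linked when the
  minimum inter-bead minimum-image distance between them — over **all**
  beads, heads and tails alike, since tail contact is what holds a droplet
  together — is ≤ 1.2 nm. Connected components are computed per snapshot
  over all LND-origin molecules, and the largest component's size and its
  protonated/deprotonated IL counts are tracked over time. When components
  tie for the maximum, the one containing the smallest molecule id is
  reported, making the series deterministic.

## Segmental order parameters

For a segment vector $\vec v$ (two beads of one molecule, consecutive bond
or non-consecutive pair) and the bilayer normal $\hat z$:

$$P_2 = \left\langle \tfrac{1}{2}\left(3\cos^2\theta - 1\right)
\right\rangle,$$

giving 1 for alignment with the normal, 0 for isotropy, −0.5 for in-plane
orientation. The normal is the laboratory z-axis of the recentred frame —
the membranes are planar and xy-periodic, and fitting a per-frame normal
would only add noise. Vectors are pooled over molecules and window
snapshots (per-molecule-then-per-frame weighting is not distinguishable
from pooling when molecule counts are constant across frames, which they
are here); protonated and deprotonated species and POPC sn1/sn2 chains are
reported separately. Segment definitions (bead pairs, chain tags,
consecutive vs non-consecutive) live in the topology, not in code, because
the exact CG bead graphs are a property of the force-field mapping, not of
the analysis. Molecules contribute regardless of their leaflet class.

## The synthetic generator

`generate_fusion_trajectory()` is kinematic, not physical: no forces, no
thermostat, no barostat. Its sole job is to carry *known* statistical
structure through real file formats so that each analysis stage can be
validated by recovering what was planted.

What it emulates, and how:

- **Geometry.** Two PO4 sheets 4 nm apart with truncated-Gaussian jitter
  (SD 0.05 nm, clipped at 2 SD so classification margins survive the worst
  draw), each lipid species on its own near-uniform lattice per leaflet —
  keeping the POPC sheet dense everywhere, which the 1.2 nm rule's
  geometric guarantees rely on. Compositions default to the study recipes
  (EEM 192/94/162 and LEM 292/76/80 POPC/DOPE/CHOL; SLB 360/90 POPC/POPS),
  boxes to 10.7/11.5/12.2 × 25 nm, the droplet to 100 lipids at 50:40:10
  with a ~1 nm initial gap.
- **Onset.** The droplet descends rigidly so ΔZ falls linearly from the
  gap to exactly −0.05 nm at the planted onset frame; an optional shorter
  negative blip exercises the persistence rule. Because the droplet is
  placed against the *actually built* membrane's mean PO4 height, the
  planted ΔZ is exact, not approximate.
- **Migration.** Each IL draws one leaflet class per run from its species'
  probabilities — occupancy, not per-frame hopping, mirroring the
  observation that an IL flips once and stays. The species' molecule count
  is therefore the binomial n of any recovered fraction. A per-frame
  resampling mode exists as a stress test. Default probabilities are the
  50%-protonated early-endosome values (protonated outer 0.29 / midplane
  0.46; deprotonated outer 0.04 / midplane 0.94), chosen as representative
  mid-table entries.
- **Clusters.** A planted number of molecules per species stays in one
  compact connected blob at the membrane midplane; all other molecules are
  placed on an isolation lattice. Isolation is enforced in the xy plane
  only — every bead of a dispersed molecule stays within ~0.13 nm of its
  anchor's xy — so molecules in different cells are farther than the
  linkage cutoff apart *whatever* class heights their heads take. INNER
  and OUTER heads sit 3 nm apart in z and may share a cell; midplane heads
  get exclusive cells. Dispersed cholesterol/DSPC are parked well above
  the membrane, where they stay cluster singletons and never touch the ΔZ
  minimum. Plans that cannot be isolated (too many dispersed lipids for
  the box) fail loudly rather than silently violating the planted truth.
- **Order.** Tail chains follow a two-population model: with probability w
  the whole chain is rigidly aligned with the normal, otherwise rigidly
  along one isotropic random direction. Chain-rigid sampling is a
  deliberate choice: segments of one chain share beads, so independently
  planting a value on every segment (including non-consecutive ones) is
  geometrically over-determined, while a rigid chain gives *every* segment
  the same exact expectation $E[P_2] = w$. LND chains are built compact
  (0.012 nm bonds) so the isolation lattice stays valid; P2 is
  length-invariant, so this costs nothing statistically, though it does
  mean generated LND molecules are not metrically realistic shapes.

The same seed reproduces a run bit for bit; different seeds change the
jitter and draws but not the ledger structure.

What passing the desk-scale tests does **not** show: the generator's
membrane never undulates, drifts or changes area; its fusion is a
discontinuous jump from an intact droplet to a fused layout rather than a
stalk/hemifusion pathway; heads never sit ambiguously near the cutoff for
long stretches; and solvent and ions are absent. Recovery of planted
parameters validates the *estimators* — their rules, conventions,
normalisations and statistical behaviour — not the biological conclusions,
which require the original microsecond simulations.

## Problem sizes and runtime choices

The test suite exercises the estimators at sizes chosen to make their
statistical tolerances meaningful while keeping the suite fast: onset
recovery on twenty 500-frame trajectories spanning onsets at 10–90% of the
span; migration recovery on fifty seeded runs of 50 molecules per species
by 100 snapshots, judged at three binomial standard errors; oracle
equivalence (classification, clustering, minimum-image) on hundreds of
random frames against brute-force enumerations; RDF and P2 limits on
ideal-gas and aligned/planar/isotropic inputs. Full-scale analyses (10 001
frames, 2000 ns) run with the same code paths; only frame counts differ.

## Known limitations

- XTC input is not supported (TRR and a plain-text dialect are); convert
  with `gmx trjconv` first.
- Orthorhombic boxes only.
- The leaflet rule classifies fully detached heads as MIDPLANE by
  construction; use the `mean_detached` diagnostic when that matters.
- Kinetic flip-flop rates (events per unit time) are out of scope: the
  quantities here are occupancy fractions.
- No stalk/hemifusion intermediate detection and no free-energy or
  fusion-rate estimation.
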