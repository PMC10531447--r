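---
title: "Methods: permeation counting, permeability and gating statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permeation counting, permeability and gating statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelflux)
```

channelflux quantifies water transport and gating geometry in molecular
dynamics trajectories of membrane water channels (aquaporins and related
pores). This vignette is the package's account of the methods it implements:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic fixtures do and do not emulate, and the known
limitations.

## The analysis region: an NPA-centred cylinder

Aquaporin monomers conduct water through a pore whose midpoint is marked by
the two NPA-motif asparagines, where the two hemi-helices meet. The analysis
region is a cylinder centred on the centre of geometry of those asparagines'
C&alpha; atoms, aligned with the pore axis (+z by default). The default
radius of 15 Å and full length of 30 Å encompass the whole transmembrane
channel section of one monomer. Because proteins drift, the centre is
recomputed from the NPA atoms in every frame (`define_cylinder()`,
`per_frame = TRUE`); `fixed_cylinder()` exists for synthetic systems whose
channel does not move.

Units throughout: Å for lengths, ps for times, kJ/mol for energies, and
1-based atom indices (the R convention; residue ids are 1-based as in PDB
files).

## Permeation events

A permeation event is one water molecule entering the cylinder through one
flat face and leaving through the opposite face. The automaton in
`track_crossings()` takes the strictest reading of "from one extremity to
the other":

* entry through the curved wall (radially) arms nothing — a crossing must
  begin at a face;
* a water first observed already inside has no entry face and cannot score
  until it exits and re-enters (this keeps the count unbiased in direction);
* leaving through the entry face, or radially, resets the water
  (`strict_faces = TRUE`; the permissive variant, which forgives radial
  excursions while the water stays axially inside, is available and off by
  default);
* a position exactly on a face or the wall counts as inside (closed
  interval), for determinism;
* an apparent axial displacement larger than half the box edge is treated
  as a periodic wrap: the water's state is re-initialised from its new
  position and no face is deemed crossed.

Every one of these rules is exercised against a brute-force per-water
replay in the test suite, and the forward/backward totals balance within
Poisson error on equilibrium fixtures.

## Osmotic permeability from the collective coordinate

The collective coordinate accumulates the axial displacements of waters
that are inside the cylinder in both frames of each consecutive pair,

$$\mathrm{d}n_t = \frac{1}{L}\sum_{i \in \text{inside}} \Delta z_i, \qquad
  n(t) = \sum_{t' \le t} \mathrm{d}n_{t'},$$

with $L$ the cylinder length (30 Å by default, matching the counting
region so counts and pf refer to the same channel section). $n(t)$ performs
a one-dimensional random walk whose mean-square displacement grows as
$2 D_n \tau$, and the osmotic permeability follows as
$p_f = v_w D_n$ with $v_w = 2.99\times10^{-23}\,\mathrm{cm^3}$
(18.07 cm³/mol over Avogadro's number; configurable).

`diffusion_coefficient()` estimates $D_n$ by least squares on the
all-origins MSD. The default fit window is 10–50 % of the maximum lag. Two
situations call for a shorter window, which is why it is a parameter:

* **Bounded systems.** When the water population cannot turn over (all
  waters confined to the channel), $n(t)$ is bounded and its MSD saturates;
  only the short-lag slope measures $D_n$. The parameter-recovery analyses
  therefore fit lags of roughly 1–10 steps, where reflected diffusion also
  carries a known mild $\sqrt{\tau}$ boundary depletion (the recovered
  $D_n$ for 20 confined waters sits a few percent below the analytic
  $N D / L^2$, well inside the 15 % recovery band the tests enforce).
* **Short blocks.** On a 10-ns block the long lags have too few origins to
  average; the per-block pf analyses use lags of 10–200 ps.

A non-positive fitted slope is clamped to $D_n = 0$ with a warning rather
than reported as a negative diffusion coefficient.

## Free-energy profiles

The pore axis is sliced into half-open bins of 0.5 Å (configurable).
Per-frame counts of cylinder-interior waters per slice, averaged over
frames and divided by the slice volume $\pi R^2 w$, give the density
profile; Boltzmann inversion gives the potential of mean force,

$$G(z) = -k_B T \ln\frac{\rho(z)}{\rho_\mathrm{bulk}},$$

with $k_B = 0.0083145$ kJ/(mol K) and $T = 303.15$ K by default. Empty
slices are masked (`NA`), never $\pm\infty$.

The bulk density estimator is a design choice the method leaves open: here
it defaults to the mean density over slices beyond the channel section
(|z| > half-length) but still inside the extended profile range (1.5× the
half-length on each side), and it can be overridden with a constant.
Profiles are computed per monomer; averaging across monomers is left to the
caller (profiles add exactly with frame-count weights, a property the tests
pin down).

## Gating geometry

* `min_distance_series()` — per frame, the minimum over all atom pairs of
  the minimum-image distance between two selections (e.g. loop D C&alpha;
  vs N-terminus C&alpha;). A running mean (default 1 ns) is available for
  plotting; statistics always use the raw minima.
* `salt_bridge_series()` — the same minimum distance between charged-group
  heavy atoms (phosphoryl oxygens, guanidinium nitrogens, ... — see
  `charged_group_atoms()`), plus a `formed` flag at a 4.0 Å cutoff (closed
  interval). The cutoff is a convenience layer over the raw distances,
  which are always retained, since plotted bridge distances in the
  literature rarely declare one.
* `superpose()` — least-squares rigid-body superposition via the SVD
  (Kabsch) solution with the proper-rotation correction; collinear fit sets
  are refused rather than silently resolved.
* `rmsf()` — two-pass fluctuation profile: fit all frames to the first
  frame, compute the mean structure, refit to the mean, then
  $\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}$.
  Global rigid-body motion is removed by construction; isotropic jitter of
  width $\sigma$ per coordinate gives $\sigma\sqrt{3}$, which the tests
  verify to 3 %.
* `average_structure()` — frames in a `[start, end)` ps window are fitted
  to the window's first frame and averaged arithmetically, for comparison
  with a crystallographic reference. The fit selection is the caller's: a
  sensible default for gating work is all C&alpha; except the mobile loop
  and the termini, so the flexible part does not drag the fit.

## Block statistics

Condition comparisons treat fixed-length sub-trajectories as replicate
samples: `partition_blocks()` cuts a span into consecutive half-open 10-ns
blocks (remainder dropped with a warning), so 200 ns of one monomer yields
20 repetitions and 500 ns over four monomers yields 200.
`per_block_metric()` evaluates crossings (by exit time), pf, or mean
minimal distance independently per block; a block on which a metric is
undefined is flagged `NA`, not silently dropped.

`compare_conditions()` gates the test choice: Shapiro–Wilk per group and
median-centred Levene (Brown–Forsythe) across groups, both at
$\alpha = 0.05$. All gates pass → Student's t (two groups) or one-way
ANOVA with Tukey HSD; any gate fails → Mann–Whitney or pairwise Wilcoxon
rank-sum with Bonferroni correction. Two open points are resolved as
follows: "Wilcoxon" for multi-group data is read as the rank-sum test on
independent blocks (signed-rank would presume pairing the block design does
not create), and no omnibus Kruskal–Wallis pre-gate is applied, matching
the literal reading of "Bonferroni post hoc correction after Wilcoxon
test". The whole decision trail is kept on the result object.

Adjacent blocks of one trajectory are not strictly independent;
autocorrelation is deliberately not corrected, for fidelity to the block
design this reproduces, and the type-I calibration of the full gated
procedure (empirically within [0.03, 0.07] at $\alpha = 0.05$ under a
normal null in the tests) quantifies what the gate itself costs.

## Synthetic fixtures and what they do (not) show

`simulate_channel_waters()` generates non-interacting particles whose
axial moves are Gaussian with variance $2 D \,\mathrm{d}t$, accepted by a
Metropolis criterion on an axial potential $U(z)$ and reflected at the box
z-faces. Metropolis acceptance makes the stationary axial density exactly
Boltzmann — the property the free-energy recovery analyses need — at the
price of dynamical realism near high barriers (a warning fires when
acceptance drops below 0.5). Initial positions are drawn from the
stationary density by rejection sampling, so there is no burn-in. Lateral
positions are uniform in the channel disc and fixed. Seeds are mandatory
and fix the output bit-for-bit.

The two presets encode the study conditions compared end-to-end: `"open"`
is free diffusion, `"closed"` adds a 5 kJ/mol harmonic barrier
(half-width 7.5 Å) across the channel, with 80 waters in a 40×40×60 Å box,
$D = 0.3$ Å²/ps, 303.15 K, dt = 2 ps and 100 ns (ten 10-ns blocks). At
this barrier height (≈ 2 kT) suppression of crossings is governed by the
diffusive resistance integral $\int e^{U(z)/k_BT}\,dz$, not by the bare
Boltzmann factor — the measured count ratio (≈ 0.4) sits between
$e^{-U_0/k_BT}$ and 1, and the tests assert exactly that band.

`simulate_gating_scaffold()` builds a toy protein: rigid N-terminal
pseudo-C&alpha; (resid 21–30), a mobile loop (resid 185–200) whose
separation switches between closed (6 Å) and open (20 Å) targets on a
schedule, and phosphoryl/guanidinium pseudo-groups (SEP 188, ARG 187/190)
whose distance flips across the 4 Å bridge cutoff with the state, under
Gaussian jitter (σ = 0.3 Å).

What passing these tests shows is that the *analysis code* is correct on
data whose answer is known. What it does not show: single-file water
correlations, protein–water coupling, lipid environment, finite-size
electrostatics — none of which the generator attempts. Absolute
permeabilities of real channels, and the published magnitudes derived from
microsecond all-atom trajectories, are out of reach of these fixtures by
design; the package's claims about real data are limited to implementing
the standard estimators correctly.

## Problem sizes and numerical tolerances

The test suite runs everything at desk scale, chosen so each check has
clear statistical headroom: 20-seed oracle sweeps at 12 waters × 600
frames; D_n recovery at 20 waters × 5 ns × 20 seeds (15 % band);
free-energy recovery at 200 waters × 3 ns (0.5 kJ/mol RMS band against a
5 kJ/mol barrier, typical error ≈ 0.1); RMSF at 10 000 frames (3 % band);
gate calibration at 1000 replicates; and the preset contrast at 2 × 100 ns.
PDB round-trips are asserted to the format's 10⁻³ Å, XYZ to 10⁻⁶ (the
writers' printed precision); superposition agreement with a grid-refined
rotation search to 10⁻³ Å.

## Known limitations

Orthorhombic boxes only (triclinic input is refused, not approximated);
no binary trajectory formats (XTC/DCD); no bonded topology, hydrogen-bond
angles, secondary structure or pore-radius profiling; waters are
identified by residue name (TIP3/HOH/SOL/WAT) with the oxygen as the
molecule position. The loop-D and N-terminal residue sets of any real
channel must be supplied as selection expressions — sequence numbering
differs across homologues, so no residue list is hard-coded.
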