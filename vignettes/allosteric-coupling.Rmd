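---
title: "Ranking candidate allosteric sites by coupling to the GPCR activation variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate allosteric sites by coupling to the GPCR activation variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

G protein-coupled receptors switch between inactive and active
conformations through a stereotyped collective rearrangement: the
intracellular end of TM6 swings outward while TM3 and TM7 move inward.
`allodyn` summarizes this motion with a single geometric collective
variable,

$$\Delta = d_1 - d_2,$$

where $d_1$ is the C$\alpha$ distance between anchor residues on TM2 and
TM6 and $d_2$ the C$\alpha$ distance between anchors on TM3 and TM7.
Active-like conformations have large $\Delta$ (outward TM6, inward
TM3/TM7); inactive structures have small or negative $\Delta$.  The
package ships author-numbered anchor presets for the beta-2 adrenergic
receptor (Y70/G276/C125/I325), the glucagon receptor (A175/L347/L243/V398)
and the M2 muscarinic receptor (Y60/L390/L115/C439); any other receptor
requires four explicit anchors, because generic-numbering lookups against
external services are deliberately not performed.

Given a conformational ensemble of $F \ge 3$ frames harmonized to a common
residue set, every unordered residue pair $(i, j)$ contributes a distance
series $d_{ij}(f)$, and its coupling to activation is the Pearson
correlation

$$C_{ij} = \frac{\mathrm{cov}(d_{ij}, \Delta)}{\sigma_{d_{ij}}\,\sigma_\Delta}.$$

A candidate binding site with $N$ residues is scored by the mean absolute
coupling over its internal pairs,

$$C_\mathrm{site} = \frac{2}{N(N-1)} \sum_{i<j} |C_{ij}|,$$

and sites are ranked by $C_\mathrm{site}$; sites whose score strictly
exceeds the unweighted mean of the ranking are flagged as potentially
allosteric.  The premise is that a pocket whose internal geometry breathes
in concert with the activation motion is a pocket whose occupation can
bias that motion.

Key assumptions worth keeping in mind:

* $\Delta$ is a meaningful order parameter only when the ensemble actually
  mixes inactive and active conformations; on a single-state ensemble the
  correlations measure coupling to thermal fluctuations of $\Delta$, which
  is a much weaker and noisier signal.
* Pearson correlation captures linear (more precisely, monotone-linear)
  co-variation.  With an effectively bimodal ensemble the distinction
  barely matters — any deterministic dependence on the two-valued state
  yields $|C_{ij}| = 1$ — but on continuous ensembles strongly nonlinear
  couplings will be under-read.
* All frames carry equal weight, so the inactive/active mixture ratio of
  the input ensemble directly shapes the correlations.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| active / inactive $\Delta$ thresholds | 8 / 0 | Å | state labels for reporting only; never used in the coupling computation (they are observations on one receptor, not a general rule, so they are configurable and cosmetic) |
| strong-coupling display threshold | 0.75 (strict) | — | masks the exported coupling map to visually dominant entries |
| pocket presence fraction | 0.40 (inclusive) | — | a pocket must be detected in at least this fraction of frames to be scored |
| residue-assignment cutoff | 4.0 (inclusive) | Å | a residue joins a pocket if any heavy atom lies within this distance of any pocket dummy atom in at least one frame (union over frames; a single-frame override exists) |
| orthosteric overlap | 0.50 of the smaller set | — | sites overlapping a user-supplied orthosteric residue set at or above this fraction are dropped |
| ENM cutoff / spring constant | 13 / 1 | Å, energy Å$^{-2}$ | standard anisotropic-network practice; the spectrum scales trivially with the spring constant |
| harmonic modes | min(100, available) | — | lowest-frequency nonzero modes combined per trajectory |

Above-mean flags are computed on unrounded scores by default; a
`rounded = TRUE` option reproduces the behavior of a two-decimal printed
table.  Scores are reported at two decimals but retained at full precision
internally.

## Ensemble handling

Residues are matched across frames by chain, author number and insertion
code only; no sequence alignment or renumbering is attempted, so
heterogeneous collections must share a numbering scheme.  Residues missing
a C$\alpha$ in any frame are dropped globally (with a warning) rather than
imputed.  Altloc duplicates keep the highest-occupancy copy (ties toward
altloc A); hydrogens are ignored; HETATM records never enter the analyzed
residue set.  Superposition (Kabsch, on common-residue C$\alpha$'s) is
mathematically irrelevant to the couplings — inter-residue distances are
rigid-motion invariant, and the tests assert this — but it is applied
before pocket ingestion so that detector dummy atoms and atoms share a
frame of reference.

## The harmonic generator

The package generates mixed two-state ensembles from a C$\alpha$
anisotropic elastic network: springs of uniform stiffness connect all
C$\alpha$ pairs within the cutoff, the Hessian is diagonalized, and frames
displace the reference along the lowest-frequency nonzero modes.  This is
a coarse surrogate for all-atom, force-field normal modes: it reproduces
the low-frequency collective deformations that dominate the activation
motion, and none of the local chemistry.  Quantitative site scores from
harmonic ensembles therefore depend on the generator's amplitude
convention, which is a genuine free choice: we draw independent Gaussian
mode amplitudes per frame with variance $T/\lambda_k$ (equipartition), and
provide a deterministic sinusoidal sweep with the same per-mode variance
as an alternative.  A mode count of 100 is the conventional "lowest
frequency modes" budget; since a toy system may own fewer than 100 nonzero
modes, the default resolves to `min(100, available)` and only an
explicitly requested larger count is an error.

Zero modes are detected by a relative eigenvalue threshold
($\lambda < 10^{-8}\lambda_\mathrm{max}$); a connected, non-collinear 3-D
network has exactly six.  Disconnected networks are rejected with a
suggestion to enlarge the cutoff rather than silently analyzed per
component.

## The synthetic benchmark

The toy generator builds an idealized C$\alpha$ bundle — seven ideal
helices (rise 1.5 Å, 100°/residue, helix radius 2.3 Å) on an 11 Å circle —
and plants a known signal controlled by a latent activation coordinate
$\lambda \in \{0, 1\}$:

* the TM6 anchor moves outward along the TM2→TM6 axis and the TM3/TM7
  anchors move toward each other, so that $\Delta$ changes by exactly
  `activation_gap` (default 8 Å, matching the separation seen between
  experimental inactive and active structures) between the pure states;
* the residues of one planted "coupled" site move radially outward from
  the bundle axis, with fixed per-residue directions so that every
  internal distance of the site is a deterministic, near-linear function
  of $\lambda$; the displacement magnitude is calibrated by root-finding
  so the mean internal distance changes by `coupling_slope` (default
  1 Å per Å of $\Delta$);
* decoy sites receive only the isotropic i.i.d. Gaussian coordinate noise
  (default $\sigma = 0.2$ Å) shared by every residue and frame.

Radially outward motion points into empty space outside the bundle, which
keeps the active-state geometry clash-free; frames in which noise still
produces an inter-residue distance below 1 Å have their noise redrawn (at
most ten attempts per frame).  Default sampling is 50 + 50 frames of the
two pure states; intermediate $\lambda$ sampling is off by default because
experimental ensembles are effectively bimodal.

What passing the benchmark does and does not show: the generator emulates
the *statistical* structure of the problem — a bimodal order parameter,
one residue set whose internal geometry co-varies with it, others that
fluctuate independently — under exactly the noise model the estimator
assumes (isotropic, uncorrelated).  Real ensembles have correlated elastic
fluctuations (that role belongs to the harmonic module), anisotropic
experimental uncertainty, loop disorder and numbering heterogeneity, so
planted-signal recovery here is a necessary sanity bar, not evidence about
real receptors.

## Numerical choices

* Correlations use R's `cor` (the field-standard path); entries whose
  distance series has exactly zero variance are undefined and flagged
  invalid; they contribute zero to site sums while remaining in the
  $N(N-1)/2$ denominator, so a rigid pair dilutes rather than inflates a
  site score.  A constant $\Delta$ is an error, not a silent all-invalid
  matrix.
* Each unordered pair is computed once and mirrored, so the matrix is
  symmetric to the last bit.
* Ranking ties break by ascending site label; ranks are 1-based; the
  above-mean rule is strict (a lone site is never above its own mean).
* Superposition uses SVD with a reflection guard; collinear point sets
  are rejected as underdetermined.  Pocket assignment uses a cell-list
  neighbor search with cells of one cutoff edge, verified against an
  all-pairs oracle.
* The assignment and presence boundaries are inclusive ("within 4.0 Å",
  "at least 40%").

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: 70-residue toy bundles at 100 frames (100 replicate seeds for the
recovery rate), brute-force cross-checks on ensembles up to 8 residues by
25 frames, and harmonic ensembles of 10,000 frames for the equipartition
and mean-structure checks.  These sizes keep the full suite around a
quarter of a minute while leaving every statistical tolerance comfortably
non-marginal; the implementation itself handles receptor-sized inputs
(hundreds of residues, thousands of frames) with the same code paths.

## Known limitations

* Sites are taken from an external pocket detector or user lists; no de
  novo pocket detection, no automatic surface-versus-buried
  classification (the published workflow curated these manually; we honor
  explicit exclusion lists instead of guessing).
* Generic-number anchor resolution requires no network access and
  therefore no receptors beyond the three presets are auto-configured.
* Statistical significance of individual correlations is not assessed;
  scores are a relative ranking tool, and the above-mean flag is a
  reporting convention, not a hypothesis test.
* XTC trajectories are not read; use DCD with a PDB topology, or convert.
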