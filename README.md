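# allodyn

Ranking candidate allosteric sites in G protein-coupled receptors (GPCRs)
by how strongly their internal geometry is coupled to the receptor's
activation motion.

## The problem

GPCR activation is a collective rearrangement — TM6 swings outward, TM3
and TM7 move inward — and pockets whose shape co-varies with that motion
are natural candidates for allosteric modulation: a ligand parked there
can block or bias the transition.  `allodyn` quantifies this idea over any
conformational ensemble (collections of experimental structures,
normal-mode "harmonic" trajectories, MD snapshots):

1. A per-frame activation variable
   **Δ = d₁ − d₂**, with d₁ the TM2–TM6 and d₂ the TM3–TM7 Cα distance
   (anchor presets for β2AR, GCGR and M2 are built in).
2. For every residue pair (i, j), the Pearson coupling of its Cα distance
   series to Δ:
   **C·ᵢⱼ = cov(dᵢⱼ, Δ) / (σ_dᵢⱼ σ_Δ)**.
3. For each candidate site with N residues, the mean absolute internal
   coupling
   **C_site = 2/(N(N−1)) Σᵢ<ⱼ |Cᵢⱼ|**,
   used to rank the sites; sites strictly above the ranking mean are
   flagged potentially allosteric.

Candidate sites come from Mdpocket/fpocket dummy-atom output (STP
records), with the standard retention rules — present in ≥ 40% of frames,
residues assigned within 4.0 Å of any dummy atom — or from explicit
residue lists.  The package also ships a Cα elastic-network generator for
two-state harmonic ensembles and a synthetic toy-receptor generator with
a planted coupled site, so the entire pipeline is testable end to end
without downloading a single structure.

Intended users: structural bioinformaticians and molecular modellers
triaging pockets on receptors with at least two conformational states in
hand (or derivable via normal modes).

## Worked example

Generate a synthetic two-state bundle (50 inactive + 50 active frames,
0.2 Å coordinate noise, one planted coupled site, two decoys), write it as
a normal fixture bundle (multi-MODEL PDB + site lists + pocket cloud), and
run the full pipeline on the files:

```r
library(allodyn)

toy   <- generate_toy_ensemble(toy_receptor_spec(seed = 1))
paths <- write_fixture_bundle(toy, "fixture")

cfg <- pipeline_config(
  ensemble = list(multi_model = paths[["ensemble"]]),
  delta    = list(anchors = c("A:15", "A:55", "A:25", "A:65")),
  sites    = list(site_lists = paths[["sites"]]),
  seed     = 1)
bundle <- run_pipeline(cfg, out_dir = "fixture/out")
render_report(bundle)
```

```
== allosteric coupling report ==
frames: 100   residues: 70   sites: 3
delta by state:
  intermediate n= 51  delta   0.03 ..   8.00 (mean   3.82)
  inactive     n= 23  delta  -0.83 ..  -0.01 (mean  -0.36)
  active       n= 26  delta   8.00 ..   8.87 (mean   8.40)
strong couplings (|c| > 0.75): 564 residue pairs
ranking (mean C_site = 0.35):
   1. coupled    C_site 0.88 *  top pair A:34 - A:44 (c = +0.99)
   2. decoy2     C_site 0.10    top pair A:53 - A:70 (c = +0.19)
   3. decoy1     C_site 0.07    top pair A:4 - A:18 (c = +0.18)
```

Reading this: the two generated states differ by 8 Å in Δ, so frames
split cleanly (the "intermediate" rows are frames sitting exactly at the
reporting thresholds of 8 and 0 Å — the thresholds label states for
display and play no role in the scores).  The planted site is ranked
first with C_site = 0.88 and is the only site above the ranking mean; its
top pair couples to Δ at c = 0.99.  Decoys land an order of magnitude
lower, at the noise floor for 100-frame ensembles.  The output directory
holds the per-frame Δ table, the full/long/strong coupling matrices,
per-site sub-matrices, the ranking as TSV and JSON, and a run log with
the exact configuration.

A ranking can also be recomputed from published C_site values alone:

```r
rank_sites(c(site4 = 0.76, site3 = 0.61, site7 = 0.60, site6 = 0.59,
             site5 = 0.50, site2 = 0.49, site8 = 0.44, site9 = 0.33,
             site1 = 0.31))
#> site ranking (mean C_site = 0.51):
#>  rank  site C_site above_mean
#>     1 site4   0.76          *
#>     2 site3   0.61          *
#>     3 site7   0.60          *
#>     4 site6   0.59          *
#>     5 site5   0.50
#>     ...
```

A thin CLI wrapping the same functions lives at `inst/cli/allodyn.R`
(verbs: `run`, `delta`, `rank`, `synth`, `harmonic`).

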