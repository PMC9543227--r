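# longconn

Longitudinal functional brain network analysis from EEG source
connectivity, with a fully synthetic, ground-truth-known cohort
generator.

## The problem this package addresses

Longitudinal electrophysiology studies of neurodegenerative disease —
the motivating case is Parkinson's disease followed over baseline
(`BL`), 3-year (`3YFU`) and 5-year (`5YFU`) visits — ask which
functional subnetwork weakens as the disease progresses, whether that
loss tracks cognitive (MoCA) and motor (UPDRS-III) decline, and how it
relates to the lateralization of motor symptoms. Answering these
questions takes a chain of methods that each need careful statistical
treatment:

* **wMNE source reconstruction**: region time series from sensor data
  through a leadfield `G`, via the depth-weighted Tikhonov kernel
  `K = (GᵀG + λBᵀB)⁻¹Gᵀ`, `B = diag(‖g_k‖^w)`.
* **Phase-locking value (PLV)** connectivity per frequency band
  (θ 4–8, α1 8–10, α2 10–13, β 13–30 Hz):
  `PLV_ij = |T⁻¹ Σ_t exp(i(φ_i(t) − φ_j(t)))|`.
* **Network-based statistic (NBS)**: edgewise paired t statistics with
  confound adjustment (age, sex, education, LEDD, dominant side),
  supra-threshold connected components, and sign-flip permutation
  control of the family-wise error over component extent, with exact
  enumeration available for small n.
* **Network index (NI)**: per patient and visit, the mean weight over
  the edges of a significant subnetwork, `NI = Σᵢ Wᵢ / N` — a scalar
  trajectory that can be tested across visits (Bonferroni over the
  three visit pairs), cross-applied to controls or other subgroups,
  and correlated with clinical score changes.
* **Lateralization**: dominant motor side from the lateralized
  UPDRS-III items 20–26 (strict dominance at every visit), subgroup
  NBS, and hemisphere/lobe dominance summaries of the resulting
  networks.

Because raw clinical recordings of such cohorts are generally not
redistributable, the package includes a first-class synthetic module:
phase-coupled narrowband source simulation with a PLV oracle, and a
longitudinal cohort generator that plants a progressive connectivity
decrement in a known subnetwork and couples clinical-score changes to
each subject's realized loss. Every downstream stage is validated
against that ground truth.

## Worked example

```r
library(longconn)

atlas   <- default_atlas()                        # 210 regions, 105 per hemisphere
planted <- default_planted_subnetwork(atlas)      # 125 edges / 72 regions, right-dominant
cohort  <- simulate_longitudinal_cohort(atlas, n_pd = 35, n_hc = 32,
                                        planted = planted_effect(planted),
                                        seed = 42)

res <- nbs(cohort, "BL", "5YFU",
           confounds = c("age", "sex", "education", "ledd", "dominant_side"),
           primary_threshold = 3.2, n_permutations = 1000, seed = 42)
top <- res$components[[1]]
top
#> <subnetwork> 152 edges / 94 regions (threshold 3.2, corrected p = 0.000999)

dominance_summary(top, atlas)$edge_shares
#>    intra-L    intra-R      inter
#> 0.03947368 0.77631579 0.18421053

traj <- ni_trajectories(cohort, top)
longitudinal_ni_test(traj)
#>   tp_a tp_b  n statistic mean_change            p p_bonferroni
#> 1   BL 3YFU 35  24.63531  0.04310595 2.910004e-23 8.730011e-23
#> 2   BL 5YFU 35  23.86135  0.08653833 8.131607e-23 2.439482e-22
#> 3 3YFU 5YFU 35  22.59970  0.04343239 4.634906e-22 1.390472e-21

correlate_ni_score(cohort, traj, "moca", "change-vs-change",
                   interval = c("BL", "5YFU"))
#>          r         p  n variable          pairing     when
#> 1 0.220844 0.2023478 35     moca change-vs-change BL->5YFU
```

Reading the output: the NBS finds one large significant component —
152 edges over 94 regions at permutation-corrected p ≈ 0.001 — that
overlaps the planted 125-edge network and, like it, sits almost
entirely in the right hemisphere (intra-R edge share 0.78). The NI
over that component falls progressively and significantly across all
three visit pairs in patients (mean loss 0.087 from BL to 5YFU), and
its change correlates positively with the MoCA change (r = 0.22 here;
the generator's default score noise puts the expected change–change
correlation near 0.4, so single-cohort estimates at n = 35 scatter
widely — the package's correlation-recovery study quantifies this at
n = 200).

The `analysis/` directory runs the full study as numbered narrative
scripts (simulate → source connectivity demo → NBS contrast → network
index → lateralization), writing tables, subnetwork exports (TSV +
BrainNet Viewer `.node`/`.edge`), and seed-stamped JSON under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_source_connectivity.R
Rscript analysis/03_nbs_contrast.R
Rscript analysis/04_network_index.R
Rscript analysis/05_lateralization.R
```

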