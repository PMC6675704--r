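# pepscreen

Analysis pipeline for **peptide-microarray autoantibody serology**: screening
patient sera against a panel of overlapping peptides tiled across a candidate
tumor antigen, and asking which peptides' autoantibodies separate cases from
controls, how serostatus evolves after surgery, and whether it predicts
recurrence-free survival (RFS). The reference application is serum IgG against
MGMT (O-6-methylguanine-DNA methyltransferase) peptides in glioma patients
versus healthy donors, but every stage is antigen-agnostic.

It is written for bioinformaticians and biostatisticians analysing
case–control serology screens who need the whole chain — from per-spot
intensities to survival models — reproducible, tested and scriptable.

## What it computes

* **Tiling** — an antigen of length *L* is cut into peptides of length
  *ℓ* = 20 every *o* = 10 residues: *n* = ⌈(*L* − ℓ)/*o*⌉ + 1 tiles, the last
  truncated at *L*. The inverse (overlap assembly from a printed panel table)
  is provided for validation.
* **Spot signal** — per-block background *b* = mean of the eight blank spots;
  per-spot **SNR = (s − b)/b**; control-based array QC; replicate arrays
  averaged into one profile per serum.
* **Seropositivity cut-offs** — per peptide, the SNR threshold *c* maximizing
  the case−control difference in positive rate, with SNR ≥ *c* called
  positive; exact search over observed values, smallest-candidate tie-break.
* **Group comparison** — per-peptide 2×2 tables, two-sided Fisher exact p
  (minimum-likelihood convention), Bonferroni correction against the panel
  size, whole-percent report rendering, and selection of the top responsive
  peptides (adjusted p < 0.05, ranked by rate difference).
* **Longitudinal coverage** — seropositive fraction per peptide, group and
  timepoint at fixed preoperative cut-offs, plus per-patient trajectories
  with seroreversion/seroconversion transitions.
* **Serology–IHC association** — IHC dichotomization (MGMT > 10% positive,
  Ki-67 > 20% high) and the midrank Spearman coefficient, which equals the
  phi coefficient (ad − bc)/√((a+b)(c+d)(a+c)(b+d)) for binary pairs.
* **Survival** — RFS from clinical dates, Kaplan–Meier curves, log-rank test,
  Cox proportional hazards (Breslow ties) with Wald CIs, and forward
  selection by likelihood-ratio entry at p < 0.05.
* **Synthetic cohorts** — a seeded generator emulating the full study design
  (replicate arrays, 9×9 blocks with 4 positive / 1 negative control and 8
  blanks, log-normal SNR mixtures, postoperative decay, recurrence rebound,
  serostatus-dependent hazards) so everything runs without real sera.

## Worked example

```r
library(pepscreen)

# reconstruct the MGMT antigen from the shipped panel table and re-tile it
antigen <- assemble_from_tiles(mgmt_peptide_table())
tiles   <- tile_protein(antigen, id = "MGMT", tile_length = 20, offset = 10)
head(tiles, 3)
#>      name index start end             sequence
#> 1 MGMT-01     1     1  20 MDKDCEMKRTTLDSPLGKLE
#> 2 MGMT-02     2    11  30 TLDSPLGKLELSGCEQGLHE
#> 3 MGMT-03     3    21  40 LSGCEQGLHEIKLLGKGTSA
nrow(tiles)        # 20 peptides; the last one ends at residue 206

# data-driven seropositivity cut-off for one peptide
optimize_cutoff(case_snr    = c(7.1, 5.5, 0.6, 8.0, 0.2),
                control_snr = c(0.4, 0.1, 5.6, 0.3, 0.7, 0.5))
#> $cutoff               0.6
#> $max_difference       0.467   # 4/5 cases vs 2/6 controls at SNR >= 0.6
#> $candidates_evaluated 11

# screening-table rendering of a case-control comparison
calls <- data.frame(serum_id = paste0("s", 1:10),
                    group = rep(c("glioma", "healthy"), each = 5),
                    peptide = "MGMT-02", snr = NA, cutoff = 5.5,
                    positive = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                 TRUE, FALSE, FALSE, FALSE, FALSE))
render_comparison(compare_groups(calls, m = 20))
#>   peptide cutoff difference_pct    case control p_value p_adjusted
#> 1 MGMT-02    5.5             40 3 (60%) 1 (20%)   0.524          1
```

The columns mirror a published screening table: counts with whole-percent
rates per group, their difference in percentage points, the Fisher exact p
and its Bonferroni adjustment against the 20-peptide panel.

## The full analysis workflow

The numbered drivers under `analysis/` run a complete simulated study
(67 cases / 311 controls, two arrays per serum, day-30 and recurrence
follow-up, RFS outcomes) end to end, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # seeded synthetic study -> scratch/study
Rscript analysis/02_quantify_snr.R  # SNR profiles + array QC
Rscript analysis/03_serostats.R     # cut-offs, screening table, top peptides
Rscript analysis/04_longitudinal.R  # coverage per timepoint, trajectories
Rscript analysis/05_association.R   # serostatus vs IHC (Spearman/phi)
Rscript analysis/06_survival.R      # KM, log-rank, Cox + forward selection
```

On the default seed this selects five highly responsive peptides, shows
case coverage dropping at day 30 and rebounding at recurrence for the
target peptide, and forward selection entering serostatus alone
(e.g. `MGMT-02 serostatus log-rank: chi-square 8.40, p = 0.003746`,
multivariable HR 2.39, 95% CI 1.30–4.39). Alternatively,
`run_pipeline(<study dir>, <out dir>)` executes all stages in one call.

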