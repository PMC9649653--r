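# egfr19

Quantitative analysis of EGFR exon 19 variants and their sensitivity to
tyrosine kinase inhibitors (TKIs).

Non-small cell lung cancers driven by EGFR exon 19 mutations are treated as
a single group in the clinic, yet individual variants respond very
differently to erlotinib and osimertinib. The deletions and indels involved
all shorten the loop connecting strand β3 to the regulatory αC helix of the
kinase domain, and the net length of that shortening predicts behaviour:

- **Profile 1** (net deletion ≤ 3 residues): wild-type-like ATP affinity
  (low *K*<sub>M,ATP</sub>), primary resistance to first- and
  third-generation TKIs.
- **Profile 2** (net deletion ≥ 4 residues): raised *K*<sub>M,ATP</sub>,
  retained sensitivity to erlotinib and osimertinib.

Afatinib sensitivity is similar across both profiles. `egfr19` implements
this classification together with the estimator chain that supports it, for
kinase biochemists and translational researchers who need to place an
uncommon exon 19 variant on this map:

1. **Variant parsing & classification** — Δ-notation
   (`ΔL747-A750InsP`), HGVS-like protein notation (`E746_A750del`,
   `L747_A750delinsP`) and substitutions (`L747P`) parsed against the
   EGFR reference (UniProt P00533, precursor numbering = mature + 24),
   with net loop shortening, proline flags and profile calls.
2. **Steady-state kinetics** — fluorescence calibration, initial-velocity
   windows, Michaelis–Menten fits
   (*v* = *V*<sub>max</sub>[S]/(*K*<sub>M</sub>+[S])), one-parameter IC50
   fits (Rate = 100/(1+[TKI]/IC<sub>50</sub>)), the Cheng–Prusoff relation
   IC<sub>50</sub> = *K*<sub>I</sub>(1+[ATP]/*K*<sub>M,ATP</sub>), and the
   endpoint-titration correction
   *k*<sub>cat</sub><sup>corr</sup> = *k*<sub>cat</sub><sup>app</sup> ·
   [TKD]/(2 · IC<sub>50</sub><sup>afatinib</sup>).
3. **HDX-MS** — percent exchange
   %Ex = (*m*<sub>t</sub>−*m*<sub>0</sub>)/(*m*<sub>f</sub>−*m*<sub>0</sub>)×100,
   residue-level mapping from overlapping peptides, two-component Gaussian
   envelope deconvolution and EX1/EX2/fused-bimodal regime calls.
4. **Survival** — Kaplan–Meier estimation, median survival and the
   log-rank (Mantel–Cox) test comparing profile 1 vs profile 2 cohorts.
5. **Synthetic data** — seeded generators for progress curves under
   competitive inhibition with substrate depletion, dose–response tables,
   binomial/EX1 isotope envelopes and exponential survival cohorts, so the
   whole chain is testable without instrument data.

## Worked example

```r
library(egfr19)

classify_variants(c("ΔE746-A750", "ΔL747-A750InsP", "L747P", "ΔL747-T751InsP"))
#>       descriptor deletion_start deletion_end deleted_count inserted
#> 1     ΔE746-A750            746          750             5
#> 2 ΔL747-A750InsP            747          750             4        P
#> 3          L747P             NA           NA             0
#> 4 ΔL747-T751InsP            747          751             5        P
#>   net_shortening proline profile activation_predicted
#> 1              5   FALSE       2                 TRUE
#> 2              3    TRUE       1                 TRUE
#> 3              0    TRUE       1                 TRUE
#> 4              4    TRUE       2                 TRUE
```

The common 5-residue deletion is profile 2; the indel that deletes four
residues but inserts a proline nets out at 3 and is profile 1 — while
`ΔL747-T751InsP`, with just one more residue deleted, flips to profile 2.
`L747P` deletes nothing but the proline substitution still predicts
activation.

```r
# erlotinib IC50 predicted from K_I = 5.3 nM and K_M,ATP = 23 uM at 1 mM ATP
predict_ic50(5.3, 23, 1000)
#> [1] 235.7348        # measured: 232 +/- 48 nM

# active-site correction of the apparent turnover number:
# afatinib IC50 36 nM at 100 nM TKD => 72% active enzyme
cc <- correct_kcat(0.91, 100, 36)
c(cc$active_fraction, round(cc$corrected_kcat, 2))
#> [1] 0.72 1.26
```

A command-line wrapper (`inst/cli/egfr19`) exposes the same stages as
subcommands (`classify`, `kinetics`, `ic50`, `ki`, `hdx`, `survive`,
`simulate`) over CSV files with provenance headers.

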