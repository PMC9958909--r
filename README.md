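# nmrdomain

Desk-level analysis of solution-NMR and analytical-SEC data for small
protein domains, written for structural biologists characterizing a newly
delimited domain: does it adopt the expected fold, which parts are rigid,
where does a ligand bind, does it tumble like a monomer or a dimer?

The package covers five stages, each usable on its own:

* **Secondary chemical shifts** — combined Cα/Cβ SCS against a bundled
  random-coil reference, `SCS = ΔδCα − ΔδCβ`; helices are maximal runs of
  ≥ 3 consecutive residues with SCS > +1 ppm, strands ≥ 4 residues with
  SCS < −1 ppm.
* **Backbone flexibility** — {¹H}¹⁵N heteronuclear NOE ratios
  (I_sat/I_ref); residues below 0.5 are flexible, above 0.65 rigid, and a
  gap-tolerant scan delimits the rigid core.
* **Titrations** — fast-exchange peak tracking and combined amide CSPs,
  `CSP = sqrt((ΔδN/5)² + ΔδH²)`, with mean/2σ significance thresholds,
  shift-trajectory cosines between ligands, peak-dispersion fold
  assessment, and wild-type-vs-variant binding comparison.
* **¹⁵N relaxation** — mono-exponential decay fits to R1/R2/R1ρ, the
  R2/R1 correlation-time estimator
  `τc = (1/(2π·νN))·sqrt((3/2)(R2/R1) − 7/6)` (classical reading
  selectable), apparent MW via the empirical 0.6 ns/kDa rule, and a
  chemical-exchange flag from the relative spread of R2.
* **SEC calibration** — `Kav = (Ve − V0)/(Vc − V0)` fit against log₁₀(MW),
  apparent-MW interpolation, and monomer / intermediate / dimer-or-larger
  classification against the theoretical monomer mass.

A seeded synthetic-data module generates every input with known ground
truth — titration peak trajectories from the exact single-site binding
isotherm, relaxation rates from a model-free (Lipari–Szabo) spectral
density oracle, shift tables with planted secondary structure, hetNOE
profiles, SEC runs — so the whole pipeline is testable without
spectrometer data. Readers cover NMR-STAR v3 chemical-shift loops (BMRB
depositions), FASTA, and simple TSV/CSV tables; reports are JSON or TSV.

## Worked example

Flexibility, tumbling and oligomeric state of a 53-residue domain, on
synthetic data with known truth:

```r
library(nmrdomain)

# hetNOE: rigid core with flexible termini
noe <- gen_hetnoe_dataset(residues = 18:70, core = c(30, 67),
                          plateau = 0.8, terminal = 0.2,
                          noise = 0.05, seed = 11)
classify_flexibility(noe)
#> Flexibility over 53 residues: 13 flexible, 2 intermediate, 38 rigid
#> Rigid core: residues 30-67 (gaps <= 3 tolerated)

# relaxation: oracle rates at tau_c = 6 ns, 700 MHz -> decays -> fits
oracle <- simulate_relaxation_rates(6, 700)
t1 <- gen_relaxation_decays(setNames(rep(oracle$r1, 8), 30:37),
                            relaxation_delays("paper_T1"),
                            noise_frac = 0.01, seed = 1,
                            experiment = "T1", field_proton_mhz = 700)
t2 <- gen_relaxation_decays(setNames(rep(oracle$r2, 8), 30:37),
                            relaxation_delays("paper_T2"),
                            noise_frac = 0.01, seed = 2,
                            experiment = "T2", field_proton_mhz = 700)
domain_tauc(fit_rates(t1), fit_rates(t2), nitrogen_larmor(700))
#> Domain tau_c = 6.19 +/- 0.05 ns over 8 residues
#> Apparent MW = 10.32 kDa (0.6 ns/kDa rule)

# SEC: is an 11-kDa apparent mass a dimer of a 5.87-kDa monomer?
run <- gen_sec_run(samples = c(SAP_WT = 11), noise_ml = 0)
cal <- fit_calibration(run$standards, run$v0, run$vc)
cal
#> SEC calibration (V0 8.00 mL, Vc 23.60 mL, 5 standards):
#>   Kav = -0.3500 * log10(MW) + 0.9000   (R^2 = 1.0000)
kav <- compute_kav(run$samples$ve_ml, run$v0, run$vc)
classify_oligomer(estimate_mw(kav, cal), 5.87)
#> $ratio
#> [1] 1.873936
#> $state
#> [1] "dimer_or_larger"
```

The hetNOE call recovers the planted 30–67 core through the noise; the
relaxation chain recovers the 6 ns input to within ~3% (the residual
offset is the documented bias of the R2/R1 estimator, not noise); and the
SEC stage reads an 11-kDa apparent mass as a dimer of a 5.87-kDa chain
(mass ratio 1.87).

There is also a small command-line front end (`inst/cli/nmrdomain`) with
subcommands `mass`, `scs`, `hetnoe`, `csp`, `relax`, `sec` and
`simulate`; run it without arguments for usage.

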