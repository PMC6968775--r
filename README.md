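# psdiff

Portal–systemic (P-S) difference pharmacokinetics: quantifying how much the
intestinal efflux transporters BCRP and P-glycoprotein limit oral drug
absorption, from three-arm knockout-mouse studies.

## What it does

After an oral dose, every absorbed molecule passes the portal vein before
the liver. The excess of portal over systemic plasma exposure, scaled by
portal blood flow, therefore measures intestinal input directly:

    FaFg = Qpv · Rb · (AUC_pv − AUC_sys) / Dose

with Qpv = 106.6 mL/min/kg (mouse portal flow), Rb the blood/plasma
concentration ratio, and the dose in nmol/kg. Around this core estimator
the package provides:

- **NCA** of sparse concentration–time profiles: terminal slope λz,
  t½ = ln2/λz, AUC/AUMC to infinity by trapezoidal rule with terminal
  extrapolation, Cmax/Tmax, MRT, CLtot = Dose/AUC, Vdss = MRT·CL, MAT.
- **Availability chain**: FaFg (portal–systemic difference), BA =
  (AUC_oral/AUC_iv)·(Dose_iv/Dose_oral), Fh = BA/FaFg.
- **ka fitting**: Bateman nonlinear least squares with ke fixed from the
  iv arm, profiled scale, deterministic multistart.
- **Contribution scores**: the absorptive quotient AQ (from ka triplets)
  and rate of contribution R (from FaFg triplets) across
  WT / Bcrp(−/−) / Mdr1a/1b(−/−) arms,
  e.g. R_bcrp = Δb / (x_WT + Δb + Δp) with Δb = x_Bcrp − x_WT.
- **IVIVC quadrants**: in vitro Caco-2 AQ vs in vivo R at a 0.4 criterion
  (true/false positive/negative classes).
- **A recirculatory simulator** with an exact analytic mass balance
  (Qpv·Rb·∫(Cpv−Csys)dt = FaFg·Dose by construction), for parameter
  recovery testing of the whole pipeline.

## Worked example

```r
library(psdiff)

# apparent absorbed fraction of ciprofloxacin in wild-type mice,
# from portal/systemic oral AUCs (nmol/L·h), Rb, and the molar dose
fafg(489, 306, rb = 1.20, qpv = 106.6,
     dose_oral = dose_to_nmol_per_kg(1, 331.34))$fafg
#> [1] 0.4653874        # i.e. 46.5% of the dose reaches portal blood

# rate of contribution of BCRP for sulfasalazine from its FaFg triplet
r_contribution(c(0.16, 1.30, 0.30))$r_bcrp
#> [1] 0.7916667        # BCRP accounts for ~0.79 of the normalized change

# simulate a three-genotype study and run the whole pipeline
study <- simulate_study(n_animals = 2, cv_noise = 0.10, seed = 42)
specs <- list(simdrug = compound_spec("simdrug", 400, 1, 1, 1))
res <- analyze_study(study, specs)
res$contribution
#>   compound   aq_bcrp     aq_pgp aq_estimable    r_bcrp     r_pgp r_estimable
#> 1  simdrug 0.4074653 0.08309166         TRUE 0.3067181 0.1904528        TRUE
```

The simulated truth behind the last call is FaFg 0.50/1.00/0.60 across
WT/BcrpKO/PgpKO — so the true R_bcrp is 0.5/1.1 ≈ 0.45, and a single noisy
two-animal replicate at the sparse schedule scatters around it (0.31
here); the zero-noise and replicated recovery properties are exercised in
the test suite. A score ≥ 0.4 classifies the compound as
transporter-limited in vivo.

Packaged reference tables (printed AUC, ka, FaFg and in vitro AQ summaries
for ciprofloxacin, nitrofurantoin, topotecan and sulfasalazine) are listed
by `psdiff_example()`.

A thin command-line front end lives at `inst/cli/psdiff.R`
(`simulate` and `report` subcommands).

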