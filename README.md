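# perfusim

Desk-scale simulation of myocardial blood perfusion and coronary flow.

Blood reaches the heart muscle through the large epicardial coronary
arteries and then percolates through a hierarchy of intramural vessels down
to the capillaries. Two features dominate this system: coronary flow is
*diastolic-dominant* (systolic contraction squeezes the intramyocardial
vessels, so most perfusion happens while the ventricle relaxes), and valve
disease can *steal* coronary flow — in aortic regurgitation (AR) the leaking
valve lets aortic blood drain back into the ventricle during diastole,
exactly when the myocardium should be perfused.

`perfusim` is an R package for exploring these mechanisms with a reduced,
fully self-contained model chain, aimed at cardiovascular modellers and
methods students who want the coupled physics without a supercomputer or
patient data:

* a **closed-loop 0D circulation**: time-varying-elastance left ventricle,
  passive left atrium, diode valves with instantaneous switching, systemic
  windkessel, constant pulmonary-venous pressure (10 mmHg);
* a **reduced epicardial coronary network**: J terminal branches (LCA/RCA)
  from the aortic root to the perfusion territories, each a series of an
  epicardial resistance, a systolic ostial obstruction, and an interface
  conductance α_j;
* a **three-compartment Darcy model** of the biventricular myocardium
  (arterioles → small vessels → capillaries), solved with P1 finite elements
  on a synthetic truncated-ellipsoid mesh.

## Model

On the porous myocardial domain Ω, each compartment i = 1, 2, 3 satisfies

    u_i + K_i ∇p_i = 0,
    ∇·u_i = g_i − Σ_k β_{i,k} (p_i − p_k),        u_i · n = 0 on ∂Ω,

with permeabilities K_i and exchange coefficients β_{i,k}. The arteriolar
source g_1 distributes each terminal coronary flux Q_j uniformly over its
(Voronoi) territory; g_2 = 0; and the capillary sink

    g_3 = −γ (p_3 − p_bed),      p_bed(t) = a1 · p_LV(t) + a2

surrogates the reservoir effect of the coronary bed: p_bed rises with
ventricular pressure (a1 = 0.4, a2 = 1500 Pa, γ = 1e-4 1/(Pa·s)), which
throttles perfusion in systole and produces the diastolic-dominant flow
pattern. Branch fluxes obey

    Q_j = (p_root − p̄1_j) / (R_epi + R_ostium·[valve open] + 1/α_j),

and the network/Darcy fixed point is solved at every time step by iterative
splitting with under-relaxation (factor 0.1). Myocardial blood flow is
reported as

    MBF(x) = β_{2,3}(x) (p_2 − p_3) · 60 · 100   [mL/min/100mL].

Two scenarios are built in: **PH** (physiological) and **AR** (regurgitant
orifice of 4.5% of the aortic annulus, with the systemic arterial pressure
raised 20% in systole and lowered 20% in diastole).

## Worked example

```r
library(perfusim)

cfg <- default_config(level = "tiny")   # coarse mesh, 4 territories
ph  <- run_scenario(cfg, "ph")
ar  <- run_scenario(cfg, "ar")
ph
#> Perfusion scenario result [PH]
#>   SV 81.5 mL, EF 53.6%, peak p_LV 128.0 mmHg, BP 101.6/78.9 mmHg
#>   diastolic-peak coronary flow 2.20 mL/s at t = 1.228 s (LCA 1.56 / RCA 0.64)
#>   mean MBF at diastolic peak: 88.5 mL/min/100mL
compare_scenarios(ph, ar)
#> PH vs AR comparison
#>   diastolic-peak coronary flow reduction: 26.6%
#>   systolic coronary flow change: +14.5%
#>   mean MBF: 88.5 (PH) -> 64.9 (AR) mL/min/100mL (delta -23.6)
```

Reading: the physiological beat ejects ~81 mL at a peak ventricular pressure
of ~128 mmHg; total coronary inflow peaks early in the filling phase
(t = 1.228 s is 0.43 s into the reported second beat), with the left
coronary carrying more than the right; the mean perfusion of ~88
mL/min/100mL sits in the clinical resting range. The regurgitant valve
steals about a quarter of the diastolic coronary inflow and depresses mean
MBF accordingly, while the (higher) systolic aortic pressure slightly raises
systolic coronary flow.

`plot(ph)` draws the volume, pressure and flow transients;
`write_outputs(ph, "out/ph")` writes CSV transients, a JSON biomarker
summary and VTK snapshots (`fields_peak.vtu` with `p1_Pa`, `p2_Pa`,
`p3_Pa`, `MBF_mL_min_100mL`) viewable in ParaView. A thin command-line
wrapper lives at `inst/cli/perfusim.R` (`run` / `compare` subcommands), and
`scripts/calibrate.R` regenerates the calibrated default parameters.

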