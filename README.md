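# ilizarov

Screw-theory force-transmission analysis for Ilizarov-type circular
external fixators during gradual deformity correction (distraction
osteogenesis). The package is for biomechanics researchers and
device-modelling engineers who have per-period rod-force measurements from
a ring fixator and want to know how much of that force actually reaches the
regenerating bone end.

## The model

The fixator is described by two screws: a prismatic twist
ξ₁ = (0,0,0; 0,0,1) for rod lengthening Δl and a revolute twist ξ₂ (unit
axis x through the hinge at (0,0,l)) for the hinge angle θ. Closed-form
exponential maps give the posture as a product of exponentials,
p(θ) = e^{Δl ξ̂₁} e^{θ ξ̂₂} p(0). Statically, each rod's axial force is a
wrench rotated into the bone-end frame by R_x(θ), so the theoretical axial
tension at the osteotomy is

    F_z,2t = (F1 + F2 + F3 + F4) · cos θ,

with the passive support-rod forces modelled as F3 = κ·F1, F4 = κ·F2
(default κ = 0.4). The transfer efficiency is

    η_z = F_z,2m / F_z,2t,

the measured tension over the theoretical one. Companion modules map CT
gray values to bone elastic moduli (E = 2065·ρ^3.09 MPa compact,
1904·ρ^1.64 MPa cancellous), solve a small linear ring/rod/wire surrogate
for load sharing, and generate seeded synthetic bench data so the whole
pipeline is testable without measurement hardware.

## Worked example

```r
library(ilizarov)
analyze_series(load_table3())
```

```
Transfer-efficiency report (10 periods)
 period theta_deg   Fz2t    eta
      1     6.165  12.69 0.4144
      2     5.480  45.93 0.2401
      3     4.795  65.85 0.2366
      4     4.110  93.99 0.5119
      5     3.425 124.17 0.4812
      6     2.740 149.63 0.4867
      7     2.055 190.00 0.4922
      8     1.370 227.34 0.4899
      9     0.685 266.20 0.4893
     10     0.000 304.02 0.4782
plateau mean eta (periods 4-10): 0.4899
total rod load, final period: 304.02 N
```

Reading: per period, the residual hinge angle (degrees), the theoretical
tension F_z,2t (N) and the efficiency η. The first three periods sit at
0.24–0.41 while the frame pre-tightens; afterwards the efficiency plateaus
at about 0.49 — roughly half the theoretically available force reaches the
bone end. The final-period total rod load of 304 N is the sum of the two
measured adjustable forces and the two modelled support forces.

A command-line wrapper ships at `inst/cli/ilizarov-cli.R`:

```sh
Rscript inst/cli/ilizarov-cli.R analyze \
    --in inst/extdata/bench_period_forces.csv --out report.csv
Rscript inst/cli/ilizarov-cli.R simulate --seed 1 --out series.csv
Rscript inst/cli/ilizarov-cli.R show-config
```

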