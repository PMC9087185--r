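# tierdyn

Dynamics of patient visits across China's three-tier hospital system.

China grades its hospitals into first-, second- and third-level
institutions (FLH, SLH, TLH). Because patients may seek care at any tier,
many "leapfrog" past primary care to higher-level hospitals, overloading
them while first-level hospitals sit underused. `tierdyn` is for health
services researchers and modellers who want to analyse where this system
is heading: it implements a three-compartment logistic model of monthly
visit counts x(t), y(t), z(t),

    dx/dt = -(r_f/m_f) x² + r_f x - αx - ηx - c_f x
    dy/dt = -(r_s/m_s) y² + r_s y + αx - βy - c_s y
    dz/dt = -(r_t/m_t) z² + r_t z + ηx + βy - c_t z

where each tier grows logistically toward its capacity `m` at inherent
rate `r`, loses visits at churn rate `c`, and the leapfrog rates α
(FLH→SLH), β (SLH→TLH), η (FLH→TLH) move visits up the hierarchy. The
package provides:

* closed-form equilibria E1\*–E4\* with existence conditions, and local
  stability classification from the (lower-triangular) Jacobian;
* trajectory simulation (compiled RHS, adaptive RK45) with steady-state
  detection and one-parameter sensitivity sweeps;
* bounded nonlinear least-squares estimation of the twelve parameters from
  observed Jan–Nov monthly series, with an explicit account of which nine
  parameter combinations the data actually identify;
* a synthetic-data generator for parameter-recovery experiments, plus the
  2019 national hospital-resources table as a packaged fixture;
* a config-driven pipeline (`run_pipeline()`) writing JSON/CSV artifacts
  and a reproducibility manifest.

## Worked example

The packaged reference parameters (`reference_params()`) were estimated
from China's 2011–2018 national monthly series; counts are in units of
10,000 visits per month.

```r
library(tierdyn)
p <- reference_params()

existence_conditions(p)[c("H1", "H2", "H3")]
#> $H1
#> [1] FALSE
#> $H2
#> [1] TRUE
#> $H3
#> [1] TRUE
```

H1 fails (`r_t = 0.0020 < c_t = 0.0271`): third-level growth is below
churn, so TLH visits persist only through leapfrog inflow. H3 holds, so
the positive equilibrium exists and — by the stability theory — attracts:

```r
equilibrium("E4", p)
#> Equilibrium E4: exists
#>   point (10,000 visits/month): x = 2126.3, y = 11041.3, z = 18203.3

classify_equilibrium("E4", p)
#> Equilibrium E4: stable
#>   eigenvalues: -0.0232, -0.0489468, -0.0267933

steady_state(p, c(100, 100, 100))$state
#>       x       y       z
#>  2126.3 11041.3 18203.3
```

Read: under these parameters the system settles at roughly 21.3, 110.4
and 182.0 million visits/month at first-, second- and third-level
hospitals — all three tiers retain patients, far below their capacities
(9000.1, 29899.2, 42999.8 in the same units), and the long-time
integration lands on the closed-form point. Sensitivity sweeps
(`sweep_parameter()`, `capacity_sweep()`) show the one-way coupling:
changing β or `m_t` leaves x untouched, raising α or η drains every tier.

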