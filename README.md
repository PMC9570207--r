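# mipk — pharmacokinetics of oral myo-inositol over an endogenous baseline

Myo-inositol is present in serum before any dose is given: the body makes
it. Standard oral PK models that decay to zero cannot describe such an
analyte. `mipk` implements, as a tested R package, the analysis appropriate
for a single oral dose of an endogenous compound, built around a sparse
nine-rat study (three groups of three Wistar rats, staggered sampling
schedules covering 0–48 h, one oral gavage of 2 g/kg body weight).

The model is a one-compartment disposition with first-order absorption and
a zero-order endogenous input that sustains the pre-dose steady state:

    dA/dt = -ka * A                          A(0) = D
    dX/dt = k_in - (CL/F / V/F) * X + ka*A   X(0) = C0 * V/F
    C(t)  = X / (V/F),        k_in = C0 * CL/F   (steady-state constraint)

so the concentration is the baseline plus a Bateman term,

    C(t) = C0 + D*ka / (V/F * (ka - k_el)) * (exp(-k_el t) - exp(-ka t)),
    k_el = (CL/F) / (V/F).

Observations follow a proportional residual-error model
`C_obs = C * (1 + eps)`, `eps ~ N(0, sigma^2)`, and parameters are
estimated by pooled maximum likelihood on the log scale, with asymptotic
CV% from the observed information. The package also derives the secondary
parameters (k_el, half-life, endogenous input rate k_in = C0·CL/F, AUC =
dose/CL), simulates studies at arbitrary sparse designs with disciplined
per-subject random substreams, runs Monte-Carlo parameter-recovery studies,
and reads/writes an event-oriented delimited dataset format with a
deterministic report pipeline.

Audience: pharmacokineticists and quantitative pharmacologists who need a
reproducible baseline-aware PK analysis, and simulation evidence of what a
sparse design can and cannot estimate.

## Worked example

Simulate the nine-rat study at the published typical values and refit it:

```r
library(mipk)

p <- structural_params(ka = 1.89, cl_f = 0.853, v_f = 5.1, c0 = 10,
                       sigma = 0.243)
sim <- simulate_study(p, rat_study_design(), seed = 20220924)
fit <- mi_fit(sim)
fit
#> Pooled ML fit: 45 observations, logLik -148.851, converged: TRUE
#>   ka    = 1.706     (CV 20.0%) 1/h
#>   cl_f  = 0.8674    (CV 8.8%) L/h
#>   v_f   = 4.937     (CV 9.6%) L
#>   c0    = 10.2      (CV 6.4%) mg/L
#>   sigma = 0.225     (CV 11.1%)

secondary_parameters(fit$estimates, dose_per_kg = 2)
#> Secondary PK parameters
#>   k_el   = 0.175688 1/h        (elimination rate constant)
#>   t_half = 3.94534 h          (biological half-life)
#>   k_in   = 8.84783 mg/h       (endogenous input rate)
#>   AUC    = 2.30568 (g/kg)/(L/h) at 2 g/kg
```

Reading the output: the 45 sparse observations recover the generating
values well — clearance within 2%, volume within 3%, baseline within 2% —
and the absorption rate constant, the hardest parameter at this design, is
recovered within 10% here with an asymptotic CV of ~20%. The derived
half-life of ~3.9 h and an endogenous input of ~8.8 mg/h say the rat turns
over its baseline myo-inositol pool at about 9 mg per hour, and a 2 g/kg
oral dose peaks at `mi_tmax(p)` ≈ 1.41 h, with serum still above the
pre-dose baseline at 24 h (`mi_concentration(p, dose_event(656), 24)` ≈
12.55 mg/L against a 10 mg/L baseline).

The same analysis is available as a one-call pipeline producing a report
bundle (dataset, parameter table, observed-vs-predicted table, manifest):

```r
run_pipeline(list(seed = 20220924), out_dir = "run1")
```

See `vignettes/myo-inositol-pk.Rmd` for the model assumptions, the
numerical choices in the fitter, and what the simulator does and does not
emulate.

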