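# rtspc — statistical process control for automated radiotherapy plan QA

Automated treatment-planning services generate a plan on a reference beam
model; each clinic then recalculates that plan in its own treatment planning
system (TPS) before delivery. The two calculations never agree exactly —
algorithm, commissioning and MLC-model differences (dosimetric leaf gap,
transmission factor) all shift the dose — so a fixed universal tolerance is a
poor monitor. `rtspc` instead applies statistical process control to the
workflow: for every contoured structure it tracks the percent mean-dose
difference between the local recalculation and the reference autoplan,

```
d_s = 100 × (D̄_local(s) − D̄_ref(s)) / D̄_ref(s)   [%]
```

and charts it on an individual (I-) control chart with 3-sigma limits

```
UCL = μ + 3σ,    LCL = μ − 3σ
```

where μ and σ are estimated from the clinic's own history after iteratively
removing observations outside the current limits (so a few gross errors do
not inflate the limits that are supposed to catch them). New cases falling
outside a structure's limits are flagged as out-of-control — evidence of a
systemic change (TPS upgrade, beam-model edit, CT-calibration change) rather
than ordinary case-to-case variation.

The package also characterizes *why* limits sit where they do: sweeping an
MLC machine parameter (dosimetric leaf gap DLG in cm, or MLC transmission
factor MLC-TF) over ≥ 3 levels, it fits ordinary least squares lines to each
structure's per-level UCL/mean/LCL, reports rates of change per 0.1 cm DLG or
0.01 MLC-TF, and estimates the zero crossing — the parameter value at which
the local calculation matches the reference — with configurable exclusion of
unphysical crossings from small structures (eye, lens, optic nerve).

It is aimed at medical physicists monitoring an autoplanning deployment, and
works from either DICOM RT Dose / RT Structure Set pairs, plain JSON dose
fixtures, or precomputed per-structure mean-dose CSV tables.

## Worked example

```r
library(rtspc)

# a 32-case cohort: targets run ~2.3 % hot, brain is flat, one gross error
structures <- data.frame(name = c("PTV1", "larynx", "brain"),
                         offset_pct = c(2.3, 2.3, -0.2),
                         noise_pct  = c(0.45, 0.4, 0.1))
spec <- cohort_spec(structures, n_cases = 32, seed = 2024,
                    outliers = data.frame(case = 17, structure = "PTV1",
                                          value_pct = 9.4))
comp   <- generate_cohort(spec)
charts <- build_charts(comp, min_points = 20)
charts$PTV1
#> <control_chart> PTV1 n = 32 (1 excluded, 1 pass(es))
#>   mean 2.19 %  sigma 0.51 %  limits (0.66, 3.73) %  [sd]
```

The injected 9.4 % error was excluded before μ and σ were estimated, so the
limits reflect routine variation only. The full summary and a new-case check:

```r
chart_summary(charts)
#>   structure         mu     sigma        lcl       ucl n_used iterations
#> 1      PTV1  2.1948041 0.5128045  0.6563906 3.7332176     31          1
#> 2    larynx  2.3509819 0.3510061  1.2979636 3.4040001     32          0
#> 3     brain -0.2099116 0.1046109 -0.5237444 0.1039211     32          0

new_case <- data.frame(case_id = "case_033",
                       structure = c("PTV1", "larynx", "brain"),
                       pct_diff  = c(6.1, 2.5, -0.15))
evaluate_case(charts, new_case)
#>   structure  case_id value_pct  violated       mu       lcl      ucl
#> 1      PTV1 case_033       6.1 above_ucl 2.194804 0.6563906 3.733218
```

A 6.1 % difference on PTV1 is flagged (`above_ucl`); the other structures
are within their limits and produce no report. For machine-parameter work,
see `group_sweep()`, `fit_parameter_response()` and
`summarize_zero_crossings()`; a shell interface with the same functionality
is installed at `inst/cli/rtspc` (subcommands `summarize`, `compare`,
`chart`, `sensitivity`, `simulate`; exit code 0 = in control, 2 = flags
raised, 1 = error).

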