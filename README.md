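# sarcotwitch

Spatially resolved simulation of cardiac sarcomere isometric twitches,
for muscle physiologists and modellers studying why relaxation slows
when peak tension rises.

Experiments on cardiac trabeculae show that the relaxation phase of an
isometric twitch is prolonged in muscles that reached higher peak
tension. `sarcotwitch` implements a mechano-chemical explanation:
tension in the thin filament tightens Ca²⁺ binding to troponin, so the
filament deactivates last where it is loaded most. The activation field
A(x,t) — the fraction of force-generating cross-bridges — is resolved
along the single-overlap region (x = 0 at the mid-line-proximal edge,
x = L_so at the z-disk):

    P(x,t)  = 1 / (1 + exp(n·(−C_s·S(x,t) − ln([Ca²⁺](t)/K_TnCa0))))
    K_TnCa0 = −a·L_sarc + b
    ∂A/∂t   = (1 − A)·P·f_DA − A·f_AD
    ∂S/∂x   = C_f·A,   S(0,t) = 0

driven by a prescribed two-exponential calcium transient and integrated
as a stiff method-of-lines system. Total tension is S(L_so, t), the
accumulated sum of all cross-bridge forces. The package ships the two
reference protocols (a 7-point sarcomere-length sweep at 1.90–2.20 µm
and a calcium-amplitude sweep at fixed 2.2 µm), twitch metrics (peak
tension, time from peak to 50% relaxation t_R50), and least-squares
estimation of (a, b, C_f, C_s) from tension traces with a
synthetic-trace generator for parameter-recovery testing.

## Worked example

```r
library(sarcotwitch)

p  <- model_parameters()      # published constants (a = 1.39, b = 7.76, ...)
ct <- calcium_transient()     # diastolic 0.09, peak 1.45 uM

tw <- simulate_twitch(p, l_sarc = 2.05, ct)
compute_metrics(tw)
#> Twitch metrics: peak 68.63 kPa at 0.187 s, t_R50 = 0.1791 s

length_sweep(p, ct = ct)
#> Twitch sweep (length), 7 conditions
#>  l_sarc peak_tension t_peak  t_r50 ca_peak
#>    1.90        42.71  0.186 0.1275    1.45
#>    1.95        51.42  0.186 0.1455    1.45
#>    2.00        60.06  0.187 0.1621    1.45
#>    2.05        68.63  0.187 0.1791    1.45
#>    2.10        77.13  0.187 0.1956    1.45
#>    2.15        85.54  0.187 0.2117    1.45
#>    2.20        93.88  0.187 0.2273    1.45
```

Peak twitch tension rises near-linearly with sarcomere length (by
51.2 kPa from 1.90 to 2.20 µm here) and t_R50 stretches by ~0.10 s over
the same range — higher tension, slower relaxation. Inspecting
`tw$A` shows the spatial signature: activation peaks later and higher
toward the z-disk, and the 50%-relaxation time of each local trace moves
outward monotonically.

A command-line wrapper with the same defaults lives at
`inst/cli/sarcotwitch` (subcommands `simulate`, `sweep-length`,
`sweep-calcium`, `fit`, `make-fixtures`, `ca-wave`, `overlap`, each
writing delimited text/JSON plus a manifest with the resolved YAML
configuration).

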