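# isodyn

Trajectory-ensemble analysis of photoisomerization quantum efficiency for
light-driven molecular rotors.

## What this is for

Ultrafast double-bond photoisomerization — the primary event of vision in
rhodopsin (via its 11-cis retinal protonated Schiff base chromophore,
rPSB11) and the power stroke of synthetic indanylidene–pyrrolinium (NAIP)
molecular rotors — proceeds on the excited state S1 down a barrierless
twist coordinate to a conical intersection near a 90° twist, where the
molecule hops to S0 and either completes the rotation (product) or snaps
back (reactant).  The quantum efficiency Φ^iso is the fraction of excited
molecules that react.

`isodyn` analyses ensembles of quantum-classical (surface-hopping)
trajectories of such systems.  For each trajectory it extracts, per 1 fs
frame, the twist α (C1–C2–C3–C4), the substituent wag β (R1–C2–C3–R4),
the out-of-plane wag δ_op = α − β, and the p-orbital overlap dihedral

    τ = α − ½ δ_op      (τ = 0 cis, −90° at the intersection, −180° trans)

with finite-difference velocities.  It locates the S1→S0 decay point,
classifies each trajectory reactive/unreactive from the configuration
reached after the hop, and computes the statistics that link reactivity
to the sign and amplitude of dτ/dt at decay: Φ^iso, the fraction of the
population (and of the reactive population) with dτ/dt^decay < 0, the
reactive fraction of the negative-velocity population, the occupancy and
reactivity of the low-amplitude band (−0.8, 0) deg/fs, decay-velocity
histograms, and the initial decay time (IDT) / decay time length (DTL) of
the ensemble.  Population decay is fitted with a lag-plus-two-channel
law, oscillation periods are extracted by sinusoid fits and discrete
spectra, and the average twist is decomposed into a monotonic drift α_I
plus an oscillatory, promoter-coupled α_II.

Because real surface-hopping ensembles are expensive, the package also
ships two generators that exercise the full pipeline at desk scale:

* a kinematic generator with `rh_like`, `naip_like` and `naip_gas_like`
  presets (fast coherent rotor, slow promoter-quenched rotor, isolated
  rotor with a 250 fs ring-inversion promoter), emitting labelled
  ensembles with exact ground truth, and
* a minimal two-state two-mode fewest-switches surface-hopping simulator
  with energy-based decoherence, which reproduces the Landau–Zener limit.

## Worked example

```r
library(isodyn)

rep <- run_pipeline("rh_like", seed = 1)   # 200 synthetic trajectories
rep
#> <isodyn_report: 200 trajectories, 200 classified | Phi_iso = 0.715 [0.649, 0.773] | IDT 30 fs, DTL 152 fs>
```

Of 200 trajectories, 71.5% are reactive (Wilson 95% interval
0.649–0.773); the first hop occurs at 30 fs and the decay window spans
152 fs — the fast, vibrationally coherent regime.  The S1 population fit
and the promoter-velocity (−½ dδ_op/dt) sinusoid fit:

```r
rep$lifetime
#> <S1 lifetime fit: a1=0.000 t1=45.5 fs t2=23.4 fs y0=0.010 | lifetime t1+t2 = 68.9 fs, rms 2.14e-02>
rep$promoter_fit
#> <sinusoid fit: A=1.55, T=40.43 fs, phi=-0.287 rad, c=0.0317, rms 4.81e-02>
```

i.e. a ~69 fs characteristic S1 lifetime and a 40 fs wag promoter with a
1.6 deg/fs average velocity amplitude.  Comparing against the slow-rotor
preset:

```r
cmp <- compare_runs(rep, run_pipeline("naip_like", seed = 1),
                    labels = c("rh", "naip"))
cmp[cmp$quantity %in% c("phi_iso_pct", "frac_reactive_of_neg_pct",
                        "idt_fs", "dtl_fs"), ]
#>   quantity                    rh  naip difference
#> 1 phi_iso_pct              71.5  43.4       28.1
#> 2 frac_reactive_of_neg_pct 85.2  51.9       33.3
#> 3 idt_fs                   30.0 157.0     -127.0
#> 4 dtl_fs                  152.0 448.0     -296.0
```

The slow rotor loses efficiency exactly as the velocity statistics
predict: only half of its negative-velocity decays react, because almost
all of them fall in the low-amplitude band where the sign of dτ/dt stops
being decisive.

Real ensembles are read with
`read_ensemble(root, layout = "xyz_dir")` (multi-frame XYZ with
`time=`/`state=` comment tokens plus a `hops.tsv` sidecar) and analysed
with the same `run_pipeline()` call; `plot_alpha_traces()`,
`plot_velocity_histogram()` and `autoplot()` methods draw the standard
diagnostic figures, and `tidy()`/`glance()` expose the fits.

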