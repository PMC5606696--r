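# paokin

Phosphate-driven selection among polyphosphate-accumulating organisms
(PAOs) in enhanced biological phosphorus removal (EBPR).

## The problem

*Candidatus* Accumulibacter phosphatis — the key uncultured PAO lineage in
EBPR plants — splits by its *ppk1* gene into Type I and Type II, and which
type dominates an enrichment depends strongly on the phosphate concentration
held during the aerobic phase. `paokin` is for researchers and process
engineers who want to analyse that selection quantitatively: it implements
the substrate-inhibition kinetic model that explains the dominance pattern,
the reactor mass balances used to track enrichment, and the clone-library
community profiling used to measure it, plus seeded synthetic-data
generators so the entire pipeline runs end-to-end with no external data.

## The model

The specific substrate-utilization rate of each type follows
substrate-inhibition (Haldane) kinetics:

    nu(S) = Vmax * S / ((Km + S) * (1 + S / Ki))

with `S` the aerobic phosphate concentration (mg P L⁻¹), `Vmax` the maximum
specific rate (T⁻¹), `Km` the half-saturation constant and `Ki` the
inhibition constant (both mg P L⁻¹). The curve peaks at `S* = sqrt(Km*Ki)`
and declines at higher `S`. Because utilization rate maps to growth rate,
the type with the higher `nu(S)` at the held concentration is predicted to
dominate; the concentration where the two types' curves intersect (the
*crossover*) marks the predicted switch from Type II to Type I dominance.
With the published assumed parameter pair — Type I (0.95, 0.48, 2000),
Type II (1.0, 0.5, 300) — Type II wins below the crossover, Type I above
it, and the two are a near-tie at very low phosphate.

## Worked example

```r
library(paokin)

pair <- default_accumulibacter_params()
crossover_concentrations(pair)
#> [1] 18.34844
dominant_label(pair, s = 5)
#> [1] "Type II"
dominant_label(pair, s = 50)
#> [1] "Type I"

traj <- simulate_competition(pair, reactor_config(aerobic_s = 50),
                             n_cycles = 200)
predicted_dominant(traj)
#> [1] "Type I"

composition(c(rep("IA", 8), rep("IIA", 3), rep("IIB", 2)), "Run 1")
#> <composition_table> Run 1 (13 clones)
#>   clade count percent
#> 1    IA     8      62
#> 2   IIA     3      23
#> 3   IIB     2      15
#> Type I 62% / Type II 38%
```

The crossover at ≈18.3 mg P L⁻¹ lies between the 5 mg P L⁻¹ condition
(Type II enriched) and the 50 mg P L⁻¹ condition (Type I enriched): the
kinetic model reproduces the observed dominance switch. The composition
table shows the clade bookkeeping: 8 of 13 clones in clade IA is 62% of the
library, summing to 62% Type I overall.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study over synthetic
inputs and write their tables under `results/`:

1. `01_synthesize_inputs.R` — seeded generation of parameter tables, weekly
   reactor cycle records, clone libraries and the clade reference panel
2. `02_kinetics_dominance.R` — rate curves, per-run dominance, crossover,
   and the exhaustive search for parameter pairs that explain the pattern
3. `03_competition.R` — cycle-by-cycle Type I vs Type II competition
4. `04_mass_balance.R` — per-cycle phosphate uptake/release and COD
   consumption, specific rates per sponge volume
5. `05_community.R` — OTU clustering, clade assignment and composition,
   scored against the generating truth

Run them in order with `Rscript analysis/01_synthesize_inputs.R` etc.

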