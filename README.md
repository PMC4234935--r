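# flatreact

Compile compact multistate biochemical models into flat single-state
reaction networks, with SBML Level 3 Version 1 and CSV export.

## The problem

Many regulatory proteins exist in a family of distinguishable forms —
a substrate with ten phosphorylation sites, a ribosome sitting at one of
300 codons, a scaffold bound or free. Writing such systems as plain
reaction lists is painful: a single phosphorylation chain of length
*n* needs *n* phosphorylation and *n* dephosphorylation reactions that
differ only in an index, and changing *n* means rewriting all of them.

`flatreact` implements a small modeling language in which a species
carries named **sites**, each with an **ordered** (optionally circular)
list of **states**, and one **multistate reaction** stands for the whole
batch of single-state reactions obtained by instantiating its state
ranges. Because the state list is ordered, transitions can be written
with the **succ**/**pred** operators instead of being enumerated:

```
Cdh1(p{0:maxP})                                     # species: 11 forms
Cdh1(p{0:maxP-1}) + ClbM -> Cdh1(succ(p)) + ClbM    # one reaction = maxP reactions
```

Supporting constructs cover the common patterns of such models:

* **SUM aggregates** — `SUM(Cdh1;p{1:maxP})` is the total amount over a
  state range, usable in any expression (optionally weighted per term);
* **variable ranges** — bounds may be fixed global quantities
  (`p{low:high-1}`), so rescaling a model is a one-value edit;
* **transfer of state** — a product or modifier site copies a
  reactant's matched state, optionally through an operator:
  `P1(c=succ(R.c))`;
* **aggregate modifiers** — a stateless species defined by an
  assignment with a moving window, e.g. `M(c) := SUM(R;c{M.c+1:M.c+14})`,
  materialized per instance;
* **user-defined rate laws** with role-typed parameters
  (`GLQ` global, `SITE` numeric state value, `SUB` substrate amount):
  `dis(GLQ N, SITE i, GLQ k, SUB X, SUB K) = (N-i)*k*X*K`;
* **complexes** — species composed of components with tracked,
  optionally range-restricted sites, and auto-generated
  complexation/decomplexation reactions using transfer of state.

Models are validated with severity-graded diagnostics and remain
representable — and saveable — while inconsistent; rename and delete
propagate under user-selectable policies (cascade, numeric replacement,
or deliberately leaving the inconsistency). A clean model is expanded
deterministically into the equivalent flat network and exported.

## Worked example

```r
library(flatreact)

m <- cdh1_toy(maxP = 10)     # the 11-form phosphorylation chain
flat <- expand_model(m)
model_stats(m, flat)
#> species:   2 compact -> 12 flat (reduction 83%)
#> reactions: 2 compact -> 20 flat (reduction 90%)

head(flat_reaction_table(flat), 3)
#>     name                         reaction         kinetic_law
#> 1 phos_1 Cdh1_p0 + ClbM -> Cdh1_p1 + ClbM kp * Cdh1_p0 * ClbM
#> 2 phos_2 Cdh1_p1 + ClbM -> Cdh1_p2 + ClbM kp * Cdh1_p1 * ClbM
#> 3 phos_3 Cdh1_p2 + ClbM -> Cdh1_p3 + ClbM kp * Cdh1_p2 * ClbM
```

The two collective reactions (phosphorylation by `succ` over `p{0:9}`,
dephosphorylation by `pred` over `p{1:10}`) expand to the 20
single-state reactions a modeler would otherwise write by hand; the
aggregate `Cdh1T := SUM(Cdh1;p{1:maxP})` grounds to the explicit
10-term assignment rule `Cdh1_p1 + ... + Cdh1_p10`. Rescaling the chain
is one edit — `expand_model(set_global_value(m, "maxP", 4))` gives 8
reactions over 5 forms with no other change.

Export:

```r
write_sbml(flat, "cdh1.xml")      # SBML L3V1; sbml_check(doc) reports no errors
write_tables(flat, "cdh1_tables") # species.csv / reactions.csv / parameters.csv
```

A command-line wrapper ships in `inst/cli/flatreact`:

```sh
flatreact validate model.msl        # JSON diagnostics, exit 1 on errors
flatreact expand   model.msl --out flat.msl
flatreact export   model.msl --format sbml --out model.xml
flatreact stats    model.msl
```

Other bundled fixtures: `xp_phosphorylation()` (ordered vs disordered
distributive multisite phosphorylation — switching mechanism changes
only the rate law), `translation_toy()` (ribosome translocation with a
moving-window aggregate modifier), `nonconsecutive_demo()` (symbolic
and nonconsecutive integer states: `succ(free) = bound`,
`succ(2) = 4`). Their `.msl` sources are in `inst/extdata/`.

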