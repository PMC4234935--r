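---
title: "Compact multistate models and their expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact multistate models and their expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatreact)
```

## The model of the language

A multistate species is one conceptual entity existing in many
distinguishable forms. Formally it is a name plus an ordered list of
sites; each site takes one value from an ordered, possibly circular,
list of states. A site with states `{0:10}` is the canonical
phosphorylation counter; states may equally be symbolic
(`{free,bound,hidden}`) or nonconsecutive integers (`{2,4,6,8,0}`,
encoding double-phosphorylation events in one step). The language
attaches no meaning to the values themselves — only the declared order
matters, and it defines the successor (`succ`) and predecessor (`pred`)
of every state. On a non-circular list the last state has no successor
and the first no predecessor; a circular list connects the ends.

A multistate reaction is a template: every reactant pattern admits a
set of states per site (a fixed state, an explicit subset, an integer
range, or — when unmentioned — the full list), and the template stands
for one single-state reaction per element of the cartesian product of
those sets. Products resolve per combination: fixed states verbatim,
carried-over states for a species that appears unchanged on both sides,
`succ`/`pred` of the matched reactant state, or a transfer of state
(`P1(c=succ(R.c))`) that copies — optionally through an operator — the
matched state of a named reactant. This is the whole semantics of the
compiler: `expand_model()` makes that correspondence explicit, and the
test suite checks it against an independent brute-force enumerator
that filters every full state combination through the patterns.

Two aggregate constructs complete the language. `SUM(S; site{lo:hi};
weight)` denotes the summed amount of a species over a state selection
and grounds to an explicit sum of flat species (each term multiplied by
the weight with the term's state value substituted, when a weight is
given). An *aggregate modifier* is a species whose site has no states
of its own and whose value is defined by an assignment over its own
site accessor, e.g. `M(c) := SUM(R;c{M.c+1:M.c+14})`; used as a
modifier with a transfer (`; M(c=R.c)`), it materializes as one
assignment-rule-bearing flat species per expanded instance — the moving
window of ribosome occupancy in the translation fixture.

Rate laws are either mass action (`MA : k`, the constant times the flat
reactant amounts) or a user-defined function with role-typed
parameters: `GLQ` arguments stay global references, `SUB` arguments
bind to the matched flat instance, and `SITE` arguments bind to the
*numeric* state value of the referenced site in that instance — which
is why a `SITE` argument over symbolic state labels is rejected. The
disordered multisite phosphorylation law `dis(GLQ N, SITE i, GLQ k,
SUB X, SUB K) = (N-i)*k*X*K` is the motivating example: one template,
N instantiated rates `(N-i)·k`.

## The text format

Multistate model editors are traditionally interactive spreadsheets
with one tab per block of the model; this package instead defines a
GUI-free, diffable serialization: a sectioned plain-text format
(`.msl`) with headers `[species]`, `[reactions]`, `[globals]`,
`[functions]`, `[complexes]`, `[initials]` playing the role of those
tabs. Species lines read
`definition = default_initial` (or `:= assignment` for assigned
species); globals use `=` for fixed and `:=` for assigned quantities;
reactions carry an optional `name :` prefix and an optional
`| MA : k` / `| UD : fn(...)` rate tag. `#` starts a comment.

Two syntax points had no established convention to follow and were
fixed here:

* **Circular state lists.** The circular flag needed a concrete
  written form; this package uses a trailing site marker,
  `p{0:10}~circ`.
* **SUM weights.** Per-term weight functions likewise needed a
  concrete form; this package uses a third segment,
  `SUM(species; restrictions; weight_expr)`, with the summed species'
  site accessors available inside the weight. Models written against a
  different weight syntax would need a one-line rewrite.

Identifiers admit a leading digit when the token is not a pure number,
because real models use names like `80S_aatRNA_eEF1A_GTP`; the
tokenizer therefore matches exponent-form numerals before identifiers.
Ranges are inclusive on both ends (`{0:10}` has 11 states — the eleven
forms of the worked phosphorylation chain). Whitespace inside patterns
is insignificant.

## Validation and the save-with-errors contract

Every model — including one that fails checks — remains representable
and saveable: a line that does not parse is kept verbatim in its
section (and re-emitted on save) with a recorded diagnostic, and
semantic problems become issues, never exceptions. Severities follow a
documented taxonomy, modeled on the error/warning split that
interactive editors present as cell colors: an undefined reference in an expression is an **error**;
an auto-created species is a **warning**; an empty expansion range is a
**warning** (the reaction simply contributes no instances). Structural
impossibilities — `succ` applied where a reactant range includes the
last state of a non-circular list, a transferred state outside the
target site's list, a role or arity mismatch, a statically
uncomputable range bound — are errors. `expand_model()` refuses to run
while error-severity issues are outstanding and lists them;
`validate()` itself is pure.

Autocompletion of species that are referenced but never defined is a
policy, not a behavior: `silent` creates them (default initial 0,
configurable) with a warning, `off` records a major-issue error and
creates nothing, `confirm` returns the pending names to the caller.
Deletion likewise: per class of reference the caller chooses between
cascading, substituting a numeric value, or deliberately leaving the
inconsistency for later. A numeric value can replace an entity inside
an expression but never as a reaction participant; that combination
falls back to leaving the inconsistency, with an issue saying so.
Renames propagate everywhere, and complexes with auto-maintained names
regenerate them when a component is renamed.

## Expansion: determinism and naming

Expansion is a pure function of the model text. Orderings are fixed
(species in declaration order, sites in declaration order with the
last site varying fastest, reaction instances in pattern order), so
two runs produce byte-identical SBML and CSV output.

Flat names follow `base_site1state1_site2state2...` in site
declaration order (`Cdh1_p3`, `S_s1free_s22`); characters outside
`[A-Za-z0-9_]` in state labels are replaced by `_`, and a name that
collides with an already-claimed different instance receives a numeric
suffix. SBML ids are additionally sanitized to the SId grammar
(`80S` becomes `_80S`) with the original kept as the display name.

Unconstrained sites of a multistate reactant iterate over their full
state list; a multistate species appearing on both sides with no
pattern change carries its state through (the multistate-catalyst
case). Non-integer values arising in range arithmetic are floored
before enumeration. An integer-range SUM restriction is intersected
with the state list rather than bounds-checked: this is what lets the
occupancy window slide past the end of the mRNA chain and simply
truncate, which the translation model requires near the 3' end; a
selection that ends up *empty* is still an error. A statically empty
reactant range (`lo > hi`) expands to zero reactions with a warning.

## Export

SBML output is Level 3 Version 1 core: one default compartment of size
1 (the language has no compartment concept), species with initial
amounts, fixed globals as constant parameters, SUM-derived quantities
and per-instance modifiers as assignment rules (their species are
flagged `boundaryCondition` so a rule may govern them), and each flat
reaction with its grounded kinetic law as explicit MathML — no
SBML-multi constructs. `sbml_check()` verifies the structural
constraints that matter for these documents (unique and well-formed
SIds, required attributes, resolvable species references and rule
variables, one rule per variable, no rules on constants, every `ci`
symbol defined); it is the package's own checker, written against the
L3V1 core rules, and every fixture's export must pass it with zero
errors. CSV export writes `species.csv`, `reactions.csv`,
`parameters.csv` (comma-separated, quoted where needed, UTF-8, header
row) with the flat reaction string and grounded formula as plain text.

## Fixtures: what they emulate, and what they do not

The bundled builders reconstruct the worked toy examples:
`cdh1_toy(maxP)` (the 2-reaction chain that expands to `2·maxP`
single-state reactions, 20 at the default), `xp_phosphorylation(N,
mechanism)` (ordered = mass action, disordered = the `dis` law; same
graph, different formulas), `translation_toy(length, d, window)` (the
transfer-of-state translocation step with the moving-window modifier),
and `nonconsecutive_demo()`. Rate constants and initial amounts in the
fixtures are plausible placeholders — the full kinetic
parameterizations of the published cell-cycle and translation models
are not reproduced here, and no simulation is attempted. Passing tests
therefore demonstrate the *compilation* semantics (counts, graph
structure, instantiated formulas, export validity) at toy scale, not
the biology of any particular parameterization. Full published models
of this kind (cell-cycle networks whose multistate encoding compacts
them roughly three-fold, 300-codon translation machinery with
thousands of flat reactions) are not bundled; the claims they embody
are covered instead by the closed-form count laws and the brute-force
equivalence property, which hold at every scale.

The width of the occupancy window is a plain parameter (default 14
codons of lookahead). Descriptions of ribosome-footprint windows vary
by one codon depending on whether the occupied codon itself is
counted; `translation_toy(window = 15)` reproduces the other reading.

The property-based suite generates random small models — up to 3
sites, up to 5 states per site, mixed integer ranges and (sometimes
circular) enumerated lists, random reactant patterns and product
resolutions — and compares the expander against an independent
brute-force enumerator on 100+ models per run, alongside the count-law
and operator-algebra properties. Test problem sizes (chains up to
maxP = 12, N up to 10, a 300-codon rescale) keep the default suite in
the tens of seconds while still exercising every construct.

## Known limitations

* No import from SBML or other exchange formats; `.msl` is the only
  input.
* No simulation: the exported SBML is the hand-off point to standard
  simulators.
* Complex components cannot themselves be complexes (nesting is
  rejected with a diagnostic); complexes are flattened species with
  tracked sites, not bond graphs.
* State transitions are limited to `succ`/`pred`; arbitrary jump
  functions are not supported (a progressive phosphorylation mechanism
  cannot be encoded directly).
* Generated complexation/decomplexation reactions need rate constants
  the declaration cannot express; fixed globals `<name>_kon` /
  `<name>_koff` (value 1) are auto-created for the modeler to adjust.
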