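---
title: "The CAZac activity descriptor: grammar, model and search semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CAZac activity descriptor: grammar, model and search semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazac)
```

## The descriptor

Carbohydrate-active enzymes that cleave or form glycosidic bonds —
glycoside hydrolases (GH), polysaccharide lyases (PL) and the lytic
polysaccharide monooxygenases (LPMOs) among the auxiliary activities
(AA) — are classified into sequence-based families, but their functions
are traditionally annotated only with EC numbers. The CAZac descriptor
replaces that flat annotation with a structured record built from two
kinds of parameters: family-level ones (catalytic mechanism, glycosidic
bond orientation) and enzyme-level ones (the substrate/product subsites,
their connecting bonds, and the reactant).

Each activity line holds eight descriptor fields — four subsites (-2,
-1, +1, +2, numbered across the point of cleavage; cleavage occurs
between -1 and +1), the three interconnecting bonds, and the reactant —
plus the activity ID, EC number, activity name, family list and CAZy
class. The -1 subsite is strictly carbohydrate: it names the reaction for
GHs, while for PLs the residue undergoing catalysis sits at +1. The bond
between -1 and +1 is the *reacting bond*, the one cleaved or created.

### Mechanisms and orientation

Koshland mechanisms conserve (retaining) or invert (inverting) the
anomeric configuration at the -1 carbon; GH97 harbors both; the
NAD-dependent families (GH4, GH109, GH177, GH179, GH188) and the
unsaturated-substrate families (GH88, GH105) are grouped as "other",
which always carries both bond orientations; "unknown" covers families
whose mechanism is not yet established. PLs eliminate (β-elimination) and
LPMOs act as peroxygenases; neither carries an orientation. Orientation
is written *a*/*e* (axial/equatorial) rather than α/β because it is then
independent of the D/L series: β-D-glucosides and α-L-arabinosides both
have equatorial bonds. An "(inferred)" marker records a mechanism
assigned by analogy rather than experiment; the search engine ignores it
when matching.

### The residue grammar

```{r residues}
parse_residue("bDGalpNAc_4S")        # N-acetyl galactosamine 4-sulfate
parse_residue("(aDXylp-1,6)bDGlcp")  # xyloglucan subsite
parse_residue("[(aDGlcp)3")          # three glucoses beyond the last subsite
parse_residue("DGlcp]")              # free reducing glucose, anomer unresolved
```

The grammar is case-sensitive: anomer `a`/`b` lowercase, stereo `D`/`L`
uppercase, a three-letter title-case sugar code, ring `p`/`f`. Common
modifications (default whitelist `NAc`, `N`, `A`, configurable via
`options(cazac.common_mods = )` since no exhaustive list exists) are
appended directly; all other modifications name the carbon after an
underscore (`_6P`). Side chains precede the backbone parenthetically with
their linkage; parenthesized units with a trailing count denote repeats
extending past the outer subsites; `(cyclic)` marks cyclic glycans; `[`
and `]` mark the last occupiable subsite toward the non-reducing and
reducing end — the notation that distinguishes exo- from endo-acting
enzymes. Anything that cannot open a monosaccharide is kept verbatim as
an aglycon label (`alcohol` for pNP-type assay substrates or unresolved
positive subsites, or a physiological aglycon such as `Mandelonitrile`);
text that *starts* like a monosaccharide but breaks the grammar is a
parse error naming the offending character, so typos do not silently
become aglycons. The -1 subsite additionally must be a saccharide, which
the validator enforces.

Rendering is canonical: repeats print as `(aDGlcp)3` (the running-text
spelling `(aDGlcp)_3_` is accepted on input), positioned modifications
sort by carbon, bond alternatives sort ascending, and
`parse(render(x)) == x` holds structurally for every valid value — the
property suite fuzzes this over ten thousand generated residues.

### Bonds and reactants

Bonds name the linked carbons donor-first (`1,4`), allow disjunctive
alternatives (`1,3/4`) and the wildcard `X` for unspecified positions
(`1,X`, typically toward an aglycon). For LPMOs the oxidized carbon of
the cleavage carries an `o`: `1o,4` for C1, `1,4o` for C4 oxidation; the
validator requires exactly one such mark on an oxidase reacting bond.
The reactant couples to the activity class: water for H, hydrogen
peroxide for O, none for L, inorganic phosphate with its ring
orientation (`aPi`/`ePi`) for phosphorylases, and for
transglycosylases/mutases the leaving part of the donor together with
the anomer and linkage of the cleaved donor bond (amylosucrase:
`a-1,2-bDFruf]`).

Two advisory lints are reported as warnings, not violations: nested side
chains (the grammar permits one level, but no curated record exercises
it) and phosphorylase orientation (the phosphate is expected to keep the
-1 anomer orientation under retention and flip it under inversion, as
starch phosphorylase `aPi`/retaining and maltose phosphorylase
`ePi`/inverting illustrate).

### Exclusions

Four EC numbers — 4.2.1.179 and 4.2.2.16/17/18, the difructose
dianhydride lyases — describe a cleavage followed by condensation to a
cyclic disaccharide. A single eight-field record cannot hold two
sequential reactions, so the validator flags these ECs
(`excluded-difructose-dianhydride`) instead of modelling them.

## Search semantics

A query needs at least a residue, an EC number or a family; every other
field is additive — each one set can only restrict the result. The
residue is matched against the line's reacting-side subsite (-1 for
GH/AA, +1 for PL). Non-strict matching compares only the backbone core,
so `bDGalp` retrieves all its variants; the `strict` option requires
full structural equality including boundary markers, which is how
`[aDGlcp` isolates the exo-acting activities. EC matching is exact field
equality — an incomplete EC such as `3.2.1.-` is a distinct value, not a
prefix wildcard, because incomplete ECs denote distinct not-yet-
classified activities. Bond matching treats record alternatives
disjunctively, lets `X` match anything, and considers oxidation marks
only when the query carries one. Results preserve dataset order, one row
per activity ID × mechanism.

```{r search}
ds <- load_fixture()
endo <- run_query(ds, cazac_query(cazy_class = "GH", residue = "aDGlcp",
                                  strict = TRUE, reac_bond = "1,4"))
summarize_results(endo)
tidy(summarize_results(endo))
```

The bundled table covers α-1,4-glucan chemistry: 18 endo-acting lines
(17 activity IDs — the endo-α-1,4-glucosidase H1 appears once retaining
and once inverting-inferred), 8 exo-acting lines (7 IDs, the
exo-α-1,4-glucosidase H3 duplicated for GH15 vs GH97), and the three
mechanism lines of the α-galactosidase function EC 3.2.1.22. For those
three lines only the mechanisms and family sets are curated data; the
subsite fields (`[aDGalp`, `1,X`, `alcohol`, H2O) and the activity-ID
number H500 are synthetic placeholders chosen here so the lines validate
— they are never treated as reference values beyond their count,
mechanisms and families.

## The generators

`gen_residue()`, `gen_dataset()` and `gen_query()` draw random notation
values and activity tables for property testing. Every grammar feature
has nonzero default probability — modifications 0.3 (split between
common and positioned), boundary markers 0.25, repeats 0.15, cyclic 0.1,
at most one side chain, anomer-less reducing units 0.07, plus bond
wildcards and oxidation marks — values chosen once as a realistic
notation mix rather than estimates of any curated distribution; an
8-sugar pool and 50-line datasets keep draws small and fast. Class
letters, EC prefixes, reactants and oxidation marks are drawn jointly so
generated lines satisfy the class/reactant correspondences by
construction; generated data are syntactically valid, not biochemically
meaningful. What passing property tests show is therefore grammatical
and semantic soundness (round-trip stability, validator totality, search
equal to a brute-force per-field scan, additivity, strict ⊆ non-strict)
— not fidelity to the real distribution of curated CAZy records, which
is represented only by the bundled table.

## Numerical and design choices

* Equality of parsed values is structural; strict residue matching uses
  canonical-render equality, which is equivalent because rendering is
  injective on canonical structures.
* Parsing is memoised per session: activity tables repeat a small set of
  notation strings, so each distinct cell parses once.
* The grammar permits one level of side-chain nesting (flagged
  "unverified depth"); deeper nesting is a parse error.
* Whether non-strict matching should also relax D/L stereochemistry or
  ring form is unresolved upstream; this implementation requires core
  equality and treats only the query's unspecified anomer as a relaxer.
* Residue queries against AA records consult subsite -1, like GH.
* Activity-ID numbers are opaque curator identifiers; the package never
  invents or renumbers them (the synthetic H500 above is data, not code).
* Problem sizes in the test suite — 10^4 residue draws for round-trip
  fuzzing, 1,000 (query, dataset) pairs at 30 lines each for oracle
  equivalence — were chosen as the package's own coverage targets; the
  whole suite runs in well under two minutes on one CPU.

## Limitations

* Glycosyltransferase (GT) records are out of scope; the transferase
  class currently covers phosphorylases and transglycosylases only.
* No conversion to or from other glycan formats (GlycoCT, WURCS, IUPAC
  condensed) and no SNFG graphics.
* The sugar-code and modification-code vocabularies are open: the parser
  accepts any well-formed three-letter code, so it cannot catch a
  misspelled sugar that is still grammatical.
* Search is a filter, not a ranker: no free-text search over names, no
  scoring.
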