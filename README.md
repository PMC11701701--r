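# cazac

Parse, validate and search CAZac activity descriptors for
carbohydrate-active enzymes.

## The problem

The CAZy classification groups carbohydrate-active enzymes (CAZymes) into
sequence-based families, and annotates their functions with Enzyme
Commission (EC) numbers. EC numbers are a flat list: the fourth digit
carries no structure, the catalytic mechanism is usually unstated, and the
same chemical event — say, cleavage of an α-1,4 bond between two glucose
units — is scattered over more than ten EC entries. The CAZac activity
descriptor fixes this by describing each activity with a small set of
searchable fields:

* **mechanism** — retaining / inverting (the Koshland mechanisms, by
  anomeric outcome at the -1 carbon), both (GH97), other (NAD-dependent and
  unsaturated-substrate families), unknown, β-elimination (lyases) or
  peroxygenase (LPMOs), with the glycosidic bond orientation written *a*
  (axial) or *e* (equatorial) so it is independent of D/L stereochemistry;
* **four subsites** (-2, -1, +1, +2) around the point of cleavage, each
  holding a monosaccharide in a compact grammar (`bDGlcp` =
  β-D-glucopyranose, `bDGlcpNAc`, `bDGalpNAc_4S`, side chains
  `(aDXylp-1,6)bDGlcp`, repeats `(aDGlcp)3`, chain-end markers `[`/`]`),
  an aglycon label, or nothing;
* **three bonds** — the linked carbons (`1,4`, alternatives `1,3/4`,
  wildcard `1,X`, LPMO oxidation marks `1o,4` / `1,4o`), the middle one
  being the reacting bond;
* **reactant** — H2O (hydrolases), H2O2 (LPMOs), none (lyases), `aPi`/`ePi`
  (phosphorylases), or the leaving group of the donor
  (transglycosylases/mutases, e.g. `a-1,2-bDFruf]` for sucrose donors);
* an **activity ID** (H/T/L/M/O + number) and the EC number it maps to
  (3.2.1 → H, 2.4.1/2/3/99 → T, 4.2.2 → L, 5.4.99 → M, 1.14.99 → O).

This package implements the full grammar (parsers and canonical
renderers), the eight-field record model with EC mapping and a validator,
a fixed TSV dialect with a bundled starch-chemistry table, the search
engine with strict/non-strict residue matching, seeded generators for
property testing, and a command-line interface. It is aimed at
glycoscientists and database curators who want to query activity records
the way the CAZy "CAZac search" does, offline and scriptably.

## Worked example: enzymes acting on the α-1,4 glucose bond

Starch chemistry is the classic worked example: searching class GH with
reacting bond `1,4` and strict -1 residue `aDGlcp` retrieves every
endo-acting activity on the α-1,4 glucan backbone.

```r
library(cazac)

ds <- load_fixture()           # 29-line bundled activity table
endo <- run_query(ds, cazac_query(cazy_class = "GH", residue = "aDGlcp",
                                  strict = TRUE, reac_bond = "1,4"))
summarize_results(endo)
#> <cazac_summary>
#>   lines:              18
#>   distinct activities: 17
#>   by class letter:    H=13, T=4
#>   by role:            hydrolase=13, phosphorylase=1, transglycosylase=3
#>   families (8): GH119, GH13, GH57, GH126, GH14, GH49, GH87, GH77
```

Seventeen activity IDs across eight GH families act on the
`aDGlcp-1,4` bond: thirteen hydrolases, one phosphorylase (T292) and
three transglycosylases (T309, T311, T338). The family breakdown shows
GH13 dominating with 13 of the 17 activities:

```r
tidy(summarize_results(endo))
#> # A tibble: 8 × 2
#>   family n_activities
#>   <chr>         <int>
#> 1 GH13             13
#> 2 GH57              4
#> 3 GH49              2
#> 4 GH119             1
#> ...
```

Adding a `[` before the -1 residue (`"[aDGlcp"`, strict) switches the
search to exo-acting enzymes — 7 further activities, among them the
lyase L345 and maltose phosphorylase T265 — and `cazac_query(ec =
"3.2.1.22")` returns the three mechanism lines of the α-galactosidase
function (retaining *a* in GH27/GH31/GH36/GH57, other *a,e* in GH4,
inverting and retaining *a* in GH97). `glance()` and `autoplot()` give
one-row summaries and family bar charts of any result.

The same searches run from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cazac.R", package = "cazac"))')
Rscript $CLI search --class GH --residue aDGlcp --strict --reac-bond 1,4
Rscript $CLI parse residue "bDGalpNAc_4S"
Rscript $CLI validate my_activities.tsv
Rscript $CLI gen --seed 7 --n 50 --out random.tsv
```

## File formats

Activity tables are UTF-8 TSV with a fixed header
(`activity_id, ec, name, mechanism, res_m2, bond_m1, res_m1, reac_bond,
res_p1, bond_p1, res_p2, reactant, families, cazy_class`), one line per
activity ID × mechanism, families comma-separated, empty cells empty.
`activity_table_json()` exports the same fields one-to-one as JSON. See
the vignette (`vignettes/cazac.Rmd`) for the grammar, matching semantics
and design notes.
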