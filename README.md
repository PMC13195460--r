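# tpnet

Transformation-product reaction networks for suspect screening.

Transformation products (TPs) — the compounds that parent chemicals turn
into through metabolism, environmental degradation or water treatment —
are chronically under-annotated in nontarget mass-spectrometry studies.
Community datasets now report thousands of predecessor → successor
reaction pairs, but each row shows only a single step, while real
degradation pathways span many steps and many datasets. `tpnet` turns
such tables into a queryable directed reaction network for environmental
chemists and suspect-screening practitioners.

## What it does

- **Ingest** the two-table CSV schema used by compiled transformation
  collections: a compound table (CID, SMILES, InChI/InChIKey/IKFB,
  formula, monoisotopic mass, XlogP, names) and a reaction table
  (predecessor/successor CIDs and names, reaction SMILES, biosystem,
  enzyme, mass and XlogP differences, dataset/evidence/source
  provenance). Rows with unparseable CIDs are skipped with a report,
  never silently.
- **Normalize names** with a majority-vote rule: candidate names are
  collected from the compound table and every reaction-row mention,
  then ranked by frequency of mention, then by length (shorter common
  names beat systematic ones — "6:2 FTOH" rather than
  "3,3,4,4,5,5,6,6,7,7,8,8,8-Tridecafluorooctan-1-ol"). Names longer
  than 100 characters or containing more than 20 special characters are
  replaced by `CID <n>` for display; all names are kept for search.
- **Build a directed multigraph**: compounds are nodes, every reaction
  row is a directed edge, parallel edges are retained as independent
  evidence, and edges referencing unknown CIDs are quarantined.
- **Query** it: all equally short directed pathways between two
  compounds; direct-neighbor / predecessor-path / successor-path /
  all-connections views; exact identifier and case-insensitive name
  lookup (single or batch), with an optional biosystem restriction; and
  SMARTS substructure screening (single patterns or batch files)
  through Open Babel.
- **Filter displays**: reactions where a sub-60 Da precursor (CO2,
  formaldehyde, acetate...) forms a product above 300 Da act as data
  hubs that weld unrelated pathway islands together; they are hidden
  from pathway search and compound views by default, always listed by
  `hidden_edges()`, and never removed from the data.
- **Compute statistics**: node roles (predecessor-only / successor-only
  / both / isolated), hub compounds by distinct reaction partners,
  per-dataset reaction-pair uniqueness, mass-difference distributions
  and mass-vs-XlogP pairs, multistep-pathway counts, component sizes.
- **Export suspect lists**: MetFrag
  (`Identifier, Name, InChIKey, InChI, SMILES, MolecularFormula,
  MonoisotopicMass`) and patRoon
  (`Name, InChI, SMILES, Formula, ExactMass`) formats, plus generic
  CSV/XLSX.

A deterministic synthetic-table generator (`fixture_spec()` /
`generate_fixture()`) produces schema-conformant datasets with known
ground truth (roles, unique pairs, probe path lengths, injected
filter-target edges), so the whole stack is testable offline.

## Worked example

```r
library(tpnet)

fx <- generate_fixture(fixture_spec(seed = 42))
compounds <- normalize_compounds(fx$compounds, fx$reactions)
g <- build_graph(compounds, fx$reactions)

tp_summary(g)
#> <tp_stats>
#>   compounds: 60   reactions: 139
#>   roles: 10 predecessor-only, 5 successor-only, 45 both, 0 isolated
#>   degree: 0 compounds with >=10 distinct TPs, 0 with >10 distinct predecessors
#>   multistep: 33 compounds >=2 steps from an original predecessor (100% spanning >=2 datasets)
#>   hidden by display filter: 2 reactions
```

Ten compounds only ever appear as parents, five only as TPs, and 33
compounds sit two or more reaction steps away from every "original
predecessor" (a compound with no documented precursor) — the multistep
pathways a single-step table cannot show. Two reactions are hidden by
the display filter, and they are exactly the injected small → large
edges:

```r
hidden_edges(g)[, c("predecessor_name", "predecessor_mass",
                    "successor_name", "successor_mass")]
#>       predecessor_name predecessor_mass successor_name successor_mass
#> 1 carbon dioxide #1001         43.98983 6:2 FTOH #1003       364.0133
#> 2   formaldehyde #1002         30.01056     PFOA #1004       413.9737
```

Pathway search enumerates every equally short directed route:

```r
shortest_pathways(g, 1009, 1012, filter = edge_filter(enabled = FALSE))
#> <tp_pathways> 1009 -> 1012
#>   2 shortest pathway(s) of 2 step(s)
#>    1009 -> 1010 -> 1012
#>    1009 -> 1011 -> 1012
```

SMARTS screening finds all CF3-containing (PFAS-type) compounds, and a
selection exports directly as a MetFrag suspect list:

```r
res <- substructure_search(g, c(CF3 = "C(F)(F)F"))
head(res, 3)
#>    cid matched_labels
#> 1 1003            CF3
#> 2 1004            CF3
#> 3 1013            CF3

write_export(compounds[compounds$cid %in% res$cid, ], "metfrag")
#> <tp_export> format: metfrag - 6 rows
#>   columns: Identifier, Name, InChIKey, InChI, SMILES, MolecularFormula, MonoisotopicMass
```

## Command line

A thin shell entry point wraps the same functions:

```sh
TPNET_CLI=$(Rscript -e 'cat(system.file("cli", "tpnet", package = "tpnet"))')
Rscript "$TPNET_CLI" ingest --compounds Transformations_CID_Info_all.csv \
    --reactions PubChem_all_transformations_wExtraInfo.csv --out cache/
Rscript "$TPNET_CLI" query path --graph cache/graph.json --source 2256 --target 135398733
Rscript "$TPNET_CLI" stats --graph cache/graph.json --out stats.json
Rscript "$TPNET_CLI" export --graph cache/graph.json --format metfrag --out suspects.csv
```

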