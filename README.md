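# chemcheck

Batch validation and standardization of chemical structure records.

Public chemistry databases aggregate millions of depositor-supplied
structures, and the files behind them are riddled with depiction problems
that silently corrupt identifiers downstream: query atoms left in
connection tables, impossible valences, wedge bonds on atoms that are not
stereocenters, aromatic rings whose hydrogens cannot be restored, salts
drawn with the wrong proton removed, sugar rings drawn in perspective (which
InChI cannot interpret) or accidentally mirrored into the L series, and
SMILES/InChI annotations that do not match the connection table they
accompany. `chemcheck` validates each record of a MOL/SDF/SMILES file
against these checks, assigns every finding one of three severities —
**Information**, **Warning**, **Error** — and aggregates a filterable JSON
report, so a data curator can review exactly the subset that needs eyes.

It is aimed at database curators and cheminformaticians preparing structure
collections for deposition or exchange.

## What it checks

The connection table is treated as the primary structure source; everything
else is validated against it.

* **Atoms, bonds, valences** — query atoms/bonds; drawn valences judged
  against a data-driven model of common and uncommon valences per
  (element, charge): uncommon states (e.g. nitro drawn as pentavalent
  `N(=O)=O`) warn, impossible ones error.
* **Dearomatization** — a record drawn with aromatic-type bonds must admit
  exactly *one* hydrogen placement consistent with a Kekulé structure;
  imidazole drawn fully aromatic with no ring NH admits two, so its
  hydrogens cannot be restored (Error).
* **Wedge/hash stereo battery** — wedges on non-stereocenters, wedges whose
  narrow end is at the wrong atom, two like wedges in adjacent positions, an
  up and a down wedge nearly opposite, stereo-bond angles below a threshold,
  and implicit-hydrogen ambiguity (all three explicit bonds of a center in
  one half-plane). Potential stereocenters come from symmetry-aware
  substituent-distinctness analysis (iterative-refinement atom classes).
* **Undefined stereo** — records are classified by their (defined,
  undefined) stereocenter counts into *epimers*, *partially undefined
  mixtures*, *enantiomers* or *completely undefined mixtures*; wedges
  without the molfile chiral flag warn as relative stereo.
* **Dictionary rules** — user-editable XML of SMARTS tests (single, AND-ed
  or OR-ed) with per-rule severity. Element-class abbreviations such as
  `{Hal}`, `{M}`, `{NM}` expand at load time. The default set flags small
  fragments (methane/ammonia/water/S/B), adjacent like charges,
  metal–non-metal / metal–N / metal–O bonds, enols, non-1H-tetrazoles,
  `N=C-OH`, azides drawn `N#N=N`, free carbon monoxide, multiple radical
  centers and non-zero net charge.
* **Competitive ionization** — a ranked acid/base table (33 groups; smaller
  rank = more acidic) detects partially ionized systems in which a weaker
  acid lost its proton before a stronger one, and an opt-in standardizer
  moves protons one at a time until the ionization state is canonical,
  conserving net charge and molecular formula.
* **Ring-walking shape classification** — walking an unfused six-membered
  ring's 2D depiction and recording a left/right turn at each node gives a
  six-character signature; under rotation and L↔R complement the 64
  signatures fall into exactly 8 classes (chair, boat, twist-boat,
  half-chair, homotropous and three unnamed ones). Non-convex
  (chair/boat "perspective") pyranose depictions, Haworth projections and
  mirrored L-pyranose rings are flagged.
* **Cross-validation** — the standard InChI is generated from every
  connection table; mapped SDF fields (`REGID`, `SMILES`, `InChI`) are
  compared through it, and duplicate fragments are grouped by InChI.

SMARTS matching, SMILES parsing and standard-InChI generation are delegated
to RDKit through a bundled Python helper (`inst/python/chem_backend.py`);
the system requirement is a `python`/`python3` on the PATH that can
`import rdkit`.

## Worked example

Validate three records: 4-hydroxybenzoate drawn with a neutral carboxylic
acid but an ionized phenol, a wedged stereocenter without the chiral flag,
and propen-2-ol.

```r
library(chemcheck)

records <- list(
  parse_molfile(make_fixture("strongest_acid_not_ionized_first")$molfile, 1),
  parse_molfile(make_fixture("relative_stereo")$molfile, 2),
  parse_molfile(make_fixture("contains_enol")$molfile, 3)
)
report <- build_report(records)
report
#> <chem_report> 3 records, 3 with issues
#>   Information  contains_enol                        1
#>   Information  net_charge_nonzero                   1
#>   Warning      relative_stereo                      1
#>   Information  strongest_acid_not_ionized_first     1

for (iss in report$entries[[1]]$issues) print(iss)
#> [Information] net_charge_nonzero: Overall charge is non-zero (net charge -1)
#> [Information] strongest_acid_not_ionized_first: Strongest acid not ionized
#>   first in partially-ionized system (neutral CO2H (rank 70) vs ionized
#>   Arom-OH (rank 170)) atoms 4,7,8,9,10
```

The first record violates competitive ionization: the carboxylic acid
(rank 70, more acidic) is still neutral while the phenol (rank 170) is
ionized. Reprotonation moves the proton from the carboxyl to the phenolate:

```r
fixed <- reprotonate_to_canonical(records[[1]])
assign_ionization_state(fixed$record)
#> <ionization state>
#>   CO2H                   rank  70  base  proton atom 9
#>   Arom-OH                rank 170  acid  proton atom 10
```

Now the carboxylate is the ionized form and the phenol is neutral; net
charge and molecular formula are unchanged.

Filtering and export mirror the review workflow:

```r
errors_only <- filter_report(report, severities = "Error")
report_to_json(report, "report.json")
```

## Command line

```sh
inst/cli/chemcheck validate in.sdf --map DB_ID=REGID --out report.json \
    --filter-severity Error --export errors.sdf
inst/cli/chemcheck standardize in.sdf --out standardized_report.json
inst/cli/chemcheck fixtures --out fixtures/   # dump the built-in test suite
```

Gzip/zip-compressed inputs are decompressed transparently. Exit status: 0
success, 1 usage error, 2 unreadable input.

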