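---
title: "How chemcheck validates structure records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How chemcheck validates structure records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chemcheck` validates chemical structure records one at a time, treating the
connection table as the primary source of structural truth and every other
annotation (mapped SMILES, mapped InChI) as secondary. This vignette
explains each check's model and assumptions, the tunable parameters and
their defaults, the design decisions that were genuinely open, and what the
built-in fixture suite does and does not demonstrate.

## The record model

A record is the parsed V2000 connection table plus its SDF data fields.
Parsing is deliberately non-normalizing: query atoms, impossible valences
and contradictory wedges all survive into the record, because they are the
subject of validation, not noise to be repaired. Only structural corruption
(a malformed counts line, truncated blocks) is a parse error, and inside an
SDF stream it is confined to its own record — one corrupt entry yields one
record-level Error and never suppresses its neighbors. V3000 tables are
rejected with a clear message rather than misread. `M  ISO` isotope lines
are parsed and preserved, but no shipped rule consumes isotopes.

Charge bookkeeping follows the V2000 convention that the first `M  CHG`
(`M  RAD`) property line supersedes *all* atom-block charge (radical)
codes. A record counts as 3D when any |z| exceeds `z_3d_threshold`
(default 1e-4 coordinate units — drawing programs emit tiny non-zero z
values that do not indicate real 3D content).

## Severities and the issue registry

Every finding carries one of exactly three severities — Information,
Warning, Error — and a stable snake_case code from `issue_registry()`.
Codes are this package's own identifiers; the registry also records which
codes the fixture generator can trigger deliberately (all but the two
internal-fault codes `internal_check_error` and `reprotonation_failed`,
which only arise when a check itself fails).

## Valence model

The drawn valence of an atom is its bond-order sum plus its radical
electron count, filled with implicit hydrogens up to the smallest *common*
valence for its (element, charge) — the MDL implicit-hydrogen convention.
If no common valence accommodates the drawn bonds, no hydrogens are added
and the raw sum is judged: a value in the *uncommon* set is a Warning
(`unusual_valence`; e.g. neutral N at valence 5, as in nitro drawn
`N(=O)=O`), anything else an Error (`bad_valence`). The sets live in
`inst/extdata/valences.yaml`, seeded from the MDL default-valence
conventions for the organic subset; elements or charge states absent from
the file are not checked, which is the honest choice for metals whose
bonding the molfile model does not capture. Atoms in aromatic systems are
only checked when the dearomatization step (below) produced a unique
Kekulé assignment, whose bond orders are then used.

## Dearomatization

A record drawn with aromatic-type (4) bonds is only interpretable if the
implicit hydrogens on its ring heteroatoms can be restored uniquely. Each
aromatic atom is assigned a role: carbons must take exactly one ring double
bond; neutral O/S and N drawn with an exocyclic substituent or explicit H
are saturated (no ring double bond); bare neutral ring nitrogens are
*flexible* — pyridine-like (double bond) or pyrrole-like (takes the H).
The check enumerates all flexible-nitrogen assignments and tests each for a
perfect matching of ring double bonds: zero feasible assignments is
`dearomatization_failed`, two or more is `dearomatization_not_unique`
(imidazole with no ring NH is the canonical case: the H can sit on either
nitrogen). Enumeration is capped at `dearomatization_cap` (default 4096)
hydrogen placements; a system that large is reported as ambiguous with a
note, since no drawing that size should rely on implicit aromatic
hydrogens anyway. The test suite checks the role/matching analysis against
a brute-force enumerator over all hydrogen placements × all edge subsets
on ring systems up to 10 atoms.

## Stereochemistry

Potential tetrahedral stereocenters are found by symmetry-aware
substituent-distinctness analysis: atom equivalence classes are computed by
iterative (Morgan-style) refinement from (element, charge, radical, degree,
bond-order sum, implicit H count), and an sp3 atom with four substituents
in four distinct classes (implicit H counting as one) is potential. This
refinement can in principle merge classes that a full automorphism
computation would separate; at the molecule sizes this package targets it
agrees with an independent perception (checked in the test suite against
RDKit's chiral-center finder).

Wedge interpretation runs only on 2D records — a 3D record gets a
`contains_3d` Information flag and skips the battery, since wedges have no
defined meaning on 3D coordinates. The geometric rules, all on the drawn
bond directions at a center, with their defaults:

* two stereo bonds subtending less than `stereo_min_angle` (15°) —
  `stereo_bond_angle_too_small`. Severity is configurable
  (`angle_rule_severity`, default Warning) because the finding sits on the
  boundary between cosmetic and fatal; we default to the lenient reading.
* two like wedges closer than `stereo_opposite_angle` (150°) —
  `two_same_wedges_at_center` (Error). Two like wedges drawn nearly
  opposite are geometrically consistent and not flagged.
* an up and a down wedge at 150° or more —
  `up_and_down_at_center` (Error). A mixed pair drawn adjacent is how
  chairs are legitimately annotated, so it is not flagged.
* a stereocenter with an implicit hydrogen whose three explicit bonds all
  lie in one half-plane (largest angular gap > 180°) —
  `implicit_h_near_stereocenter` (Error): the implied H position, and with
  it the parity, is ambiguous.
* a wedge joining two stereocenters — `stereo_bond_direction_nonsense`;
  narrow end at a plain atom but wide end at a stereocenter —
  `wedge_points_at_stereocenter`; both ends plain —
  `wedge_on_non_stereocenter` (all Errors).

A center is *defined* when a wedge has its narrow end there and no Error
from the battery touches it; an either-type stereo bond marks it *unknown*.
With `d` defined and `u` undefined-or-unknown centers the record is
classified: `d≥1,u=1` epimers; `d≥1,u≥2` partially undefined mixtures;
`d=0,u=1` enantiomers; `d=0,u≥2` completely undefined mixtures. The
mixtures/enantiomers boundary is taken at `u≥2`; reading the
completely-undefined-mixtures clause as "at least one undefined" would make
the enantiomers class unreachable. Any up/down wedge without the molfile
chiral flag is `relative_stereo` (Warning); crossed double bonds and stereo
bonds inside rings are Information flags.

## Dictionary rules

Validation rules are XML: a severity element (`Error`/`Warning`/
`Information`) with `message` and `description` attributes containing
`test` elements whose `name` must be `SMARTStest` and whose `param` is the
SMARTS; `<and>`/`<or>` wrappers combine tests, multiple bare tests mean OR.
Element-class abbreviations (`{Hal}`, `{Pn}`, `{M}`, `{NM}`, `{TM}`,
`{TM^Hg}`, `{M_V6}`, `{M_+1}`) expand at load time from
`inst/extdata/abbreviations.yaml` into atomic-number alternations, so they
match aromatic and aliphatic atoms alike. `{M}` is defined as every element
outside the non-metal list *and* outside {C, H} — the literal complement
would make hydrogen a metal. A rule firing several times on a record
yields one issue carrying all match locants, because reports count
affected records, not matches.

Patterns are matched against the aromaticity-perceived form of the
connection table, with two deliberate deviations from full normalization:
the valence check is disabled (records under validation are often
deliberately invalid) and hypervalent-nitrogen cleanup is disabled, so
azide drawn `N#N=N` and nitro drawn `N(=O)=O` are matched *as drawn* —
which is exactly what the azide dictionary rule looks for.

Two default checks are not expressible in SMARTS (which has no net-charge
or radical-count primitive): more-than-one-radical and non-zero net charge
are built-in structural checks attached to the default rule set. The
shipped SMARTS of the default dictionary are best-effort reconstructions
from the rule names and are commented as such in `default_rules.xml`.

## Competitive ionization

`inst/extdata/fda_acid_groups.xml` ships 33 ranked acid/base pairs
(rank 10–330, smaller = more acidic), each with acid-form and base-form
SMARTS and atom-mapped SMIRKS. Overlapping matches are resolved by keeping
the lowest-rank match per atom set (ties: acid form first, then first atom
index), so retained matches are disjoint. A record violates competitive
ionization when some neutral acid outranks (has smaller rank than) some
ionized base — the strongest acid was not ionized first. Equal ranks never
violate. By default the whole record is examined; `per_fragment_ionization`
restricts comparisons to within each fragment for salt-like inputs.

Standardization (opt-in, `standardize = TRUE` or the CLI's
`--standardize reprotonate`) repeatedly moves one proton: the highest-rank
ionized group is reprotonated and the lowest-rank neutral acid
deprotonated. Each move strictly decreases the sum of ionized ranks, so the
loop terminates at the canonical state — the one that ionizes the
lowest-rank groups, which the test suite verifies against a brute-force
optimum on randomly generated polyprotic molecules. The proton move itself
is applied as a formal-charge flip at the acid/base-differing atom of the
group (located by diffing the two SMARTS' charge queries); this conserves
net charge, heavy atoms and molecular formula exactly and leaves atom
numbering and wedges untouched. The shipped SMIRKS are validated at load
time and document the transforms; three typographic repairs to the source
table are listed in the file header.

## Ring-walking shape classification

Walking an unfused six-membered ring (no bond shared with another ring) in
depiction order and taking the sign of the planar cross product at each
node gives a six-letter L/R signature. A cross product within
`collinear_tol` (relative, default 1e-3) of zero means three near-collinear
nodes: the signature is undefined and the ring is not classified. Rotation
(start node) and letterwise complement (walk direction, mirroring) are
symmetries, and brute-force enumeration of all 64 signatures yields exactly
8 classes: homotropous (all turns equal — the convex depiction), chair,
boat, twist-boat, half-chair, and three classes with no common name, which
we label by their lexicographically smallest members (`unnamed_LRLRLR`,
`unnamed_LRLRRR`, `unnamed_LLLLRR`). The published signature table prints
one signature pair twice under two rows; enumeration resolves the eighth
class unambiguously.

A non-homotropous pyranose candidate (exactly one ring oxygen) is a
"perspective" depiction — the chair/boat drawings that identifier
algorithms cannot interpret — and is flagged as Information. A homotropous
pyranose candidate with two long near-horizontal edges (length ≥
`haworth_edge_ratio` = 1.5 × the shortest edge) and at least two
near-vertical exocyclic bonds (within `haworth_axis_angle` = 20° of the
axis) is flagged as a Haworth projection. These two thresholds are
heuristics invented here (no published criteria exist) and are exposed in
the configuration.

L-pyranose detection targets the common accident of mirroring a sugar
ring: for a pyranose candidate with at least three exocyclic oxygens the
reference carbon is the ring carbon adjacent to the ring oxygen bearing an
exocyclic carbon (C5 of an aldohexopyranose). Its configuration is read
from the wedge geometry under the fixed priority order ring-O > ring-C >
exocyclic-C > implicit-H, which coincides with the CIP order for the
common sugars; the parity corresponding to L is flagged. Rings whose
reference carbon carries no wedge are left alone — guessing would be worse
than silence. The sign convention is pinned against an independent CIP
assignment in the test suite, and mirroring the x coordinates provably
flips the outcome. For unusual substitution patterns where the fixed
priority order departs from CIP, the call may differ from a full CIP
treatment; this is a known limitation.

## Cross-validation

The standard InChI (prefix `InChI=1S/`) is generated from every record's
connection table; the generating software version is recorded in the
report header since InChIs are version-dependent. Records with query
atoms/bonds get `inchi_generation_failed` instead. A mapped SMILES is
parsed, converted to InChI and compared full-string; a mapped InChI is
compared after whitespace trimming, with non-standard prefixes
(`InChI=1/`) flagged without comparison. `compare_stereo_layer = FALSE`
drops the stereo layers from both sides for triage; the default compares
all layers. Duplicate fragments are grouped by standard InChI: any group
of size ≥ 2 warns, and a record that is nothing but copies of one molecule
gets the stronger flag.

## The fixture suite

`fixture_suite()` generates one minimal molfile per triggerable issue code
(45 fixtures), each designed so that full-pipeline validation emits its
target code; the seed adds only ±0.003-unit coordinate jitter, far from
every geometric threshold, so expected outcomes are seed-invariant. The
fixtures emulate the *defect*, not realistic chemistry: they are small
(2–18 atoms), bare molecules. Passing the suite shows that every check
fires on its canonical trigger and stays quiet on clean depictions; it
does not show recall on real database dumps, where defects co-occur,
coordinates are messier, and aromatic perception across toolkits differs.
The published per-database issue counts depend on those toolkit-specific
models and on dataset downloads, and are deliberately not reproduced here.

## Problem sizes and runtime choices

The shipped test suite validates the full 45-fixture suite end to end
(twice: once per jitter seed), enumerates all 64 ring signatures
exhaustively, runs the dearomatization brute force on ring systems up to
10 atoms (2^11 edge subsets), and checks reprotonation optimality on 20
random polyprotic molecules of 2–4 groups. Whole-file validation batches
all backend work (SMARTS matching, InChI) for all records into a single
helper invocation, so a report over the fixture suite costs one Python
start-up (~2 s) rather than one per record.
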