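---
title: "Methods: quality control of marine-forest occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control of marine-forest occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marineqc)
```

## The problem

Occurrence records of marine forest species — kelps and fucoid brown algae
(orders Fucales, Laminariales, Tilopteridales) and seagrasses (families
Cymodoceaceae, Hydrocharitaceae, Posidoniaceae, Zosteraceae) — are compiled
from literature, herbaria and digital repositories. Aggregated records carry
characteristic errors: outdated or misspelled taxon names, coordinates on
land, locations where no light reaches the bottom (impossible for benthic
photosynthesizers, except rafting material), points far outside a species'
documented range, and duplicates arising when sources overlap. `marineqc`
implements a standardization-and-flagging pipeline for such data: errors that
make a record unusable lead to removal, while *doubtful* records are flagged
but retained, so users decide their fate (rafted specimens, for instance,
are valuable for dispersal ecology even though unsuitable for benthic niche
models).

## Pipeline

The stages, in order, each appending counts to the record set's provenance
log:

1. **Read** (`read_records()`): delimited text with Darwin-Core-style
   headers. Rows violating type invariants (latitude outside [−90, 90],
   month outside [1, 12], a day without a month, ...) are dropped and
   counted rather than repaired — an unusable value cannot be trusted to be
   repairable.
2. **Geocode** (`geocode_records()`): records lacking coordinates are
   looked up by locality in a local gazetteer table (a pluggable stand-in
   for a live geocoding service, keeping the pipeline deterministic and
   offline). Unmatched coordinate-less records are removed.
3. **Standardize** (`standardize_records()`): verbatim names are resolved
   against a local WoRMS-style registry keyed by aphiaID. Matching is exact
   after case/whitespace normalization — no fuzzy matching, since a
   misspelling corrected by guesswork is a new error source; no-match and
   uncertain-status names are removed. Synonyms follow their
   `acceptedAphiaID` chain (transitively, cycle-checked, depth-capped at
   20) to the accepted species. Names resolving to an infraspecific rank
   are rolled up to the species-rank parent when the binomial itself is
   registered; species-level analysis is the convention for this data.
4. **Deduplicate** (`dedup_records()`): records agreeing exactly on
   accepted taxon, longitude, latitude, depth and date (year, month, day)
   collapse to the first in input order (stable and reproducible; no rule
   favors one source over another). Depth uses `verbatimDepth` when
   present — the least processed value — else the min/max depth pair.
   Missing compares equal to missing: two records both lacking a day are
   duplicates if everything else agrees exactly.
5. **Flag** (`apply_flags()`): the three quality checks below.
6. **Summarize / export / prune** (`summarize_records()`,
   `export_geojson()`, `write_records()`, `prune_records()`).

## The three flags

Flags are tri-state — `flagged`, `clear`, `unevaluated` — and independent:
a record can carry up to three.

**On land.** A record is flagged when its point lies *inside* a land
polygon *and* farther than `shoreline_threshold_km` (default **1 km**) from
the nearest shoreline. The tolerance absorbs the finite spatial resolution
of the land polygons: a benthic record digitized a few hundred meters
inland is a cartographic artifact, not an error. The two conditions
together mean a point 0.5 km inside the coast is clear, a point 5 km
inland is flagged, and a point in open ocean is always clear.

**Unsuitable light.** Benthic light, not bathymetry, limits the vertical
distribution of marine forests, so the check compares annual light dose at
the bottom with the photosynthesis limit `light_threshold` (default **50
E·m⁻²·yr⁻¹**, strict inequality: exactly 50 is suitable). Light layers
come in three depth ranges; since a record's true depth is usually unknown
or unreliable, the **maximum** across the three layers is used — the most
conservative choice, flagging only locations unsuitable at *every* plausible
depth. Holopelagic species that complete their life cycle afloat
(*Sargassum fluitans*, *S. natans*, *S. pusillum* by default; configurable)
are exempt.

**Outside known distribution.** Documented ranges are kept as sets of
marine province identifiers (the intermediate level of the Marine
Ecoregions of the World scheme — coarse enough to avoid flagging records
just beyond an ecoregion boundary, fine enough to catch continent-scale
errors). A record in a province outside its species' set is flagged; a
species entirely absent from the range table cannot be verified at all and
its records are **removed**. A species *present* with an empty province set
is different: it is documented to occur nowhere in the covered domain, so
its records are flagged, not removed.

**Unevaluated flags.** Each check leaves its flag `unevaluated` when its
inputs do not apply: no coordinates; no light data at the point (including
land cells — benthic light is undefined there); no province containing the
point (province schemes cover shelf waters; being far offshore is not
evidence of a range error). `prune_records()` removes records with at least
one `flagged` state and treats `unevaluated` as "no evidence of bias";
calling it on a set where some record has *all three* flags unevaluated is
an error, because that means flagging never ran. On write, flags serialize
to the deposited-table convention `-1` (flagged) / empty (clear);
`unevaluated` also writes as empty, with the affected flags listed in
`recordNotes` — the two-state file encoding is deliberately lossy here, and
round-trip identity holds for evaluated flags.

## Geometric kernels and numerical choices

No geodesy library is assumed; the kernels are small enough to verify
against brute force, which the test suite does:

- **Great-circle distance**: haversine on a sphere of mean radius
  6371.0 km. Checked against the closed forms πR/180 per degree of
  latitude and πR for antipodes, and against an independent
  implementation.
- **Point in polygon**: even-odd ray casting, planar in lon/lat, holes
  supported. Points exactly on a boundary edge count as inside (a record
  on the coastline is on land). Verified against a winding-number oracle
  on randomized simple polygons.
- **Shoreline distance**: minimum haversine distance to the polygon
  boundary, each segment densified to ≤ 0.01° steps (≈ 1.1 km at the
  equator; together with segment-endpoint minimization this is finer than
  the 1 km decision needs). Verified within 0.05 km against a 0.001°
  dense-sampling oracle.
- **Raster sampling**: nearest cell, no interpolation — an extraction, not
  a model. Grid row 1 is the northernmost row, matching the ASCII-grid
  layout.
- **Province lookup**: first containing polygon in increasing-id order, so
  shared boundaries resolve deterministically to the lowest id.
- Polygons crossing the antimeridian are rejected at load; inputs must be
  split at ±180°. Rings must be closed, ≥ 4 vertices, non-self-intersecting.

## The synthetic world

`build_world()` + `generate_records()` produce a complete, deterministic
test bench: rectangular islands on a lattice of slots (diagonal-first so
coastal light reaches provinces across the domain), a light stack whose
layer *k* decays at 1×/1.5×/2× the base rate per cell of shore distance
(so deeper layers are always dimmer), a rectangular province tiling,
a registry with synonyms (plus one uncertain taxon and one species absent
from the range table), contiguous-block species ranges, and a gazetteer.
Rectangles everywhere mean every ground-truth property — containment,
shore distance, province membership, light value — follows from interval
arithmetic, independent of the geometry code under test.

Defaults: a 12° × 12° domain on a 0.1° grid, two 2° islands, surface light
170 E·m⁻²·yr⁻¹ decaying 8 % per cell, 3 × 3 provinces, 12 species with 2
synonyms each. These give a world where well-lit coastal rings, dark
offshore basins, and in-range/out-of-range provinces all exist with room to
spare. Range blocks are drawn at random but anchored so that every province
containing an island interior is covered by at least one species — coastal
species occur near their coasts, and on-land error placements are always
feasible.

Error placements keep **guard margins** from every decision boundary:
light ≥ 55 for clean placements, < 45 for low-light ones (the threshold is
50); ocean points ≥ 0.15° from any shore (the tolerance is ≈ 0.009°);
on-land points ≥ 0.15° inside an island; all points ≥ half a cell plus the
jitter amplitude from province boundaries; coordinates jitter uniformly
within ±0.3 cell so distinct records never collide exactly while staying in
their cell. Because of the margins, recovery of the labels by the pipeline
is exact — equality of sets, not approximate rates. Label counts are
`round(n × proportion)` with the remainder to `clean`; duplicates are
appended after all originals so keep-first deduplication removes exactly
them.

What the synthetic world does *not* emulate: fractal coastlines, real
bathymetry-driven light fields, the heavy source-type imbalance of real
aggregated data, fuzzy locality strings, and coordinate precision
artifacts. Passing the suite therefore demonstrates the *logic* of the
pipeline is correct at the decision boundaries, not that real-world land
polygons or light layers are accurate — those are user-supplied inputs at
full scale.

Test and acceptance problem sizes: the end-to-end suite uses 20 seeds ×
2,000 records with a mixed error budget (10 % on land, 5 % low light, 5 %
out of range, 10 % duplicates, 5 % synonyms, 2 % without range
information), geometry oracles run on 50 polygons × 1,000 points and 100
shoreline cases — sizes at which the brute-force oracles themselves are
exact and fast.

## Known limitations

- Planar lon/lat geometry: polygon edges are straight in degree space, not
  great circles; distances are spherical. Adequate at the ≤ 0.05 km
  verification tolerance for coastal-scale polygons, inadequate for
  polygons with multi-degree edges at high latitude.
- No spatial index beyond bounding boxes; the intended full-scale use
  (millions of points, thousands of polygons) is minutes, not seconds.
- Exact-match taxonomy: misspellings are removed, not recovered.
- The `-1`/empty flag encoding cannot represent `unevaluated` in files.
- Antimeridian-crossing and polar geometries are unsupported in this
  version.
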