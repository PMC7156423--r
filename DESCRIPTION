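Package: marineqc
Title: Quality Control for Marine-Forest Species Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to clean and quality-flag Darwin-Core-style occurrence
    records of marine forest species (kelps, fucoids and seagrasses):
    taxonomic standardization against a local WoRMS-style registry with
    synonym resolution, gazetteer-based geocoding, exact-duplicate removal,
    and a three-part flagging system marking records on land (1 km shoreline
    tolerance), in regions with unsuitable benthic light (below 50
    E.m-2.yr-1), or outside the known distribution of species at the level
    of marine provinces. Includes self-contained geographic kernels
    (great-circle distance, point-in-polygon, shoreline distance, gridded
    raster sampling), Table-style summary reports, GeoJSON export, a
    command-line pipeline runner, and a deterministic synthetic-world
    generator producing coastlines, light rasters, province tilings,
    registries and labelled record sets for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    yaml
Config/testthat/edition: 3
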