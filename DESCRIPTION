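Package: resalloc
Title: Gridded Accounting of Cereal Crop-Residue Production and Usage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for allocating cereal crop residues on a regular
    latitude-longitude grid. Converts gridded grain production to residue
    production by three alternative harvest-index methods, estimates on-field
    burning from gridded and point-record fire data, computes livestock feed
    and bedding demand from feed-conversion ratios, redistributes residues
    from surplus to deficit cells by nearest-first trade, assigns other
    off-field uses by national income level, and closes a per-cell mass
    balance into five usage layers written as netCDF. Includes a seeded
    synthetic-world generator so the whole scheme can be exercised and
    tested without external downloads, and an ensemble driver for the
    eighteen method combinations and their mean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
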