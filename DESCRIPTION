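Package: crownshade
Title: Shadow-Resistant Hybrid Retrieval of Chlorophyll Content for Individual Tree Crowns
Version: 0.1.0
Authors@R:
    person("crownshade", "developers", email = "crownshade@example.org", role = c("aut", "cre"))
Description: Simulates multispectral reflectance of row-structured orchard canopies with a
    simplified three-dimensional radiative-transfer scene (PROSPECT-5 style leaf optics,
    ellipsoidal crowns with Beer's-law gap probability, four-component sunlit/shaded imaging,
    photon escape probability), ranks broadband vegetation indices by their resistance to
    crown-shadow variation, and trains Gaussian-process hybrid inversion models that map
    per-tree leaf and canopy chlorophyll content (LCC/CCC) from UAV-style five-band imagery.
    Includes a synthetic orchard survey generator with known ground truth, an end-to-end
    pipeline with deterministic seeding, and plain-text raster/CSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
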