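Package: invadosim
Title: Mechanochemical Simulation of Invadopodia Protrusion into a Collagen Fiber Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based three-dimensional simulator of cancer-cell invadopodia
    protruding into a discrete collagen type 1 fiber network. Couples five
    viscoelastic membrane layers (invadopodial membrane, force transduction
    layer, actin cortex layer and a double nuclear envelope), a branched actin
    network with Arp2/3 nucleation, capping, crosslinkers and bipolar myosin
    minifilaments, Bell-model integrin slip-bond adhesions, and a six-species
    reaction-diffusion field for MT1-MMP/MMP-2/TIMP-2 mediated matrix
    degradation. Protrusion is driven through cyclic protrusive, retractile
    and severing phases; in-silico knockout experiments (alpha-actinin,
    filamin, fascin, MT1-MMP, Arp2/3 inhibition) probe the actin-myosin
    machinery of invasion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
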