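Package: evloadr
Title: Descriptor-Guided Selection of Extracellular Vesicle Drug-Loading
    Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support framework for choosing among five extracellular
    vesicle (EV) drug-loading methods (passive incubation, electroporation,
    saponin permeabilization, freeze-thaw cycling, sonication) from seven
    physicochemical descriptors of a small-molecule cargo. Fits one elastic-net
    regression per loading method on z-scored descriptors, recommends the
    method with the highest predicted loading efficiency, validates the
    recommendation by leave-one-out cross-validation, a predefined external
    set and repeated random splits, and flags extrapolation with a
    leverage-based applicability domain. Ships the 21-compound reference
    dataset, a synthetic-compound generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
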