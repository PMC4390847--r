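Package: osmocell
Title: Variable-Volume Vesicle Reactors for Encapsulated Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models mass-action reaction networks encapsulated in semi-permeable
    lipid vesicles whose aqueous volume tracks osmotic balance. Provides the
    four classical reactor formulations (reservoir, CSTR, high-buffer vesicle,
    full variable-volume vesicle), stiff time integration with injection
    protocols, an all-roots polynomial homotopy continuation solver for
    fixed-surface steady states, bifurcation sweeps through vesicle morphology
    space with detection of spherical (reduced surface = 1) steady states, and
    two-phase Monte-Carlo parameter-space searches for emergent bistability,
    including censuses of fixed-point counts and the morphology-space
    transformation and concentration-rescaling rules used to steer bifurcation
    curves into the vesicle viability region.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
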