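Package: thermoflux
Title: Thermodynamics-Constrained Analysis of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of metabolic networks under
    thermodynamic feasibility constraints. Implements flux balance analysis
    (FBA), thermodynamics-based metabolic flux analysis (TMFA) as a mixed
    integer linear program coupling reaction directionality binaries to
    transformed Gibbs free energy changes, thermodynamic variability
    analysis (TVA) of per-reaction free-energy ranges at fixed growth,
    classification of reactions into thermodynamic bottlenecks and
    candidates for regulatory control, and validation of those classes
    against gene-expression fold-change ranges.  Includes readers for a
    documented tabular model dialect and SBML Level 3, lumping of reactions
    containing metabolites with unknown formation energies, and seeded
    generators for synthetic networks and expression datasets.  Mixed
    integer programs are solved through the GLPK command-line solver
    (glpsol), which must be on the PATH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    MASS,
    pracma
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: GLPK standalone solver (glpsol) on the PATH
Config/testthat/edition: 3
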