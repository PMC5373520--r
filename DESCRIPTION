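Package: ticcircuit
Title: Simulation of Motor Tic Generation in the Basal
    Ganglia-Cerebellar-Thalamo-Cortical Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Firing-rate (neural-mass) simulation of the basal
    ganglia-cerebellar-thalamo-cortical motor loop and of the conditions
    under which it produces motor tics.  Leaky-integrator units arranged
    in three competing action channels implement basal ganglia action
    selection by disinhibition, a Marr-Albus style cerebellar microcircuit
    (mossy fibers, granule, Golgi, Purkinje and dentate layers), a
    two-population motor thalamus and primary motor cortex, together with
    phasic dopamine modulation of the striatal direct and indirect
    pathways.  The package provides the full simulated-subject protocol
    (sessions, trials, tic classification, cohorts, dopamine dose-response
    sweeps), the accompanying analyses (peak-amplitude ANOVAs,
    onset-latency estimation by cross-correlation of trace derivatives),
    genetic-algorithm parameter fitting against reference firing-rate
    curves, and a quartile-filtered sensitivity analysis over the fitting
    archive.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
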