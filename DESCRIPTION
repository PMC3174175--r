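Package: etmc
Title: Event-Transition Markov Chains for Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links qualitative gene regulatory networks to quantitative
    protein concentration time series through event-transition Markov
    chains. Events are slope changes of gene products; an event transition
    graph constrains a row-stochastic transition matrix whose entrywise
    product with per-protein multiplicative impact matrices governs the
    growth of expected protein concentrations via its Perron eigenvalue.
    Provides the equilibrium calibration of impact coefficients, exact and
    asymptotic moments of multiplicative accumulation rules, piecewise
    exponential fitting of protein time series, reverse engineering of
    transition matrices from growth objectives (exact and interval
    constrained), solution-set sampling with volume estimation, and
    per-transition sensitivity ranking. Includes a two-gene tutorial
    fixture and a reconstruction of the Escherichia coli carbon-starvation
    event transition graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'etg.R'
    'chain.R'
    'impact.R'
    'accumulation.R'
    'timeseries.R'
    'inference.R'
    'fixtures.R'
    'io.R'
    'case_study.R'
    'cli.R'
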