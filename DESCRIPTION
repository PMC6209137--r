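Package: paretoMFA
Title: Multiple-Criteria Experimental Design for 13C Metabolic Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for information-economic design of carbon labeling
    experiments (CLEs) in steady-state 13C metabolic flux analysis. Simulates
    isotope labeling of atom-mapped metabolic networks via the cumomer
    cascade, scores candidate experiments by Fisher-information optimality
    criteria (D, A, E, degrees of freedom) together with a detailed
    experimental and analytical cost model, and approximates the Pareto front
    over tracer mixtures, measurement selections and replicate counts with a
    speed-constrained multi-objective particle swarm optimizer (SMPSO) with a
    bounded crowding-distance archive. Includes hierarchical clustering of
    Pareto-optimal tracer mixtures, robustness sampling around the design
    point, and table exports for front scatter plots, chord diagrams, ternary
    diagrams and replicate histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
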