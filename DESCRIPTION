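Package: ssinfer
Title: Adaptive Inference of S-System Models of Cellular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers parsimonious phenomenological models of biochemical
    dynamics from measured concentrations and rates of change. Rate laws are
    represented as S-systems (differences of products of power laws), fitted
    by alternating log-space ridge regression, and model complexity is chosen
    by Bayesian posterior model selection over a nested hierarchy of
    interaction structures, with effective-parameter counting from the
    eigenvalues of the posterior Hessian. Includes a weighted linear-regression
    baseline, a yeast-glycolysis oscillator benchmark generator, out-of-sample
    evaluation metrics, an experiment driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'ssinfer-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'ssystem-model.R'
    'chi-squared.R'
    'altreg.R'
    'linear-baseline.R'
    'glycolysis.R'
    'selection.R'
    'evaluate.R'
    'io.R'
    'utils.R'
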