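Package: betaflux
Title: Steady-State 13C Metabolic Flux Analysis for Beta-Cell Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying central-carbon metabolism in insulin-secreting
    beta-cells from parallel stable-isotope tracer experiments. Implements
    elementary metabolite unit (EMU) simulation of mass isotopomer distributions
    over atom-mapped reaction networks, weighted least-squares flux regression
    against GC-MS fragment measurements and extracellular exchange rates with
    chi-square goodness-of-fit and profile-likelihood confidence intervals,
    estimators for cell-specific uptake/excretion rates from medium time courses,
    futile glucose cycling from deuterated-glucose labeling, compartmental redox
    ratios from metabolite pools, and a seeded synthetic-experiment generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
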