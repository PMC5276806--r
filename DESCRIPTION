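Package: acetrace
Title: Quantitative Analysis of 13C-Acetate Tracing in Cultured Cells
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of stable-isotope (13C) acetate tracing experiments in
    cell culture: natural-abundance correction of GC-MS mass isotopomer
    distributions, internal-standard quantification of medium and hydrolysate
    acetate from selected-ion intensities, growth-normalized net acetate
    exchange with deconvolution into simultaneous uptake and release fluxes,
    isotopomer spectral analysis of palmitate labeling to infer lipogenic
    acetyl-CoA enrichment, kinetic flux profiling of palmitate synthesis and
    two-carbon acetyl demand, and aggregate histone-bound acetate labeling.
    A seeded scenario simulator generates every input table the pipeline
    consumes, enabling end-to-end recovery tests.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
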