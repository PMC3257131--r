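Package: ckshuttle
Title: Compartmentalized Energy Transfer and the Creatine Kinase Shuttle in
    Cardiac Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional reaction-diffusion model of energy transfer in
    cardiac muscle cells. The diffusion path spans ten myofibrillar units, two
    cytosolic units and the mitochondrial intermembrane space, coupled to a
    well-mixed mitochondrial matrix through the adenine nucleotide translocase,
    the phosphate carrier and ATP synthase. Creatine kinase is compartmentalized
    into a myofibrillar/cytosolic pool and a mitochondrial pool that can be
    functionally coupled to the translocase through a local ATP
    microcompartment; adenine-nucleotide permeability of the mitochondrial
    outer membrane can be selectively restricted. The package simulates
    pulsatile contraction cycles to a cyclic steady state, partitions
    mitochondrial energy export between phosphocreatine and ATP, fits
    mitochondrial response times to workload steps, converts between tissue
    contents, molar concentrations and oxygen-consumption rates for an
    idealized perfused heart, and generates synthetic working-heart data sets
    for testing the analysis stages.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
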