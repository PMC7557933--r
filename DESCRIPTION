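Package: hrdkit
Title: Sequence Analysis and Metal-Binding Models for Histidine-Rich Plant Defensins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing histidine-rich plant defensins (HRDs) built on the
    eight-cysteine CSab scaffold: FASTA input/output for mature defensin domains,
    scaffold detection with inter-cysteine loop partition, disulfide-connectivity
    assignment under the standard and shifted patterns, physicochemical
    characterisation (average mass with disulfide correction, Henderson-Hasselbalch
    charge curves and isoelectric points, GRAVY hydrophobicity, histidine counting
    and HRD classification), cysteine-anchored alignment with redundancy reduction
    and classical multidimensional-scaling sequence-space projection, 1:1
    protein-metal binding isotherm fitting for microscale-thermophoresis style
    dilution series, and a ground-truthed synthetic defensin generator for
    validating every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    seqinr,
    jsonlite,
    minpack.lm,
    cluster,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
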