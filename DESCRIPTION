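Package: distogramr
Title: Protein Inter-Residue Distance Distribution Prediction from Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for predicting binned inter-residue
    distance distributions (distograms) of proteins from multiple sequence
    alignments. Covers the full pipeline: a3m/FASTA alignment parsing,
    sequence reweighting and regularized inverse-covariance direct-coupling
    analysis with average-product correction, HMM-profile features, assembly
    of the L x L x 547 pairwise input tensor, structure-derived training
    labels (10-bin C-beta distance maps, DSSP-style secondary structure,
    phi/psi and relative accessible-surface-area classes), a dilated
    residual convolutional network with crop-based training and inference
    aggregation, multi-model ensembling, and CASP-style top-L contact
    precision evaluation. Includes synthetic fixture generators
    (ideal-geometry helices, Potts-model alignments with planted couplings)
    so every stage is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
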