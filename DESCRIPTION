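Package: semgcs
Title: Analog Compressed Sensing for Surface EMG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compression and reconstruction of surface electromyography (sEMG)
    segments with analog compressed sensing. Provides a synthetic motor-unit
    action-potential (MUAP) train generator for healthy, myopathic and
    neuropathic signal classes, dynamic thresholding for sparsity control,
    random sensing matrices (Bernoulli, Gaussian, binary Toeplitz and a
    random-demodulator simulation), sensing-dictionary selection by orthogonal
    matching pursuit with K-SVD style atom updates, and reconstruction by
    l1 basis pursuit, combined l1-l1 optimization, or block sparse Bayesian
    learning with an autoregressive intra-block correlation model. Includes
    compression-quality metrics (PRD, RMSE, SNR, compression factor,
    sensitivity/specificity), a k-nearest-neighbour classification check and a
    Monte-Carlo sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
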