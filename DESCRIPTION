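Package: lambdasfs
Title: Multiple-Merger Coalescent Analysis of Site Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting balancing selection and sweepstakes
    reproduction from aligned nucleotide sequences. Computes classical
    polymorphism, divergence, differentiation and linkage-disequilibrium
    statistics (Watterson's theta, nucleotide diversity, Tajima's D,
    Jukes-Cantor corrected Dxy/Da, Hudson's FST with permutation testing,
    D-prime); builds folded and unfolded (outgroup-polarized) site
    frequency spectra; simulates genealogies under the Kingman coalescent,
    Beta(2-alpha, alpha) and point-mass (Dirac psi) multiple-merger
    Lambda-coalescents and growth-time-changed Kingman models; and fits
    these models to observed spectra by minimum-l2 grid search with
    likelihood-ratio G tests and approximate multinomial log-likelihoods.
    Includes a coalescent-based synthetic-data generator, including a
    two-haplogroup balanced-locus scenario with a strong singleton excess.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
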