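Package: mkalpha
Title: McDonald-Kreitman Tests and Adaptive Substitution Fraction from
    Transcriptome Ortholog Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for estimating the prevalence of adaptive protein
    evolution between closely related species from transcriptome data.
    Predicts open reading frames, builds trimmed pairwise codon alignments
    of orthologous coding sequences, counts synonymous and non-synonymous
    sites and substitutions with the Nei-Gojobori pathway method, calls
    diallelic SNPs from pooled-sample pileups with depth, allele-count and
    quality filters, classifies them as silent or non-silent, and combines
    divergence and polymorphism counts into per-gene McDonald-Kreitman
    tests with false-discovery-rate correction and a transcriptome-wide
    estimate of the adaptive substitution fraction alpha with bootstrap
    confidence intervals. Includes a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
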