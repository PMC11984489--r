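Package: sgentropy
Title: Speed-Gradient Entropy Dynamics on the Simplex and on Transition Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates speed-gradient evolution laws for systems obeying the
    maximum information entropy principle. Implements the projected gradient
    flow of Shannon entropy on the probability simplex under general linear
    constraints, with an independent dual-Newton maximum-entropy oracle, and
    two detailed-balance-breaking models for coarse-grained brain-state
    transition matrices in which entropy production (a Kullback-Leibler
    divergence between forward and backward transition probabilities, or the
    divergence from a uniform baseline) is driven upward by a row-normalized
    gradient ascent, in continuous and sampled time. Includes seeded synthetic
    fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
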