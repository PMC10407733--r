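Package: otstox
Title: Quantitative Toxicity Profiling of Orthogonal Translation Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for profiling the host burden of engineered
    orthogonal translation systems (OTS) in bacteria. Extracts lag time,
    specific growth rate and growth efficiency from plate-reader OD600
    time series via ranked moving-window slopes; summarizes flow-cytometry
    forward-scatter distributions as a cell-size proxy; combines growth and
    size parameters into background-normalized multi-parametric relative
    fitness values; performs label-free proteomic differential-abundance
    analysis with an s0-moderated t-statistic and permutation-based FDR,
    iBAQ abundance ranking and dysregulated-set overlap analysis; computes
    hypergeometric over-representation statistics; quantifies site-specific
    amino-acid incorporation from MS1 reporter-peptide chromatograms
    (pSer-normalized area-under-curve ratios with limit-of-detection
    handling) and reporter yield from gel densitometry; and screens
    orthogonal tRNAs for identity-element overlap with host aminoacyl-tRNA
    synthetases, proposing orthogonalizing acceptor-stem mutations. Ships
    seeded synthetic-data generators with ground truth for every input type
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
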