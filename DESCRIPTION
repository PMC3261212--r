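Package: physmapr
Title: BAC Physical Map Construction from AFLP and WGP Fingerprints
Version: 0.9.0
Authors@R:
    person("physmapr", "developers", email = "physmapr@example.org",
           role = c("aut", "cre"))
Description: Tools for building genome-wide BAC physical maps from
    restriction-fragment fingerprints, in the style used for heterozygous
    plant genomes. Implements Sulston-score fingerprint overlap testing and
    contig assembly (with questionable-clone resplitting and end-to-end
    merging) for both gel-mobility (AFLP) and exact-match sequence-tag (WGP)
    fingerprints, random k-sets superpool designs with marker deconvolution,
    in-silico genetic anchoring of contigs, a truncated two-Poisson
    copy-number model for tag heterozygosity, hybrid-map integration via
    shared-clone contig groups, and a synthetic diploid genome simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
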