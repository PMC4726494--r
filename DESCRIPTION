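Package: karyoClock
Title: Karyotype Additivity and Coalescent Dating of Clonal Hybrid Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing karyotype stability in hybrid (often polyploid)
    clonal lineages and for placing those lineages on an absolute time scale.
    Expected hybrid karyotypes are composed additively from haploid parental
    complements and checked against observed chromosome counts; two-channel
    genomic in situ hybridization (GISH) signal ratios assign chromosomes to
    parental sets. Clone ages are estimated from haploid (mitochondrial)
    haplotype samples by sequential importance sampling under the
    infinite-sites coalescent (theta profile likelihood and TMRCA posterior);
    species divergence times are estimated from multilocus nuclear data by
    Markov chain Monte Carlo under the multispecies coalescent with JC69
    sequences and per-locus rate scalars. Penalized-likelihood rate smoothing
    with leave-one-tip-out cross-validation converts a calibrated phylogram
    into a chronogram with branch-specific substitution rates, and calibration
    helpers convert coalescent-unit and substitution-unit times into years.
    Synthetic-data generators with recorded ground truth support recovery
    testing of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
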