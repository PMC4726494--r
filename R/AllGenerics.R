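#' Total chromosome count of a karyotype
#'
#' @param x a \code{Karyotype}.
#' @return integer total number of chromosomes.
#' @export
setGeneric("chromosomeTotal", function(x) standardGeneric("chromosomeTotal"))

#' @rdname chromosomeTotal
#' @export
setMethod("chromosomeTotal", "Karyotype", function(x) {
  x@meta + x@submeta + x@subtelo + x@acro
})

#' Category counts of a karyotype as a named vector
#'
#' @param x a \code{Karyotype}.
#' @return named integer vector over the four Levan categories.
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname categoryCounts
#' @export
setMethod("categoryCounts", "Karyotype", function(x) {
  setNames(c(x@meta, x@submeta, x@subtelo, x@acro), KARYOTYPE_CATEGORIES)
})

#' @export
setGeneric("thetaHat", function(x) standardGeneric("thetaHat"))

#' ML theta of a profile estimate
#' @param x a \code{ThetaEstimate}.
#' @return numeric theta maximizing the profile.
#' @rdname thetaHat
#' @export
setMethod("thetaHat", "ThetaEstimate", function(x) x@thetaHat)

#' Node ages of a chronogram
#' @param x a \code{Chronogram}.
#' @return numeric node ages in MYA (tips first, then internal nodes).
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @rdname nodeAges
#' @export
setMethod("nodeAges", "Chronogram", function(x) x@ages)

#' Per-branch substitution rates of a chronogram
#' @param x a \code{Chronogram}.
#' @return numeric rates (substitutions/site/MYA), one per edge of
#'   \code{x@phy$edge}.
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))

#' @rdname branchRates
#' @export
setMethod("branchRates", "Chronogram", function(x) x@rates)

setMethod("show", "Karyotype", function(object) {
  cat("Karyotype", if (!is.na(object@label)) sprintf("[%s]", object@label),
      "\n")
  print(categoryCounts(object))
  cat("total:", chromosomeTotal(object), "\n")
})

setMethod("show", "HaplotypeSample", function(object) {
  cat(sprintf("HaplotypeSample: n = %d sequences, %d distinct haplotypes, %d segregating sites\n",
              object@n, ncol(object@siteMatrix), nrow(object@siteMatrix)))
})

setMethod("show", "ThetaEstimate", function(object) {
  cat(sprintf("ThetaEstimate: theta_hat = %.4g%s (profile over %d grid points)\n",
              object@thetaHat, if (object@unbounded) " [unbounded]" else "",
              nrow(object@profile)))
})

setMethod("show", "TmrcaEstimate", function(object) {
  cat(sprintf(
    "TMRCA (coalescent units of N_f generations): mean %.4g, 95%% CI [%.4g, %.4g]\n  %d particles, seed %d\n",
    object@mean, object@ciLow, object@ciHigh, object@nParticles, object@seed))
})

setMethod("show", "Chronogram", function(object) {
  ntip <- length(object@phy$tip.label)
  cat(sprintf(
    "Chronogram: %d tips, root age %.4g MYA, lambda = %g\n  rates %.4g-%.4g subst/site/MYA\n",
    ntip, max(object@ages), object@lambda,
    min(object@rates), max(object@rates)))
})

setMethod("show", "MSCModel", function(object) {
  cat(sprintf("MSCModel ((T,N),E): tau_TN = %.4g, tau_TNE = %.4g\n",
              object@tauTN, object@tauTNE))
  cat(sprintf("  theta: E %.4g, T %.4g, N %.4g, TN %.4g, TNE %.4g\n",
              object@thetaE, object@thetaT, object@thetaN,
              object@thetaTN, object@thetaTNE))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: %d retained samples (seed %d)\n",
              object@nSamples, object@seed))
  print(round(object@summary, 6))
})

setMethod("show", "CalibrationParams", function(object) {
  cat(sprintf(
    "CalibrationParams: g = %g yr, L = %g sites, rate = %g subst/site/MYA, outgroup age = %g MYA\n",
    object@g, object@L, object@rate, object@outgroupAge))
})
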