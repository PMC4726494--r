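#' @import methods
#' @importFrom stats optim uniroot rexp rpois runif rgamma rnorm var sd
#'   quantile setNames dgamma acf median rmultinom
#' @importFrom utils read.delim write.table packageVersion modifyList
#' @useDynLib karyoClock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

KARYOTYPE_CATEGORIES <- c("metacentric", "submetacentric", "subtelocentric",
                          "acrocentric")
GENOME_CODES <- c("E", "T", "N")

#' Karyotype: chromosome counts in the four Levan categories
#'
#' Holds counts of metacentric (m), submetacentric (sm), subtelocentric (st)
#' and acrocentric (a) chromosomes of one genome or genome combination.
#'
#' @slot meta,submeta,subtelo,acro non-negative integer chromosome counts.
#' @slot label optional genome-composition label (e.g. \code{"EEN"}).
#' @export
setClass("Karyotype",
  representation(meta = "integer", submeta = "integer",
                 subtelo = "integer", acro = "integer", label = "character"),
  prototype(meta = 0L, submeta = 0L, subtelo = 0L, acro = 0L,
            label = NA_character_))

setValidity("Karyotype", function(object) {
  counts <- c(object@meta, object@submeta, object@subtelo, object@acro)
  if (any(is.na(counts))) return("counts must not be NA")
  if (any(counts < 0L)) return("chromosome counts must be non-negative")
  TRUE
})

#' Haplotype sample under the infinite-sites model
#'
#' A sample of n haploid sequences reduced to its distinct haplotypes: a
#' binary site matrix (segregating sites x distinct haplotypes, derived
#' allele = 1) plus the multiplicity of each haplotype.
#'
#' @slot siteMatrix binary integer matrix, rows = segregating sites,
#'   columns = distinct haplotypes.
#' @slot multiplicities integer count of each distinct haplotype.
#' @slot n total number of sequences (sum of multiplicities).
#' @export
setClass("HaplotypeSample",
  representation(siteMatrix = "matrix", multiplicities = "integer",
                 n = "integer"))

setValidity("HaplotypeSample", function(object) {
  m <- object@siteMatrix
  if (length(m) && !all(m %in% c(0L, 1L)))
    return("site matrix must be binary (0/1)")
  if (ncol(m) != length(object@multiplicities))
    return("one multiplicity per distinct haplotype required")
  if (any(object@multiplicities < 1L))
    return("multiplicities must be >= 1")
  if (object@n != sum(object@multiplicities))
    return("n must equal the sum of multiplicities")
  if (nrow(m) > 0L) {
    freq <- as.vector(m %*% object@multiplicities)
    if (any(freq == 0L) || any(freq == object@n))
      return("invariant site columns are not allowed (every site must segregate)")
  }
  if (ncol(m) > 1L && anyDuplicated(apply(m, 2L, paste, collapse = "")))
    return("haplotype columns must be distinct")
  TRUE
})

#' Scaled mutation rate estimate (theta)
#'
#' Result of profiling the sequential-importance-sampling likelihood over a
#' theta grid. theta = 2 N_f mu for a haploid maternally inherited locus
#' (mu per locus per generation).
#'
#' @slot thetaHat maximum-likelihood theta on the refined grid.
#' @slot profile data.frame with columns theta, loglik, mcse.
#' @slot unbounded TRUE when the likelihood increases without bound
#'   (all haplotypes distinct, Ewens boundary).
#' @export
setClass("ThetaEstimate",
  representation(thetaHat = "numeric", profile = "data.frame",
                 unbounded = "logical"),
  prototype(unbounded = FALSE))

setValidity("ThetaEstimate", function(object) {
  if (length(object@thetaHat) != 1L || is.na(object@thetaHat) ||
      object@thetaHat < 0) return("thetaHat must be a single value >= 0")
  TRUE
})

#' TMRCA estimate in coalescent units
#'
#' Importance-weighted posterior summary of the time to the most recent
#' common ancestor, in coalescent units of N_f generations.
#'
#' @slot mean weighted posterior mean.
#' @slot ciLow,ciHigh weighted 2.5\% and 97.5\% quantiles.
#' @slot nParticles number of importance-sampling particles.
#' @slot seed integer seed used for the run.
#' @export
setClass("TmrcaEstimate",
  representation(mean = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nParticles = "integer", seed = "integer"))

setValidity("TmrcaEstimate", function(object) {
  if (object@ciLow > object@mean + 1e-12 ||
      object@mean > object@ciHigh + 1e-12)
    return("interval must bracket the mean (ciLow <= mean <= ciHigh)")
  if (object@mean < 0 || object@ciLow < 0) return("times must be >= 0")
  TRUE
})

#' Chronogram: ultrametric tree with node ages and branch rates
#'
#' Result of penalized-likelihood rate smoothing: a rooted tree whose node
#' ages are in MYA (tips at 0) with one substitution rate per branch
#' (substitutions/site/MYA) and the smoothing value lambda used.
#'
#' @slot phy the \code{ape::phylo} topology (edge lengths = durations, MYA).
#' @slot ages numeric node ages in MYA indexed like phylo nodes
#'   (tips first, then internal nodes); tips are 0.
#' @slot rates numeric per-edge substitution rates (rows of \code{phy$edge}).
#' @slot lambda smoothing parameter.
#' @slot objective achieved penalized log-likelihood.
#' @slot convergence optimizer convergence code (0 = converged).
#' @export
setClass("Chronogram",
  representation(phy = "ANY", ages = "numeric", rates = "numeric",
                 lambda = "numeric", objective = "numeric",
                 convergence = "integer"))

setValidity("Chronogram", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("phy must be an ape phylo object")
  if (length(object@rates) != nrow(phy$edge))
    return("one rate per edge required")
  if (any(object@rates <= 0)) return("rates must be > 0")
  ntip <- length(phy$tip.label)
  if (any(abs(object@ages[seq_len(ntip)]) > 1e-9))
    return("tip ages must be 0")
  dur <- object@ages[phy$edge[, 1L]] - object@ages[phy$edge[, 2L]]
  if (any(dur <= 0)) return("every parent must be older than its child")
  TRUE
})

#' Multispecies-coalescent model for the fixed topology ((T,N),E)
#'
#' Divergence times tau (expected substitutions/site) and population
#' parameters theta (4 Ne mu) for the three contemporary populations and the
#' two ancestral ones.
#'
#' @slot tauTNE root divergence (E vs (T,N)).
#' @slot tauTN divergence of T and N.
#' @slot thetaE,thetaT,thetaN,thetaTN,thetaTNE population mutation parameters.
#' @export
setClass("MSCModel",
  representation(tauTNE = "numeric", tauTN = "numeric",
                 thetaE = "numeric", thetaT = "numeric", thetaN = "numeric",
                 thetaTN = "numeric", thetaTNE = "numeric"))

setValidity("MSCModel", function(object) {
  if (!(object@tauTN > 0 && object@tauTNE > object@tauTN))
    return("need 0 < tauTN < tauTNE")
  th <- c(object@thetaE, object@thetaT, object@thetaN,
          object@thetaTN, object@thetaTNE)
  if (any(th <= 0)) return("all theta must be > 0")
  TRUE
})

#' Posterior summary of an MCMC run
#'
#' @slot summary data.frame with one row per parameter: mean, 2.5\% and
#'   97.5\% quantiles, effective sample size.
#' @slot nSamples retained sample count.
#' @slot seed integer seed of the chain.
#' @slot settings list of chain settings (iterations, burn-in, thinning).
#' @export
setClass("PosteriorSummary",
  representation(summary = "data.frame", nSamples = "integer",
                 seed = "integer", settings = "list"))

setValidity("PosteriorSummary", function(object) {
  s <- object@summary
  need <- c("mean", "q2.5", "q97.5", "ess")
  if (!all(need %in% colnames(s)))
    return("summary must have columns mean, q2.5, q97.5, ess")
  if (any(s$q2.5 > s$mean + 1e-9) || any(s$mean > s$q97.5 + 1e-9))
    return("intervals must bracket the means")
  TRUE
})

#' Parameters converting relative times to years
#'
#' @slot g generation time in years.
#' @slot L locus length in sites.
#' @slot rate substitution rate in substitutions/site/MYA.
#' @slot outgroupAge age of the ingroup--outgroup split in MYA.
#' @export
setClass("CalibrationParams",
  representation(g = "numeric", L = "numeric", rate = "numeric",
                 outgroupAge = "numeric"),
  prototype(g = 2, L = 1140, rate = NA_real_, outgroupAge = NA_real_))

setValidity("CalibrationParams", function(object) {
  vals <- c(object@g, object@L, object@rate)
  if (any(!is.na(vals) & vals <= 0)) return("g, L and rate must be > 0")
  if (!is.na(object@outgroupAge) && object@outgroupAge <= 0)
    return("outgroupAge must be > 0")
  TRUE
})
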