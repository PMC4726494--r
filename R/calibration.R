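MYA_IN_YEARS <- 1e6   # the single place the year/MYA factor lives

#' Construct calibration parameters
#'
#' @param g generation time in years.
#' @param L locus length in sites (default 1140, canonical cytochrome b).
#' @param rate substitution rate in substitutions/site/MYA (e.g. the
#'   lineage-averaged chronogram rate).
#' @param outgroupAge ingroup--outgroup split age in MYA (for tau
#'   conversion).
#' @return a \code{CalibrationParams}.
#' @export
calibrationParams <- function(g = 2, L = 1140, rate = NA_real_,
                              outgroupAge = NA_real_) {
  new("CalibrationParams", g = g, L = L, rate = rate,
      outgroupAge = outgroupAge)
}

#' Convert a coalescent-unit TMRCA into years
#'
#' The per-generation locus mutation rate is mu = rate/MYR x L x g; the
#' female effective size follows from theta = 2 N_f mu; and the clone age is
#' t = TMRCA x N_f x g years. The credible-interval endpoints are mapped
#' through the same monotone transform (theta uncertainty is not propagated
#' unless \code{thetaProfile} resampling is requested).
#'
#' @param tmrca a \code{TmrcaEstimate} (coalescent units of N_f
#'   generations).
#' @param theta scaled mutation rate 2 N_f mu (per locus per generation).
#' @param params a \code{CalibrationParams} with positive g, L and rate.
#' @param thetaProfile optional profile data.frame (columns theta, loglik);
#'   when given, theta is resampled from the normalized profile likelihood
#'   and the CI reflects joint TMRCA + theta uncertainty.
#' @param nResample resamples for joint propagation.
#' @param seed seed for the resampling.
#' @return list with \code{ageYears}, \code{ciYears} (length 2), \code{Nf},
#'   \code{muPerGeneration} and the parameters used.
#' @export
cloneAgeYears <- function(tmrca, theta, params, thetaProfile = NULL,
                          nResample = 2000L, seed = 1L) {
  stopifnot(is(tmrca, "TmrcaEstimate"), is(params, "CalibrationParams"))
  if (is.na(params@rate) || params@rate <= 0)
    stop("params@rate must be a positive substitution rate (subst/site/MYA)")
  if (params@L <= 0 || params@g <= 0) stop("L and g must be positive")
  if (theta <= 0) stop("theta must be positive")
  muGen <- params@rate / MYA_IN_YEARS * params@L * params@g
  toYears <- function(tm, th) tm * th / (2 * muGen) * params@g
  Nf <- theta / (2 * muGen)
  age <- toYears(tmrca@mean, theta)
  ci <- c(toYears(tmrca@ciLow, theta), toYears(tmrca@ciHigh, theta))
  if (!is.null(thetaProfile)) {
    set.seed(seed)
    w <- exp(thetaProfile$loglik - max(thetaProfile$loglik))
    th <- sample(thetaProfile$theta, nResample, replace = TRUE, prob = w)
    tm <- runif(nResample, tmrca@ciLow, tmrca@ciHigh)  # flat over the CI
    yrs <- toYears(tm, th)
    ci <- as.numeric(quantile(yrs, c(0.025, 0.975), names = FALSE))
  }
  list(ageYears = age, ciYears = ci, Nf = Nf, muPerGeneration = muGen,
       params = list(g = params@g, L = params@L, rate = params@rate,
                     theta = theta))
}

#' Convert tau samples to absolute divergence times
#'
#' Speciation times estimated in expected substitutions/site are rescaled to
#' MYA through the outgroup split: tau_abs = tau / tau_outgroup x
#' outgroup_age, applied per posterior sample.
#'
#' @param tauSamples numeric vector or matrix of tau posterior samples.
#' @param tauOutgroupSplit tau of the ingroup--outgroup split (> 0), same
#'   units as \code{tauSamples}.
#' @param outgroupAge absolute age of that split in MYA.
#' @return list with \code{samplesMYA} (same shape as input) and
#'   \code{summary}, a \code{PosteriorSummary} of the converted samples.
#' @export
absoluteSpeciationTimes <- function(tauSamples, tauOutgroupSplit,
                                    outgroupAge) {
  if (!(tauOutgroupSplit > 0)) stop("tauOutgroupSplit must be > 0")
  if (!(outgroupAge > 0)) stop("outgroupAge must be > 0")
  scaled <- tauSamples / tauOutgroupSplit * outgroupAge
  m <- as.matrix(scaled)
  if (is.null(colnames(m)))
    colnames(m) <- if (ncol(m) == 1L) "tau" else paste0("tau", seq_len(ncol(m)))
  list(samplesMYA = scaled, summary = summarizePosterior(m, seed = NA_integer_,
                                                         settings = list()))
}
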