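#' Build a HaplotypeSample from a binary site matrix
#'
#' Collapses identical sequence columns into distinct haplotypes with
#' multiplicities and drops nothing else; invariant sites are rejected by the
#' class validity check.
#'
#' @param siteMatrix binary matrix, rows = segregating sites, columns =
#'   sequences (one column per sampled sequence) or distinct haplotypes when
#'   \code{multiplicities} is given.
#' @param multiplicities optional integer vector of copies per column; when
#'   omitted every column counts once and duplicates are collapsed.
#' @return a \code{HaplotypeSample}.
#' @export
haplotypeSample <- function(siteMatrix, multiplicities = NULL) {
  m <- as.matrix(siteMatrix)
  if (length(m)) mode(m) <- "integer"
  if (is.null(multiplicities)) {
    if (ncol(m) == 0L) stop("need at least one sequence")
    if (nrow(m) == 0L)
      return(new("HaplotypeSample",
                 siteMatrix = matrix(integer(0), 0L, 1L),
                 multiplicities = ncol(m), n = ncol(m)))
    key <- apply(m, 2L, paste, collapse = "")
    tab <- table(factor(key, levels = unique(key)))
    keep <- m[, match(names(tab), key), drop = FALSE]
    new("HaplotypeSample", siteMatrix = keep,
        multiplicities = as.integer(tab), n = as.integer(ncol(m)))
  } else {
    new("HaplotypeSample", siteMatrix = m,
        multiplicities = as.integer(multiplicities),
        n = as.integer(sum(multiplicities)))
  }
}

#' Read a haplotype sample from FASTA or a 0/1 site-matrix TSV
#'
#' FASTA input is reduced to biallelic segregating sites: each polymorphic
#' column with exactly two states becomes a 0/1 site (majority state coded 0);
#' columns with more than two states are rejected as incompatible with the
#' infinite-sites model.
#'
#' @param path input file; format guessed from extension (.fa/.fasta vs TSV).
#' @return a \code{HaplotypeSample}.
#' @export
readHaplotypeSample <- function(path) {
  if (grepl("\\.(fa|fasta|fas)$", path, ignore.case = TRUE)) {
    dna <- ape::read.FASTA(path)
    chars <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
    if (is.null(dim(chars))) chars <- matrix(chars, nrow = 1L)
    sites <- list()
    for (j in seq_len(ncol(chars))) {
      col <- chars[, j]
      states <- unique(col)
      if (length(states) == 1L) next
      if (length(states) > 2L)
        stop("alignment column ", j, " has >2 states; ",
             "not reducible to a biallelic infinite-sites matrix")
      major <- names(sort(table(col), decreasing = TRUE))[1L]
      sites[[length(sites) + 1L]] <- as.integer(col != major)
    }
    m <- if (length(sites)) do.call(rbind, sites)
         else matrix(integer(0), 0L, nrow(chars))
    haplotypeSample(m)
  } else {
    m <- as.matrix(read.delim(path, header = FALSE))
    haplotypeSample(m)
  }
}

#' Four-gamete (infinite-sites) compatibility check
#'
#' Two biallelic sites are incompatible with a single non-recurrent mutation
#' history when all four gametes 00, 01, 10, 11 occur in the sample.
#'
#' @param sample a \code{HaplotypeSample}.
#' @return logical \code{TRUE} when every site pair passes; attribute
#'   \code{conflicts} lists the failing site pairs (matrix with columns
#'   site1, site2).
#' @export
checkInfiniteSites <- function(sample) {
  stopifnot(is(sample, "HaplotypeSample"))
  m <- sample@siteMatrix
  S <- nrow(m)
  conflicts <- matrix(integer(0), 0L, 2L,
                      dimnames = list(NULL, c("site1", "site2")))
  if (S >= 2L) {
    for (i in seq_len(S - 1L)) {
      for (j in seq(i + 1L, S)) {
        pat <- unique(m[i, ] * 2L + m[j, ])
        if (all(c(0L, 1L, 2L, 3L) %in% pat))
          conflicts <- rbind(conflicts, c(i, j))
      }
    }
  }
  ok <- nrow(conflicts) == 0L
  attr(ok, "conflicts") <- conflicts
  ok
}

#' Ewens infinite-alleles ML estimate of theta
#'
#' Solves \eqn{k = \sum_{i=0}^{n-1} \theta/(\theta+i)} for theta, the
#' maximum-likelihood equation for the number of distinct haplotypes k under
#' the infinite-alleles model. A monomorphic sample gives 0; all-distinct
#' haplotypes (k = n) put the maximum at infinity, flagged as unbounded.
#'
#' @param n sample size.
#' @param k number of distinct haplotypes, 1 <= k <= n.
#' @param tol root-finder tolerance.
#' @return list with \code{theta} and logical \code{unbounded}.
#' @export
ewensMLTheta <- function(n, k, tol = 1e-9) {
  stopifnot(n >= 1, k >= 1)
  if (k > n) stop("k must not exceed n")
  if (k == 1L) return(list(theta = 0, unbounded = FALSE))
  if (k == n) return(list(theta = Inf, unbounded = TRUE))
  f <- function(th) sum(th / (th + 0:(n - 1L))) - k
  up <- 1
  while (f(up) < 0) up <- up * 2
  r <- uniroot(f, c(1e-12, up), tol = tol)
  list(theta = r$root, unbounded = FALSE)
}

runSIS <- function(sample, theta, nParticles) {
  .sis_run_cpp(sample@siteMatrix, sample@multiplicities, theta,
               as.integer(nParticles))
}

#' Importance-sampling estimate of the sample log-likelihood
#'
#' Griffiths-Tavare sequential importance sampling over genealogical
#' histories under the infinite-sites coalescent with mutation rate theta/2
#' per lineage per coalescent time unit. The estimator is unbiased on the
#' probability scale; the Monte Carlo standard error is reported on the log
#' scale (delta method). A sample can pass the pairwise four-gamete test yet
#' be incompatible with a rooted perfect phylogeny (carrier sets overlapping
#' without nesting, ancestral state 0); such samples have probability
#' exactly zero and yield \code{loglik = -Inf}.
#'
#' @param sample a \code{HaplotypeSample} passing
#'   \code{\link{checkInfiniteSites}}.
#' @param theta scaled mutation rate (2 N_f mu per locus), >= 0.
#' @param nParticles number of importance-sampling particles.
#' @param seed integer seed.
#' @return list with \code{loglik}, \code{mcse} (log-scale) and
#'   \code{nParticles}.
#' @export
sisLoglik <- function(sample, theta, nParticles = 1e5, seed = 1L) {
  stopifnot(is(sample, "HaplotypeSample"), theta >= 0, nParticles >= 1)
  if (!isTRUE(as.logical(checkInfiniteSites(sample))))
    stop("sample fails the four-gamete test; incompatible with infinite sites")
  if (theta == 0 && nrow(sample@siteMatrix) > 0L)
    return(list(loglik = -Inf, mcse = 0, nParticles = as.integer(nParticles)))
  set.seed(seed)
  r <- runSIS(sample, theta, nParticles)
  lw <- r$logw
  if (!any(is.finite(lw)))   # incompatible with a rooted perfect phylogeny:
    return(list(loglik = -Inf, mcse = 0,   # the sample has probability zero
                nParticles = as.integer(nParticles)))
  ll <- logSumExp(lw) - log(nParticles)
  # relative MC se of the mean weight
  w <- exp(lw - max(lw[is.finite(lw)]))
  relse <- stats::sd(w) / (mean(w) * sqrt(nParticles))
  list(loglik = ll, mcse = relse, nParticles = as.integer(nParticles))
}

#' Profile the SIS likelihood over a theta grid
#'
#' Evaluates the importance-sampling log-likelihood on a grid of theta values
#' using common random numbers (the same seed at every grid point), takes the
#' grid argmax and refines it by golden-section search between the
#' neighbouring grid points.
#'
#' @param sample a \code{HaplotypeSample}.
#' @param thetaGrid numeric grid; default log-spaced 0.05..50.
#' @param nParticles particles per evaluation.
#' @param seed integer seed shared across evaluations.
#' @param refine logical: golden-section refinement of the argmax.
#' @return a \code{ThetaEstimate}.
#' @export
mlThetaProfile <- function(sample, thetaGrid = exp(seq(log(0.05), log(50),
                                                       length.out = 25)),
                           nParticles = 1e4, seed = 1L, refine = TRUE) {
  stopifnot(length(thetaGrid) >= 1)
  thetaGrid <- sort(thetaGrid)
  evalLL <- function(th) sisLoglik(sample, th, nParticles, seed)
  prof <- lapply(thetaGrid, evalLL)
  ll <- vapply(prof, `[[`, numeric(1L), "loglik")
  se <- vapply(prof, `[[`, numeric(1L), "mcse")
  profile <- data.frame(theta = thetaGrid, loglik = ll, mcse = se)
  k <- ncol(sample@siteMatrix)
  unbounded <- (k == sample@n && nrow(sample@siteMatrix) > 0L &&
                which.max(ll) == length(thetaGrid))
  best <- which.max(ll)
  thetaBest <- thetaGrid[best]
  llBest <- ll[best]
  if (refine && length(thetaGrid) >= 3L && best > 1L &&
      best < length(thetaGrid)) {
    lo <- log(thetaGrid[best - 1L]); hi <- log(thetaGrid[best + 1L])
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- evalLL(exp(x1))$loglik; f2 <- evalLL(exp(x2))$loglik
    for (it in seq_len(15L)) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- evalLL(exp(x2))$loglik
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- evalLL(exp(x1))$loglik
      }
    }
    cand <- if (f1 > f2) c(exp(x1), f1) else c(exp(x2), f2)
    if (cand[2L] > llBest) { thetaBest <- cand[1L]; llBest <- cand[2L] }
  }
  new("ThetaEstimate", thetaHat = thetaBest, profile = profile,
      unbounded = unbounded)
}

#' Importance-weighted TMRCA posterior
#'
#' Runs the same sequential importance sampler and summarises the genealogy
#' height of each particle with its importance weight: weighted mean and
#' weighted 2.5/97.5 percentile interval, in coalescent units of N_f
#' generations.
#'
#' @param sample a \code{HaplotypeSample}.
#' @param theta scaled mutation rate (typically the profile ML value).
#' @param nParticles particle count (default 1e5).
#' @param seed integer seed.
#' @return a \code{TmrcaEstimate}.
#' @export
tmrcaPosterior <- function(sample, theta, nParticles = 1e5, seed = 1L) {
  stopifnot(is(sample, "HaplotypeSample"), theta >= 0, nParticles >= 1)
  if (!isTRUE(as.logical(checkInfiniteSites(sample))))
    stop("sample fails the four-gamete test; incompatible with infinite sites")
  if (theta == 0 && nrow(sample@siteMatrix) > 0L)
    stop("theta = 0 is incompatible with segregating sites")
  set.seed(seed)
  r <- runSIS(sample, theta, nParticles)
  keep <- is.finite(r$logw)
  if (!any(keep)) stop("all particles have zero weight")
  w <- exp(r$logw[keep] - max(r$logw[keep]))
  h <- r$height[keep]
  ci <- weightedQuantile(h, w, c(0.025, 0.975))
  new("TmrcaEstimate", mean = sum(w * h) / sum(w),
      ciLow = ci[1L], ciHigh = ci[2L],
      nParticles = as.integer(nParticles), seed = as.integer(seed))
}
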