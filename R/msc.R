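MSC_PARAM_NAMES <- c("tau_TNE", "tau_TN", "theta_E", "theta_T", "theta_N",
                     "theta_TN", "theta_TNE")

#' Construct an MSCModel
#'
#' @param tauTNE,tauTN divergence times in expected substitutions/site,
#'   0 < tauTN < tauTNE.
#' @param thetaE,thetaT,thetaN,thetaTN,thetaTNE population mutation
#'   parameters (4 Ne mu), > 0.
#' @return an \code{MSCModel} for the fixed topology ((T,N),E).
#' @export
MSCModel <- function(tauTNE, tauTN, thetaE, thetaT, thetaN, thetaTN,
                     thetaTNE) {
  new("MSCModel", tauTNE = tauTNE, tauTN = tauTN, thetaE = thetaE,
      thetaT = thetaT, thetaN = thetaN, thetaTN = thetaTN,
      thetaTNE = thetaTNE)
}

compressPatterns <- function(bases) {
  key <- apply(bases, 2L, paste, collapse = ".")
  tab <- table(factor(key, levels = unique(key)))
  list(patterns = bases[, match(names(tab), key), drop = FALSE],
       weights = as.numeric(tab))
}

#' JC69 log-likelihood of an alignment on a gene tree
#'
#' Felsenstein pruning under Jukes-Cantor (stationary frequencies 1/4) on
#' compressed site patterns. Branch lengths are node-time differences times
#' the locus rate scalar.
#'
#' @param geneTree internal gene-tree structure (\code{parent}, \code{time},
#'   \code{nTip}, \code{root}), as produced by the MSC simulator/sampler.
#' @param bases integer matrix (tips x sites) with bases coded 0..3
#'   (negative = missing).
#' @param scalar locus rate scalar multiplying every branch.
#' @return log-likelihood.
#' @export
jc69Loglik <- function(geneTree, bases, scalar = 1) {
  stopifnot(nrow(bases) == geneTree$nTip, scalar > 0)
  pat <- compressPatterns(bases)
  .jc69_tree_cpp(geneTree$parent, geneTree$time, geneTree$nTip,
                 geneTree$root, scalar, pat$patterns, pat$weights)
}

jcDistance <- function(x, y, correct = TRUE) {
  ok <- x >= 0 & y >= 0
  p <- mean(x[ok] != y[ok])
  if (!correct) return(p)
  if (p >= 0.745) p <- 0.745       # guard against saturation blow-up
  -0.75 * log(1 - 4 * p / 3)
}

#' Per-locus mutation rate scalars from outgroup distances
#'
#' The relative substitution rate of each locus is the mean ingroup-outgroup
#' distance at that locus divided by the grand mean over loci, so the
#' scalars average to one.
#'
#' @param loci list of loci (each with \code{bases}, \code{species}).
#' @param outgroup list of outgroup base matrices (rows = outgroup
#'   sequences), one per locus, aligned to the locus.
#' @param corrected use JC-corrected distances (default) or raw p-distances.
#' @return numeric vector of scalars, mean 1.
#' @export
computeRateScalars <- function(loci, outgroup, corrected = TRUE) {
  if (length(outgroup) != length(loci))
    stop("one outgroup matrix per locus is required")
  d <- vapply(seq_along(loci), function(i) {
    og <- outgroup[[i]]
    if (is.null(og) || length(og) == 0L)
      stop("locus ", i, " has no outgroup sequence")
    if (is.vector(og)) og <- matrix(og, nrow = 1L)
    ing <- loci[[i]]$bases
    mean(vapply(seq_len(nrow(ing)), function(a) {
      mean(vapply(seq_len(nrow(og)),
                  function(b) jcDistance(ing[a, ], og[b, ], corrected),
                  numeric(1L)))
    }, numeric(1L)))
  }, numeric(1L))
  if (mean(d) <= 0) stop("outgroup distances are all zero")
  d / mean(d)
}

## ---- MSC coalescent density ------------------------------------------------

## species set below each node as a collapsed sorted string ("T", "NT",
## "ENT", ...); cached on the gene tree because it only changes with
## topology, never with node times
annotateSpeciesSets <- function(gt) {
  nNode <- 2L * gt$nTip - 1L
  sets <- vector("list", nNode)
  for (i in seq_len(gt$nTip)) sets[[i]] <- gt$tipSpecies[i]
  internal <- setdiff(seq_len(nNode), seq_len(gt$nTip))
  for (v in internal[order(gt$time[internal])]) {
    ch <- which(gt$parent == v)
    sets[[v]] <- sort(unique(unlist(sets[ch])))
  }
  gt$ss <- vapply(sets, paste, character(1L), collapse = "")
  gt$ssCode <- ifelse(gt$ss == "T", 0L,
               ifelse(gt$ss == "N", 1L,
               ifelse(gt$ss == "E", 2L,
               ifelse(gt$ss == "NT", 3L, 4L))))
  gt$tipCode <- ifelse(gt$tipSpecies == "T", 0L,
                ifelse(gt$tipSpecies == "N", 1L, 2L))
  gt
}

popOfNode <- function(time, ss, tauTN, tauTNE) {
  if (time >= tauTNE) return("TNE")
  if (time >= tauTN) {
    if (ss %in% c("T", "N", "NT")) return("TN")
    if (ss == "E") return("E")
    return(NA_character_)
  }
  if (ss %in% c("T", "N", "E")) return(ss)
  NA_character_
}

## log density of a gene tree under the MSC; -Inf when the tree violates the
## species-tree constraints (computed in C++; theta order T, N, E, TN, TNE)
mscLogDensity <- function(gt, model) {
  if (is.null(gt$ssCode)) gt <- annotateSpeciesSets(gt)
  .msc_density_cpp(gt$time, gt$ssCode, gt$nTip, gt$tipCode,
                   model@tauTN, model@tauTNE,
                   c(model@thetaT, model@thetaN, model@thetaE,
                     model@thetaTN, model@thetaTNE))
}

## ---- priors ----------------------------------------------------------------

## gamma(2, 2/mean) on tau_TNE and each theta; tau_TN | tau_TNE uniform
defaultPriors <- function(tauMean, thetaMean) {
  list(tauShape = 2, tauRate = 2 / tauMean,
       thetaShape = 2, thetaRate = 2 / thetaMean)
}

mscLogPrior <- function(model, priors) {
  lp <- dgamma(model@tauTNE, priors$tauShape, rate = priors$tauRate,
               log = TRUE)
  if (model@tauTN <= 0 || model@tauTN >= model@tauTNE) return(-Inf)
  lp <- lp - log(model@tauTNE)   # tau_TN ~ Uniform(0, tau_TNE)
  th <- c(model@thetaE, model@thetaT, model@thetaN, model@thetaTN,
          model@thetaTNE)
  lp + sum(dgamma(th, priors$thetaShape, rate = priors$thetaRate, log = TRUE))
}

## crude hyper-mean heuristics from the data
priorHyperMeans <- function(loci) {
  between <- c(); within <- c()
  for (lc in loci) {
    sp <- lc$species
    for (a in seq_len(nrow(lc$bases) - 1L)) {
      for (b in seq(a + 1L, nrow(lc$bases))) {
        d <- jcDistance(lc$bases[a, ], lc$bases[b, ])
        if ((sp[a] == "E") != (sp[b] == "E")) between <- c(between, d)
        if (sp[a] == sp[b]) within <- c(within, d)
      }
    }
  }
  list(tauMean = max(mean(between) / 2, 1e-4),
       thetaMean = max(mean(within), 1e-4))
}

## ---- MCMC ------------------------------------------------------------------

modelAsVector <- function(model) {
  setNames(c(model@tauTNE, model@tauTN, model@thetaE, model@thetaT,
             model@thetaN, model@thetaTN, model@thetaTNE), MSC_PARAM_NAMES)
}

#' MCMC under the multispecies coalescent for ((T,N),E)
#'
#' Metropolis-within-Gibbs sampler over the species-tree parameters
#' (tau_TNE, tau_TN and five thetas) and the per-locus coalescent gene
#' trees: gene-tree re-simulation from the coalescent prior and node-time
#' slides; theta multipliers; a global scale move on (tau, theta, times);
#' and a tau_TN slide that linearly rescales the coalescent times contained
#' in the affected populations. Sequences are modelled as JC69 with fixed
#' per-locus rate scalars.
#'
#' @param loci list of loci (\code{bases}, \code{species}) or \code{NULL}
#'   for a prior-only run.
#' @param scalars per-locus rate scalars (default all 1).
#' @param priors list as from \code{defaultPriors}; when \code{NULL},
#'   hyper-means are set from pairwise-distance heuristics (data runs) and
#'   must be supplied for prior-only runs.
#' @param chain list: \code{iterations}, \code{burninFrac} (default 0.25),
#'   \code{retain} (post-thinning samples, default 2000), \code{essFloor}.
#' @param seqsPerSpecies haplotypes per species for prior-only runs.
#' @param seed integer seed.
#' @return matrix of retained samples (columns tau_TNE, tau_TN, theta_*),
#'   with attributes \code{ess}, \code{acceptance}, \code{seed},
#'   \code{settings}.
#' @export
mcmcMSC <- function(loci, scalars = NULL, priors = NULL,
                    chain = list(), seqsPerSpecies = 2L, seed = 1L) {
  cfg <- modifyList(list(iterations = 8000L, burninFrac = 0.25,
                         retain = 2000L, essFloor = 50), chain)
  set.seed(seed)
  nLoci <- length(loci)
  if (is.null(scalars)) scalars <- rep(1, max(nLoci, 1L))
  if (nLoci > 0L) {
    scalars <- rep_len(scalars, nLoci)
    pats <- lapply(loci, function(lc) compressPatterns(lc$bases))
    seqsPerSpecies <- as.integer(sum(loci[[1L]]$species == "T"))
    if (is.null(priors)) {
      hm <- priorHyperMeans(loci)
      priors <- defaultPriors(hm$tauMean, hm$thetaMean)
    }
  } else if (is.null(priors)) {
    stop("priors must be supplied for a prior-only run")
  }

  tauMean <- priors$tauShape / priors$tauRate
  thMean <- priors$thetaShape / priors$thetaRate
  model <- MSCModel(tauTNE = tauMean, tauTN = tauMean / 2,
                    thetaE = thMean, thetaT = thMean, thetaN = thMean,
                    thetaTN = thMean, thetaTNE = thMean)

  gts <- vector("list", nLoci)
  lik <- numeric(nLoci)
  if (nLoci > 0L) {
    for (i in seq_len(nLoci)) {
      gts[[i]] <- simulateGeneTree(model, seqsPerSpecies)
      lik[i] <- locusLik(gts[[i]], pats[[i]], scalars[i])
    }
  }
  dens <- vapply(gts, mscLogDensity, numeric(1L), model = model)
  if (nLoci == 0L) dens <- numeric(0)
  lp <- mscLogPrior(model, priors)

  nKeepIter <- cfg$iterations - floor(cfg$iterations * cfg$burninFrac)
  thinBy <- max(1L, floor(nKeepIter / cfg$retain))
  out <- matrix(NA_real_, 0L, length(MSC_PARAM_NAMES))
  acc <- c(resim = 0, slide = 0, theta = 0, scale = 0, tautn = 0)
  prop <- c(resim = 0, slide = 0, theta = 0, scale = 0, tautn = 0)
  samples <- vector("list", 0L)

  setTheta <- function(m, j, val) {
    s <- c("thetaE", "thetaT", "thetaN", "thetaTN", "thetaTNE")[j]
    slot(m, s) <- val
    m
  }
  getTheta <- function(m, j)
    c(m@thetaE, m@thetaT, m@thetaN, m@thetaTN, m@thetaTNE)[j]

  for (it in seq_len(cfg$iterations)) {
    ## 1. gene-tree re-simulation from the MSC prior (independence move)
    for (i in seq_len(nLoci)) {
      gtNew <- simulateGeneTree(model, seqsPerSpecies)
      likNew <- locusLik(gtNew, pats[[i]], scalars[i])
      prop["resim"] <- prop["resim"] + 1
      if (log(runif(1L)) < likNew - lik[i]) {
        gts[[i]] <- gtNew
        lik[i] <- likNew
        dens[i] <- mscLogDensity(gtNew, model)
        acc["resim"] <- acc["resim"] + 1
      }
    }
    ## 2. node-time slides
    for (i in seq_len(nLoci)) {
      for (rep in seq_len(2L)) {
        upd <- nodeSlide(gts[[i]], model, pats[[i]], scalars[i], lik[i],
                         dens[i])
        prop["slide"] <- prop["slide"] + 1
        if (upd$accepted) {
          gts[[i]] <- upd$gt; lik[i] <- upd$lik; dens[i] <- upd$dens
          acc["slide"] <- acc["slide"] + 1
        }
      }
    }
    ## 3. theta multipliers
    for (j in seq_len(5L)) {
      thOld <- getTheta(model, j)
      c0 <- exp(0.8 * (runif(1L) - 0.5))
      mNew <- setTheta(model, j, thOld * c0)
      densNew <- if (nLoci > 0L)
        vapply(gts, mscLogDensity, numeric(1L), model = mNew) else numeric(0)
      lpNew <- mscLogPrior(mNew, priors)
      prop["theta"] <- prop["theta"] + 1
      if (log(runif(1L)) <
          (lpNew + sum(densNew)) - (lp + sum(dens)) + log(c0)) {
        model <- mNew; dens <- densNew; lp <- lpNew
        acc["theta"] <- acc["theta"] + 1
      }
    }
    ## 4. global scale on (tau, theta, gene-tree times)
    {
      c0 <- exp(0.4 * (runif(1L) - 0.5))
      mNew <- model
      mNew@tauTNE <- model@tauTNE * c0
      mNew@tauTN <- model@tauTN * c0
      for (j in seq_len(5L)) mNew <- setTheta(mNew, j, getTheta(mNew, j) * c0)
      gtsNew <- lapply(gts, function(g) { g$time <- g$time * c0; g })
      likNew <- if (nLoci > 0L)
        vapply(seq_len(nLoci), function(i)
          locusLik(gtsNew[[i]], pats[[i]], scalars[i]), numeric(1L))
        else numeric(0)
      densNew <- if (nLoci > 0L)
        vapply(gtsNew, mscLogDensity, numeric(1L), model = mNew)
        else numeric(0)
      lpNew <- mscLogPrior(mNew, priors)
      nTimes <- if (nLoci > 0L)
        sum(vapply(gts, function(g) g$nTip - 1L, integer(1L))) else 0L
      prop["scale"] <- prop["scale"] + 1
      if (log(runif(1L)) <
          (lpNew + sum(densNew) + sum(likNew)) -
          (lp + sum(dens) + sum(lik)) + (nTimes + 7) * log(c0)) {
        model <- mNew; gts <- gtsNew; dens <- densNew; lp <- lpNew
        lik <- likNew
        acc["scale"] <- acc["scale"] + 1
      }
    }
    ## 5. tau_TN slide with linear rescaling of contained times
    {
      u <- model@tauTN
      w <- 0.3 * model@tauTNE
      uNew <- u + w * (runif(1L) - 0.5)
      # reflect into (0, tau_TNE)
      if (uNew < 0) uNew <- -uNew
      if (uNew > model@tauTNE) uNew <- 2 * model@tauTNE - uNew
      prop["tautn"] <- prop["tautn"] + 1
      if (uNew > 0 && uNew < model@tauTNE) {
        mNew <- model; mNew@tauTN <- uNew
        rlow <- uNew / u
        rhigh <- (model@tauTNE - uNew) / (model@tauTNE - u)
        nLow <- 0L; nHigh <- 0L
        gtsNew <- gts
        if (nLoci > 0L) {
          for (i in seq_len(nLoci)) {
            g <- gts[[i]]
            internal <- setdiff(seq_along(g$parent), seq_len(g$nTip))
            for (v in internal) {
              tv <- g$time[v]
              if (tv >= model@tauTNE || g$ss[v] == "E") next
              if (tv < u) {             # inside T or N
                g$time[v] <- tv * rlow; nLow <- nLow + 1L
              } else {                  # inside TN
                g$time[v] <- model@tauTNE - (model@tauTNE - tv) * rhigh
                nHigh <- nHigh + 1L
              }
            }
            gtsNew[[i]] <- g
          }
        }
        likNew <- if (nLoci > 0L)
          vapply(seq_len(nLoci), function(i)
            locusLik(gtsNew[[i]], pats[[i]], scalars[i]), numeric(1L))
          else numeric(0)
        densNew <- if (nLoci > 0L)
          vapply(gtsNew, mscLogDensity, numeric(1L), model = mNew)
          else numeric(0)
        lpNew <- mscLogPrior(mNew, priors)
        lJac <- nLow * log(rlow) + nHigh * log(rhigh)
        if (log(runif(1L)) <
            (lpNew + sum(densNew) + sum(likNew)) -
            (lp + sum(dens) + sum(lik)) + lJac) {
          model <- mNew; gts <- gtsNew; dens <- densNew; lp <- lpNew
          lik <- likNew
          acc["tautn"] <- acc["tautn"] + 1
        }
      }
    }
    if (it > cfg$iterations * cfg$burninFrac &&
        ((it - floor(cfg$iterations * cfg$burninFrac)) %% thinBy == 0L)) {
      samples[[length(samples) + 1L]] <- modelAsVector(model)
    }
  }
  out <- do.call(rbind, samples)
  colnames(out) <- MSC_PARAM_NAMES
  ess <- apply(out, 2L, essAutocorr)
  if (any(ess < cfg$essFloor))
    warning("low effective sample size (min ", round(min(ess), 1),
            " < floor ", cfg$essFloor, "); inspect the chain before use")
  attr(out, "ess") <- ess
  attr(out, "acceptance") <- ifelse(prop > 0, acc / prop, NA)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "settings") <- cfg
  out
}

locusLik <- function(gt, pat, scalar) {
  .jc69_tree_cpp(gt$parent, gt$time, gt$nTip, gt$root, scalar,
                 pat$patterns, pat$weights)
}

nodeSlide <- function(gt, model, pat, scalar, likOld, densOld) {
  internal <- setdiff(seq_along(gt$parent), seq_len(gt$nTip))
  v <- internal[sample.int(length(internal), 1L)]
  p <- popOfNode(gt$time[v], gt$ss[v], model@tauTN, model@tauTNE)
  bounds <- switch(p,
    T = c(0, model@tauTN), N = c(0, model@tauTN), E = c(0, model@tauTNE),
    TN = c(model@tauTN, model@tauTNE), TNE = c(model@tauTNE, Inf))
  ch <- which(gt$parent == v)
  lo <- max(c(bounds[1L], gt$time[ch]))
  par <- gt$parent[v]
  up <- min(c(bounds[2L], if (par > 0L) gt$time[par] else Inf))
  lHast <- 0
  if (is.finite(up)) {
    tNew <- runif(1L, lo, up)
  } else {
    tNew <- lo + (gt$time[v] - lo) * exp(runif(1L) - 0.5)
    lHast <- log((tNew - lo) / (gt$time[v] - lo))
  }
  gtNew <- gt
  gtNew$time[v] <- tNew
  likNew <- locusLik(gtNew, pat, scalar)
  densNew <- mscLogDensity(gtNew, model)
  accepted <- log(runif(1L)) <
    (likNew + densNew) - (likOld + densOld) + lHast
  if (accepted) list(accepted = TRUE, gt = gtNew, lik = likNew,
                     dens = densNew)
  else list(accepted = FALSE)
}

#' Summarise posterior samples
#'
#' Means, 2.5/97.5 percentile intervals and autocorrelation-time effective
#' sample sizes per parameter.
#'
#' @param samples numeric matrix of MCMC samples (columns = parameters), or
#'   the output of \code{\link{mcmcMSC}}.
#' @param seed seed to record; defaults to the \code{seed} attribute.
#' @param settings chain settings to record.
#' @return a \code{PosteriorSummary}.
#' @export
summarizePosterior <- function(samples, seed = attr(samples, "seed"),
                               settings = attr(samples, "settings")) {
  m <- as.matrix(samples)
  if (nrow(m) == 0L) stop("no samples to summarise")
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  s <- data.frame(
    mean = colMeans(m),
    q2.5 = apply(m, 2L, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(m, 2L, quantile, probs = 0.975, names = FALSE),
    ess = apply(m, 2L, essAutocorr),
    row.names = colnames(m))
  new("PosteriorSummary", summary = s, nSamples = nrow(m),
      seed = as.integer(if (is.null(seed)) NA_integer_ else seed),
      settings = if (is.null(settings)) list() else settings)
}
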