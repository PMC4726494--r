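## subtree height (max distance to a descendant tip, in input branch-length
## units) for every node
nodeHeightsPhylogram <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  h <- numeric(length(phy$tip.label) + phy$Nnode)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    h[par] <- max(h[par], h[ch] + po$edge.length[e])
  }
  h
}

#' Penalized-likelihood objective for rate-smoothed dating
#'
#' The Poisson log-likelihood of the per-branch substitution counts
#' x_j = b_j L (kept continuous, log-gamma generalised factorial) with mean
#' r_j t_j L, minus lambda times the rate-roughness penalty: the squared
#' rate difference between every non-root branch and its parent branch,
#' plus the variance of the rates of the root's child branches.
#'
#' @param phy rooted \code{phylo} with branch lengths in substitutions/site.
#' @param ages numeric node ages (tips first, then internal nodes); tips 0.
#' @param rates per-edge rates (rows of \code{phy$edge}),
#'   substitutions/site/MYA.
#' @param lambda smoothing parameter, >= 0.
#' @param L number of sites.
#' @param minBranch floor applied to input branch lengths
#'   (substitutions/site) so zero-length branches keep a finite Poisson term.
#' @return penalized log-likelihood (higher is better).
#' @export
plObjective <- function(phy, ages, rates, lambda, L = 1140,
                        minBranch = 1e-8) {
  stopifnot(inherits(phy, "phylo"), length(rates) == nrow(phy$edge),
            lambda >= 0, L > 0)
  dur <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(dur <= 0)) stop("non-positive branch duration; ages must respect the topology")
  x <- pmax(phy$edge.length, minBranch) * L
  mu <- rates * dur * L
  ll <- sum(x * log(mu) - mu - lgamma(x + 1))
  parentEdge <- match(phy$edge[, 1L], phy$edge[, 2L])
  inner <- !is.na(parentEdge)
  rough <- sum((rates[inner] - rates[parentEdge[inner]])^2)
  rootChildren <- rates[!inner]
  if (length(rootChildren) > 1L) rough <- rough + var(rootChildren)
  ll - lambda * rough
}

calibrationNode <- function(phy, calibration) {
  tips <- calibration$tips
  if (is.null(tips) || is.null(calibration$age))
    stop("calibration must be list(tips = <tip labels>, age = <MYA>)")
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx))
    stop("calibration tip(s) not in tree: ",
         paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L)
    stop("calibration needs at least two tips to define an MRCA")
  ape::getMRCA(phy, idx)
}

## ages from proportional-depth fractions: raw root age 1, each internal
## node a fraction of its parent's age, everything rescaled so the
## calibration node sits exactly at its age
agesFromFractions <- function(phy, frac, calibNode, calibAge) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  raw <- numeric(ntip + nnode)
  raw[root] <- 1
  co <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(co$edge))) {
    ch <- co$edge[e, 2L]
    if (ch > ntip) raw[ch] <- raw[co$edge[e, 1L]] * frac[ch - ntip - 1L]
  }
  raw * (calibAge / raw[calibNode])
}

#' Fit an ultrametric chronogram by penalized likelihood
#'
#' Maximizes \code{\link{plObjective}} over node ages and branch rates with
#' the calibration node's age held fixed. Ages are parameterized by
#' proportional depths (each internal node a fraction of its parent's age)
#' so topological ordering holds by construction; rates are log-transformed.
#' Joint quasi-Newton (BFGS) optimization with seeded random restarts.
#'
#' @param phy rooted phylogram (\code{phylo}, substitutions/site), >= 3 tips.
#' @param lambda smoothing parameter.
#' @param calibration \code{list(tips = <labels>, age = <MYA>)}; the MRCA of
#'   \code{tips} is fixed at \code{age}.
#' @param L number of sites.
#' @param nStarts random restarts (first start is deterministic).
#' @param seed integer seed for the restarts.
#' @param minBranch floor for zero-length input branches.
#' @return a \code{Chronogram}.
#' @export
fitChronogram <- function(phy, lambda, calibration, L = 1140, nStarts = 3L,
                          seed = 1L, minBranch = 1e-8) {
  stopifnot(inherits(phy, "phylo"), lambda >= 0)
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("need at least 2 tips to fit")
  if (is.null(phy$edge.length)) stop("phylogram must have branch lengths")
  phy <- ape::reorder.phylo(phy, "cladewise")
  nnode <- phy$Nnode
  root <- ntip + 1L
  calibNode <- calibrationNode(phy, calibration)
  calibAge <- calibration$age
  nEdge <- nrow(phy$edge)
  nFrac <- nnode - 1L

  unpack <- function(par) {
    frac <- stats::plogis(par[seq_len(nFrac)])
    rates <- exp(par[nFrac + seq_len(nEdge)])
    ages <- agesFromFractions(phy, frac, calibNode, calibAge)
    list(ages = ages, frac = frac, rates = rates)
  }
  negObj <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    u <- unpack(par)
    if (any(u$rates <= 0) || any(!is.finite(u$ages))) return(1e10)
    v <- tryCatch(-plObjective(phy, u$ages, u$rates, lambda, L, minBranch),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }

  ## ancestor indicator: anc[v, i] = 1 when internal node (root+i) lies on
  ## the path root -> v (inclusive); drives the proportional-depth chain rule
  nNodes <- ntip + nnode
  anc <- matrix(0, nNodes, max(nFrac, 1L))
  if (nFrac > 0L) {
    for (e in seq_len(nEdge)) {        # cladewise: parents before children
      par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      anc[ch, ] <- anc[par, ]
      if (ch > root) anc[ch, ch - root] <- 1
    }
  }
  parentEdge <- match(phy$edge[, 1L], phy$edge[, 2L])
  xCounts <- pmax(phy$edge.length, minBranch) * L
  negGrad <- function(par) {
    u <- unpack(par)
    ages <- u$ages; rates <- u$rates
    dur <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
    if (any(dur <= 0) || any(!is.finite(ages)))
      return(rep(0, length(par)))            # outside the domain; let the
                                             # objective's barrier handle it
    ## d obj / d t_e
    dt <- xCounts / dur - rates * L
    gz <- numeric(nFrac)
    if (nFrac > 0L) {
      ## d a(v) / d z_i = a(v) (1 - f_i) (anc[v,i] - anc[calib,i])
      oneMinusF <- 1 - u$frac
      sens <- sweep(anc, 2L, anc[calibNode, ], "-")   # nNodes x nFrac
      dA <- (ages * sens) * rep(oneMinusF, each = nNodes)
      gz <- colSums(dt * (dA[phy$edge[, 1L], , drop = FALSE] -
                          dA[phy$edge[, 2L], , drop = FALSE]))
    }
    ## d obj / d u_e (log rates)
    dpen <- numeric(nEdge)
    inner <- which(!is.na(parentEdge))
    diffs <- rates[inner] - rates[parentEdge[inner]]
    dpen[inner] <- dpen[inner] + 2 * diffs
    for (k in seq_along(inner))
      dpen[parentEdge[inner[k]]] <- dpen[parentEdge[inner[k]]] - 2 * diffs[k]
    rc <- which(is.na(parentEdge))
    if (length(rc) > 1L)
      dpen[rc] <- dpen[rc] + 2 * (rates[rc] - mean(rates[rc])) /
        (length(rc) - 1L)
    gu <- (xCounts - rates * dur * L - lambda * dpen * rates)
    -c(gz, gu)
  }

  ## deterministic initialisation: ages from subtree heights, rates from the
  ## implied per-branch saturated estimates
  h <- nodeHeightsPhylogram(phy)
  h <- pmax(h, max(h) * 1e-4)
  frac0 <- vapply(seq_len(nnode - 1L), function(i) {
    v <- root + i
    par <- phy$edge[match(v, phy$edge[, 2L]), 1L]
    min(max(h[v] / h[par], 0.02), 0.98)
  }, numeric(1L))
  ages0 <- agesFromFractions(phy, frac0, calibNode, calibAge)
  dur0 <- ages0[phy$edge[, 1L]] - ages0[phy$edge[, 2L]]
  r0 <- pmax(phy$edge.length, minBranch) / dur0
  r0 <- pmin(pmax(r0, 1e-8), 1e2)
  par0 <- c(stats::qlogis(frac0), log(r0))

  ## second deterministic start: one global clock rate (helps large lambda)
  rClock <- sum(pmax(phy$edge.length, minBranch)) / sum(dur0)
  parClock <- c(stats::qlogis(frac0), rep(log(rClock), nEdge))

  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, nStarts) + 1L)) {
    p <- if (s == 1L) par0 else if (s == 2L) parClock
         else par0 + rnorm(length(par0), 0, 0.5)
    fit <- tryCatch(optim(p, negObj, negGrad, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("penalized-likelihood optimization failed for every restart; ",
         "check the input branch lengths and calibration")
  if (best$convergence != 0L)
    warning("optimizer did not report convergence (code ", best$convergence,
            ", value ", signif(-best$value, 8), "); treat ages with caution")
  u <- unpack(best$par)
  out <- phy
  out$edge.length <- u$ages[phy$edge[, 1L]] - u$ages[phy$edge[, 2L]]
  new("Chronogram", phy = out, ages = u$ages, rates = u$rates,
      lambda = lambda, objective = -best$value,
      convergence = as.integer(best$convergence))
}

#' Select the smoothing parameter by leave-one-tip-out cross-validation
#'
#' For every lambda and every tip: the tip is pruned, the chronogram refit,
#' and the tip's expected substitution count predicted from the fitted rate
#' of the branch it had been attached to (pruned fit) and the fitted age of
#' its parent node (same-lambda full fit, which pins the attachment time
#' coherently across the grid). The chi-squared-style score
#' sum((obs - pred)^2 / pred) is minimized over the grid.
#'
#' @param phy rooted phylogram with >= 4 tips.
#' @param lambdaGrid candidate lambdas; default 1e-3..1e3 in half-decade
#'   steps.
#' @param calibration as in \code{\link{fitChronogram}}; tips reduced as
#'   needed when the pruned tip belongs to the calibration set.
#' @param L number of sites.
#' @param nStarts restarts per refit.
#' @param seed integer seed.
#' @return list with \code{lambda} (selected), \code{scores} (data.frame
#'   lambda/score), and \code{fit}, the chronogram refit on the full tree at
#'   the selected lambda.
#' @export
crossValidateLambda <- function(phy, lambdaGrid = 10^seq(-3, 3, by = 0.5),
                                calibration, L = 1140, nStarts = 2L,
                                seed = 1L) {
  if (length(lambdaGrid) == 0L) stop("lambda grid must be non-empty")
  ntip <- length(phy$tip.label)
  if (ntip < 4L) stop("cross-validation needs at least 4 tips")
  phy <- ape::reorder.phylo(phy, "cladewise")
  lambdaGrid <- sort(lambdaGrid)
  scores <- numeric(length(lambdaGrid))
  for (li in seq_along(lambdaGrid)) {
    lam <- lambdaGrid[li]
    full <- fitChronogram(phy, lam, calibration, L, nStarts = nStarts,
                          seed = seed + 7919L * li)
    parentAge <- full@ages[phy$edge[match(seq_len(ntip), phy$edge[, 2L]),
                                    1L]]
    tot <- 0
    for (tip in seq_len(ntip)) {
      pr <- cvPredictTip(phy, tip, lam, calibration, L, nStarts,
                         seed + 1000L * li + tip, parentAge[tip])
      if (is.null(pr)) next
      tot <- tot + (pr$obs - pr$pred)^2 / pr$pred
    }
    scores[li] <- tot
  }
  best <- which.min(scores)
  list(lambda = lambdaGrid[best],
       scores = data.frame(lambda = lambdaGrid, score = scores),
       fit = fitChronogram(phy, lambdaGrid[best], calibration, L,
                           nStarts = max(nStarts, 3L), seed = seed))
}

## prediction for one pruned tip: rate of the attachment branch in the
## reduced fit times the tip's parent-node age (attachTime)
cvPredictTip <- function(phy, tip, lambda, calibration, L, nStarts, seed,
                         attachTime) {
  ntip <- length(phy$tip.label)
  tipLab <- phy$tip.label[tip]
  calTips <- setdiff(calibration$tips, tipLab)
  if (length(calTips) < 2L) return(NULL)
  parentNode <- phy$edge[match(tip, phy$edge[, 2L]), 1L]
  sibTips <- setdiff(phy$tip.label[tipsBelow(phy, parentNode)], tipLab)
  red <- ape::drop.tip(phy, tipLab)
  fit <- tryCatch(
    fitChronogram(red, lambda, list(tips = calTips, age = calibration$age),
                  L, nStarts = nStarts, seed = seed),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  redPhy <- fit@phy
  sibIdx <- match(sibTips, redPhy$tip.label)
  attachNode <- if (length(sibIdx) == 1L) sibIdx
                else ape::getMRCA(redPhy, sibIdx)
  e <- match(attachNode, redPhy$edge[, 2L])
  rate <- if (is.na(e)) {   # tip hung off the root: use the root's children
    rootRed <- length(redPhy$tip.label) + 1L
    mean(fit@rates[redPhy$edge[, 1L] == rootRed])
  } else {
    fit@rates[e]
  }
  obs <- max(phy$edge.length[match(tip, phy$edge[, 2L])], 1e-8) * L
  list(obs = obs, pred = max(rate * attachTime * L, 1e-12))
}

tipsBelow <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  po <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1L]]] <- c(below[[po$edge[e, 1L]]],
                                 below[[po$edge[e, 2L]]])
  below[[node]]
}

#' Average substitution rate over the lineages leading to a tip set
#'
#' Arithmetic mean of the fitted branch rates over the spanning subtree from
#' the tip set's MRCA down to those tips, or over the terminal branches only.
#'
#' @param chronogram a \code{Chronogram}.
#' @param tipSet character tip labels (non-empty).
#' @param terminalOnly average the tips' terminal branches only.
#' @return mean rate, substitutions/site/MYA.
#' @export
lineageAverageRate <- function(chronogram, tipSet, terminalOnly = FALSE) {
  stopifnot(is(chronogram, "Chronogram"), length(tipSet) >= 1L)
  phy <- chronogram@phy
  idx <- match(tipSet, phy$tip.label)
  if (anyNA(idx))
    stop("tip(s) not in chronogram: ",
         paste(tipSet[is.na(idx)], collapse = ", "))
  if (terminalOnly) {
    edges <- match(idx, phy$edge[, 2L])
    return(mean(chronogram@rates[edges]))
  }
  mrca <- if (length(idx) == 1L) idx else ape::getMRCA(phy, idx)
  edges <- integer(0)
  for (t in idx) {
    v <- t
    while (v != mrca) {
      e <- match(v, phy$edge[, 2L])
      edges <- c(edges, e)
      v <- phy$edge[e, 1L]
    }
  }
  mean(chronogram@rates[unique(edges)])
}

#' Write a chronogram as annotated newick
#'
#' Branch lengths are durations in MYA; each branch carries its fitted rate
#' in a \code{[&rate=...]} comment.
#'
#' @param chronogram a \code{Chronogram}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeChronogram <- function(chronogram, path) {
  phy <- chronogram@phy
  ntip <- length(phy$tip.label)
  rec <- function(v) {
    e <- match(v, phy$edge[, 2L])
    suffix <- if (is.na(e)) "" else
      sprintf("[&rate=%.8g]:%.8g", chronogram@rates[e], phy$edge.length[e])
    if (v <= ntip) paste0(phy$tip.label[v], suffix)
    else paste0("(", paste(vapply(phy$edge[phy$edge[, 1L] == v, 2L],
                                  rec, character(1L)), collapse = ","),
                ")", suffix)
  }
  writeLines(paste0(rec(ntip + 1L), ";"), path)
  invisible(path)
}
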