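#' Simulate an infinite-sites coalescent haplotype sample
#'
#' Draws a Kingman genealogy (coalescence rate k(k-1)/2 per coalescent unit
#' of N_f generations), sprinkles Poisson(theta/2 x branch length) mutations
#' on every branch, each creating a new segregating site, and returns the
#' resulting binary haplotype sample together with the generating truth.
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate 2 N_f mu, >= 0.
#' @param seed integer seed.
#' @return list with \code{sample} (a \code{HaplotypeSample}) and
#'   \code{truth} (generator name, parameters, true TMRCA in coalescent
#'   units, segregating-site count, seed).
#' @export
simulateInfiniteSitesSample <- function(n, theta, seed = 1L) {
  stopifnot(n >= 2, theta >= 0)
  set.seed(seed)
  active <- lapply(seq_len(n), identity)   # tip sets per lineage
  start <- rep(0, n)
  t <- 0
  carriers <- list()
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    for (i in pair) {
      len <- t - start[i]
      nm <- rpois(1L, theta / 2 * len)
      if (nm > 0L)
        carriers <- c(carriers, rep(list(active[[i]]), nm))
    }
    merged <- c(active[[pair[1L]]], active[[pair[2L]]])
    active <- c(active[-pair], list(merged))
    start <- c(start[-pair], t)
  }
  S <- length(carriers)
  m <- matrix(0L, S, n)
  for (s in seq_len(S)) m[s, carriers[[s]]] <- 1L
  list(sample = haplotypeSample(m),
       truth = list(generator = "infinite_sites", n = n, theta = theta,
                    tmrca = t, segsites = S, seed = as.integer(seed)))
}

## internal gene-tree representation: tips 1..nTip then internal nodes;
## vectors parent, time (tips 0), tipSpecies; root = node with parent 0
coalesceWithin <- function(lineages, theta, tStart, tEnd, state) {
  t <- tStart
  while (length(lineages) >= 2L) {
    k <- length(lineages)
    t <- t + rexp(1L, k * (k - 1) / 2 * 2 / theta)
    if (t > tEnd) break
    pair <- sample.int(k, 2L)
    state$nodeCount <- state$nodeCount + 1L
    node <- state$nodeCount
    state$parent[lineages[pair]] <- node
    state$time[node] <- t
    lineages <- c(lineages[-pair], node)
  }
  list(lineages = lineages, state = state)
}

simulateGeneTree <- function(model, seqsPerSpecies) {
  nTip <- 3L * seqsPerSpecies
  tipSpecies <- rep(c("T", "N", "E"), each = seqsPerSpecies)
  state <- list(parent = integer(2L * nTip - 1L),
                time = numeric(2L * nTip - 1L),
                nodeCount = nTip)
  tipsOf <- function(sp) which(tipSpecies == sp)
  r <- coalesceWithin(tipsOf("T"), model@thetaT, 0, model@tauTN, state)
  linT <- r$lineages; state <- r$state
  r <- coalesceWithin(tipsOf("N"), model@thetaN, 0, model@tauTN, state)
  linN <- r$lineages; state <- r$state
  r <- coalesceWithin(tipsOf("E"), model@thetaE, 0, model@tauTNE, state)
  linE <- r$lineages; state <- r$state
  r <- coalesceWithin(c(linT, linN), model@thetaTN, model@tauTN,
                      model@tauTNE, state)
  linTN <- r$lineages; state <- r$state
  r <- coalesceWithin(c(linTN, linE), model@thetaTNE, model@tauTNE, Inf,
                      state)
  state <- r$state
  annotateSpeciesSets(list(parent = state$parent, time = state$time,
                           nTip = nTip, tipSpecies = tipSpecies,
                           root = r$lineages[1L]))
}

## postorder edge list (child-time ascending) for the pruning likelihood
geneTreeEdges <- function(gt) {
  children <- setdiff(seq_len(2L * gt$nTip - 1L), gt$root)
  ord <- children[order(gt$time[children])]
  edge <- cbind(gt$parent[ord], ord)
  len <- gt$time[edge[, 1L]] - gt$time[edge[, 2L]]
  list(edge = edge, length = len)
}

simulateJC69 <- function(gt, locusLength, scalar) {
  nNode <- 2L * gt$nTip - 1L
  seqs <- matrix(NA_integer_, nNode, locusLength)
  seqs[gt$root, ] <- sample.int(4L, locusLength, replace = TRUE) - 1L
  ed <- geneTreeEdges(gt)
  for (e in rev(seq_len(nrow(ed$edge)))) {   # parents before children
    par <- ed$edge[e, 1L]; ch <- ed$edge[e, 2L]
    b <- ed$length[e] * scalar
    q <- 1 - exp(-4 * b / 3)
    x <- seqs[par, ]
    redraw <- runif(locusLength) < q
    x[redraw] <- sample.int(4L, sum(redraw), replace = TRUE) - 1L
    seqs[ch, ] <- x
  }
  seqs[seq_len(gt$nTip), , drop = FALSE]
}

#' Simulate multilocus data under the multispecies coalescent
#'
#' Gene trees are drawn by censored coalescence within the branches of the
#' fixed species tree ((T,N),E) (pairwise rate 2/theta in substitution-time
#' units) and JC69 sequences are evolved along them, with per-locus rate
#' scalars multiplying every branch.
#'
#' @param model an \code{MSCModel}.
#' @param nLoci number of loci.
#' @param seqsPerSpecies haplotypes sampled per species (1--4).
#' @param locusLength sites per locus.
#' @param scalars per-locus rate scalars (recycled), mean ~1.
#' @param seed integer seed.
#' @return list with \code{loci} (each: integer base matrix tips x sites,
#'   coded 0..3, \code{species} per row, \code{scalar}) and \code{truth}
#'   (model parameters, gene trees, seed).
#' @export
simulateMSCLoci <- function(model, nLoci, seqsPerSpecies = 2L,
                            locusLength = 500L, scalars = 1, seed = 1L) {
  stopifnot(is(model, "MSCModel"), seqsPerSpecies >= 1, seqsPerSpecies <= 4)
  set.seed(seed)
  scalars <- rep_len(scalars, nLoci)
  loci <- vector("list", nLoci)
  trees <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    gt <- simulateGeneTree(model, as.integer(seqsPerSpecies))
    seqs <- simulateJC69(gt, as.integer(locusLength), scalars[i])
    rownames(seqs) <- paste0(gt$tipSpecies, seq_len(nrow(seqs)))
    loci[[i]] <- list(bases = seqs, species = gt$tipSpecies,
                      scalar = scalars[i])
    trees[[i]] <- gt
  }
  list(loci = loci,
       truth = list(generator = "msc", model = model, scalars = scalars,
                    geneTrees = trees, seed = as.integer(seed)))
}

#' Simulate a phylogram from a true chronogram
#'
#' Assigns a substitution rate to every branch (strict clock, or a log-normal
#' random walk along the tree with step sigma for autocorrelated variation),
#' draws the substitution count of branch j as Poisson(r_j t_j L) and
#' returns branch lengths in substitutions/site.
#'
#' @param chronogram ultrametric \code{ape::phylo}, edge lengths in MYA.
#' @param rateModel \code{"clock"}, \code{"autocorrelated"} (log-normal
#'   random walk along branches) or \code{"cladeShift"} (one clade's rate
#'   multiplied by \code{fold} -- the extreme of autocorrelated variation:
#'   rates identical within regimes, one large heritable step between them).
#' @param rate base rate in substitutions/site/MYA.
#' @param sigma log-normal step standard deviation (autocorrelated model).
#' @param fold rate multiplier of the shifted clade (cladeShift model).
#' @param L number of sites.
#' @param seed integer seed.
#' @return list with \code{phylogram} (phylo, substitutions/site) and
#'   \code{truth} (per-edge rates, node ages, parameters, seed).
#' @export
simulatePhylogram <- function(chronogram, rateModel = c("clock",
                                                        "autocorrelated",
                                                        "cladeShift"),
                              rate = 0.0065, sigma = 0.3, fold = 5,
                              L = 1140, seed = 1L) {
  rateModel <- match.arg(rateModel)
  stopifnot(inherits(chronogram, "phylo"), rate > 0, L > 0)
  set.seed(seed)
  phy <- ape::reorder.phylo(chronogram, "cladewise")
  nEdge <- nrow(phy$edge)
  rates <- rep(rate, nEdge)
  if (rateModel == "autocorrelated" && sigma > 0) {
    parentEdge <- match(phy$edge[, 1L], phy$edge[, 2L])  # NA at root children
    for (e in seq_len(nEdge)) {
      base <- if (is.na(parentEdge[e])) rate else rates[parentEdge[e]]
      rates[e] <- base * exp(rnorm(1L, -sigma^2 / 2, sigma))
    }
  }
  if (rateModel == "cladeShift") {
    ntip <- length(phy$tip.label)
    cand <- (ntip + 2L):(ntip + phy$Nnode)
    sizes <- vapply(cand, function(v) length(tipsBelow(phy, v)), integer(1L))
    ok <- cand[sizes >= 2L & sizes <= ceiling(ntip / 2)]
    v <- ok[which.max(sizes[match(ok, cand)])]
    cladeTips <- tipsBelow(phy, v)
    inClade <- vapply(seq_len(nEdge), function(e) {
      ch <- phy$edge[e, 2L]
      ch == v || all(tipsBelow(phy, ch) %in% cladeTips)
    }, logical(1L))
    rates[inClade] <- rate * fold
  }
  x <- rpois(nEdge, rates * phy$edge.length * L)
  out <- phy
  out$edge.length <- x / L
  ages <- ape::node.depth.edgelength(phy)
  ages <- max(ages) - ages
  list(phylogram = out,
       truth = list(generator = "phylogram", rateModel = rateModel,
                    rate = rate, sigma = sigma, L = L, rates = rates,
                    ages = ages, substitutions = x, seed = as.integer(seed)))
}

#' Simulate GISH signal ratios for a hybrid metaphase
#'
#' Generates one chromosome per entry of the green- and red-probe genome
#' compositions, with the true origin label and a Beta-distributed green
#' signal fraction centred on \code{meanGreen} (green-origin chromosomes) or
#' \code{meanRed} (red-origin).
#'
#' @param greenComp,redComp genome compositions painted by the green and red
#'   probes (e.g. \code{"E"} and \code{"N"} for an EN hybrid).
#' @param table reference karyotype table.
#' @param meanGreen,meanRed mean green fraction per origin.
#' @param concentration Beta concentration (a+b); \code{Inf} gives exact
#'   means.
#' @param seed integer seed.
#' @return data.frame with columns category, green_fraction, origin.
#' @export
simulateGishChromosomes <- function(greenComp, redComp,
                                    table = karyotypeTable(),
                                    meanGreen = 0.9, meanRed = 0.1,
                                    concentration = Inf, seed = 1L) {
  set.seed(seed)
  expand <- function(comp, origin, m) {
    k <- composeKaryotype(comp, table)
    cc <- categoryCounts(k)
    df <- data.frame(category = rep(names(cc), cc),
                     origin = origin, stringsAsFactors = FALSE)
    df$green_fraction <- if (is.infinite(concentration)) {
      rep(m, nrow(df))
    } else {
      stats::rbeta(nrow(df), m * concentration, (1 - m) * concentration)
    }
    df
  }
  rbind(expand(greenComp, "green", meanGreen),
        expand(redComp, "red", meanRed))
}

#' Write the packaged reference fixtures to a directory
#'
#' Copies the reference karyotype and cohort tables into \code{outdir} and
#' writes a deterministic GISH signal list (true origin labels included).
#' Re-runs produce bit-identical files; MD5 checksums are returned.
#'
#' @param outdir output directory (created if needed).
#' @return named character vector of MD5 checksums, one per written file.
#' @export
makeFixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  src <- c(karyotype = system.file("extdata", "karyotype_reference.tsv",
                                   package = "karyoClock"),
           cohort = system.file("extdata", "cohort_sampling.tsv",
                                package = "karyoClock"))
  dst <- file.path(outdir, basename(src))
  file.copy(src, dst, overwrite = TRUE)
  gish <- simulateGishChromosomes("E", "N", meanGreen = 0.9, meanRed = 0.1,
                                  concentration = 50, seed = 20160125L)
  gishPath <- file.path(outdir, "gish_signals_EN.tsv")
  write.table(gish, gishPath, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(dst, gishPath)
  tools::md5sum(files)
}
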