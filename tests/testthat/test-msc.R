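toyModel <- MSCModel(tauTNE = 0.01, tauTN = 0.0026, thetaE = 0.002,
                     thetaT = 0.002, thetaN = 0.002, thetaTN = 0.002,
                     thetaTNE = 0.002)

test_that("JC69 pruning matches closed forms and the matrix exponential", {
  pairTree <- function(t) list(parent = c(3L, 3L, 0L), time = c(0, 0, t),
                               nTip = 2L, tipSpecies = c("T", "T"),
                               root = 3L)
  b <- matrix(c(0L, 0L), 2L, 1L)
  expect_equal(exp(jc69Loglik(pairTree(0), b)), 1 / 4, tolerance = 1e-12)
  expect_equal(exp(jc69Loglik(pairTree(60), b)), 1 / 16, tolerance = 1e-10)
  b2 <- matrix(c(0L, 3L), 2L, 1L)
  expect_equal(exp(jc69Loglik(pairTree(60), b2)), 1 / 16, tolerance = 1e-10)

  gt3 <- list(parent = c(4L, 4L, 5L, 5L, 0L), time = c(0, 0, 0, 0.3, 0.8),
              nTip = 3L, tipSpecies = c("T", "T", "E"), root = 5L)
  set.seed(8)
  bases <- matrix(sample(0:3, 3 * 25, replace = TRUE), 3L, 25L)
  expect_equal(jc69Loglik(gt3, bases, scalar = 1.3),
               jcOracleLoglik(gt3, bases, scalar = 1.3), tolerance = 1e-10)
})

test_that("likelihood is invariant to sequence order within a species", {
  sim <- simulateMSCLoci(toyModel, 1, 2L, 120L, seed = 5)
  lc <- sim$loci[[1L]]
  gt <- sim$truth$geneTrees[[1L]]
  ll <- jc69Loglik(gt, lc$bases)
  # swap the two T tips (rows 1 and 2) and the matching gene-tree leaves
  basesSw <- lc$bases[c(2L, 1L, 3:6), ]
  gtSw <- gt
  p <- gt$parent; p[c(1L, 2L)] <- p[c(2L, 1L)]
  gtSw$parent <- p
  gtSw <- karyoClock:::annotateSpeciesSets(gtSw)
  expect_equal(jc69Loglik(gtSw, basesSw), ll, tolerance = 1e-12)
})

test_that("rate scalars normalize among-locus outgroup distances", {
  mk <- function(p, L = 1000L) {
    # ingroup monomorphic; outgroup differs at fraction p of sites
    ing <- matrix(0L, 2L, L)
    og <- c(rep(1L, round(p * L)), rep(0L, L - round(p * L)))
    list(loci = list(bases = ing, species = c("T", "N")), og = og)
  }
  a <- mk(0.05); b <- mk(0.10)
  sc <- computeRateScalars(list(a$loci, b$loci), list(a$og, b$og),
                           corrected = FALSE)
  expect_equal(sc, c(2 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(mean(sc), 1)
  sameD <- computeRateScalars(list(a$loci, a$loci), list(a$og, a$og))
  expect_equal(sameD, c(1, 1), tolerance = 1e-12)
  expect_error(computeRateScalars(list(a$loci), list(NULL)), "outgroup")

  # recovery of true multipliers from simulated loci (deeper outgroup)
  truthSc <- c(0.5, 1, 1.5)
  sim <- simulateMSCLoci(toyModel, 3, 1L, 4000L, scalars = truthSc,
                         seed = 31)
  og <- lapply(seq_len(3), function(i) {
    # outgroup separated by ~0.15 substitutions/site at unit rate
    set.seed(40 + i)
    ref <- sim$loci[[i]]$bases[3L, ]   # the E sequence
    t <- 0.15 * truthSc[i]
    q <- 1 - exp(-4 * t / 3)
    redraw <- runif(length(ref)) < q
    ref[redraw] <- sample(0:3, sum(redraw), replace = TRUE)
    ref
  })
  got <- computeRateScalars(sim$loci, og)
  expect_equal(got, truthSc, tolerance = 0.2)
})

test_that("the MSC density integrates simulated trees and rejects invalid ones", {
  sim <- simulateMSCLoci(toyModel, 6, 2L, 50L, seed = 3)
  for (gt in sim$truth$geneTrees)
    expect_true(is.finite(karyoClock:::mscLogDensity(gt, toyModel)))

  # a T+N coalescence below tau_TN violates the species tree
  bad <- sim$truth$geneTrees[[1L]]
  mixed <- which(bad$ss == "NT")[1L]
  bad$time[mixed] <- toyModel@tauTN / 2
  expect_identical(karyoClock:::mscLogDensity(bad, toyModel), -Inf)

  # theta -> 0: every gene tree matches the species tree, node heights ~ tau
  tiny <- MSCModel(0.01, 0.0026, 1e-7, 1e-7, 1e-7, 1e-7, 1e-7)
  sim0 <- simulateMSCLoci(tiny, 5, 2L, 10L, seed = 9)
  for (gt in sim0$truth$geneTrees) {
    tn <- gt$time[gt$ss == "NT"]
    expect_true(all(abs(tn - tiny@tauTN) < 1e-4))
    root <- gt$time[gt$root]
    expect_lt(abs(root - tiny@tauTNE), 1e-4)
  }
})

test_that("simulated pairwise distances match the coalescent expectation", {
  # theta_TN ~ 0 forces T,N to coalesce entering TNE as one lineage, so
  # E[d_TE] = 2 (tau_TNE + theta_TNE / 2) with one sequence per species
  m <- MSCModel(tauTNE = 0.02, tauTN = 0.005, thetaE = 1e-6, thetaT = 1e-6,
                thetaN = 1e-6, thetaTN = 1e-6, thetaTNE = 0.004)
  sim <- simulateMSCLoci(m, 120, 1L, 500L, seed = 13)
  dTE <- vapply(sim$loci, function(lc)
    karyoClock:::jcDistance(lc$bases[1L, ], lc$bases[3L, ]), numeric(1L))
  expected <- 2 * (m@tauTNE + m@thetaTNE / 2)
  se <- sd(dTE) / sqrt(length(dTE))
  expect_lt(abs(mean(dTE) - expected), 4 * se + 0.001)
})

test_that("a prior-only chain reproduces its prior", {
  pri <- karyoClock:::defaultPriors(0.01, 0.002)
  s <- suppressWarnings(
    mcmcMSC(NULL, priors = pri, chain = list(iterations = 30000,
                                             retain = 3000), seed = 11))
  sm <- summarizePosterior(s)@summary
  expect_equal(sm["tau_TNE", "mean"], 0.01, tolerance = 0.12)
  expect_equal(sm["tau_TN", "mean"], 0.005, tolerance = 0.15)
  for (p in c("theta_E", "theta_T", "theta_N", "theta_TN", "theta_TNE"))
    expect_equal(sm[p, "mean"], 0.002, tolerance = 0.12)
  # and matches the analytic gamma quantiles of the tau_TNE prior
  expect_equal(sm["tau_TNE", "q97.5"], qgamma(0.975, 2, rate = 200),
               tolerance = 0.2)
})

test_that("tau ordering holds in every retained sample and data runs mix", {
  sim <- simulateMSCLoci(toyModel, 4, 2L, 200L, seed = 21)
  s <- suppressWarnings(
    mcmcMSC(sim$loci, chain = list(iterations = 1500, retain = 300),
            seed = 22))
  expect_true(all(s[, "tau_TN"] < s[, "tau_TNE"]))
  expect_true(all(s > 0))
  expect_identical(attr(s, "seed"), 22L)
  # posterior should land in the truth's neighbourhood (4 short loci only)
  expect_lt(abs(mean(s[, "tau_TNE"]) - toyModel@tauTNE),
            0.75 * toyModel@tauTNE)
})

test_that("posterior summaries behave as exact functionals of the chain", {
  const <- matrix(5, 100, 1, dimnames = list(NULL, "x"))
  sm <- summarizePosterior(const, seed = 1L, settings = list())
  expect_equal(sm@summary["x", "mean"], 5)
  expect_equal(sm@summary["x", "q2.5"], 5)
  expect_equal(sm@summary["x", "q97.5"], 5)

  set.seed(4)
  z <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "z"))
  smz <- summarizePosterior(z, seed = 1L, settings = list())
  expect_gt(smz@summary["z", "ess"], 0.5 * 4000)
  expect_lt(smz@summary["z", "ess"], 1.5 * 4000)

  sh <- summarizePosterior(z + 10, seed = 1L, settings = list())
  expect_equal(sh@summary["z", "mean"], smz@summary["z", "mean"] + 10,
               tolerance = 1e-12)
  expect_equal(sh@summary["z", "q2.5"], smz@summary["z", "q2.5"] + 10,
               tolerance = 1e-12)
})
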