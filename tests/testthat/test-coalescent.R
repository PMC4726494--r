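test_that("the four-gamete test flags recurrent-mutation patterns", {
  bad <- haplotypeSample(rbind(c(0L, 0L, 1L, 1L),
                               c(0L, 1L, 0L, 1L)))
  ok <- checkInfiniteSites(bad)
  expect_false(as.logical(ok))
  expect_identical(attr(ok, "conflicts")[1L, ], c(site1 = 1L, site2 = 2L))

  single <- haplotypeSample(rbind(c(1L, 0L, 0L)))
  expect_true(as.logical(checkInfiniteSites(single)))

  for (seed in 1:10) {
    sim <- simulateInfiniteSitesSample(8, 2, seed = seed)
    expect_true(as.logical(checkInfiniteSites(sim$sample)))
  }
})

test_that("Ewens ML theta solves the expected-allele-count equation", {
  expect_identical(ewensMLTheta(10, 1)$theta, 0)
  ub <- ewensMLTheta(10, 10)
  expect_true(ub$unbounded)
  expect_error(ewensMLTheta(5, 6), "exceed")

  # brute-force bisection oracle on k = sum theta/(theta+i)
  for (case in list(c(10, 5), c(30, 12), c(50, 3))) {
    n <- case[1L]; k <- case[2L]
    f <- function(th) sum(th / (th + 0:(n - 1L))) - k
    lo <- 1e-9; hi <- 1e4
    for (it in 1:60) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
    expect_equal(ewensMLTheta(n, k)$theta, (lo + hi) / 2, tolerance = 1e-6)
  }
})

test_that("SIS likelihood matches closed forms for pairs", {
  s2 <- haplotypeSample(matrix(integer(0), 0L, 2L))
  for (th in c(0.5, 1, 2)) {
    r <- sisLoglik(s2, th, nParticles = 500, seed = 1)
    expect_equal(exp(r$loglik), 1 / (1 + th), tolerance = 1e-12)
  }
  s21 <- haplotypeSample(matrix(c(1L, 0L), 1L, 2L))
  r <- sisLoglik(s21, 1, nParticles = 500, seed = 1)
  expect_equal(exp(r$loglik), 1 / 4, tolerance = 1e-12)  # theta/(1+theta)^2

  expect_identical(sisLoglik(s21, 0, nParticles = 100, seed = 1)$loglik,
                   -Inf)
})

test_that("SIS agrees with the exact recursion on small samples", {
  configs <- list(haplotypeSample(rbind(c(1L, 0L, 0L))),
                  haplotypeSample(rbind(c(1L, 1L, 0L, 0L),
                                        c(1L, 0L, 0L, 0L))),
                  haplotypeSample(rbind(c(1L, 1L, 0L, 0L),
                                        c(0L, 0L, 1L, 0L))))
  for (th in c(0.7, 1.5)) {
    for (ci in seq_along(configs)) {
      s <- configs[[ci]]
      ex <- exactSampleProb(s, th)
      r <- sisLoglik(s, th, nParticles = 2e4, seed = 100 + ci)
      z <- abs(exp(r$loglik) - ex) / (ex * max(r$mcse, 1e-12))
      expect_lt(z, 3.5)
    }
  }
})

test_that("SIS estimates are invariant to haplotype column order", {
  sim <- simulateInfiniteSitesSample(12, 1.5, seed = 33)
  s <- sim$sample
  sPerm <- haplotypeSample(s@siteMatrix[, rev(seq_len(ncol(s@siteMatrix))),
                                        drop = FALSE],
                           rev(s@multiplicities))
  a <- sisLoglik(s, 1.5, nParticles = 5e3, seed = 5)
  b <- sisLoglik(sPerm, 1.5, nParticles = 5e3, seed = 5)
  expect_equal(a$loglik, b$loglik,
               tolerance = 4 * (a$mcse + b$mcse) + 1e-8)
  # doubling the particle count moves the estimate within shrinking MC error
  c2 <- sisLoglik(s, 1.5, nParticles = 1e4, seed = 6)
  expect_equal(a$loglik, c2$loglik, tolerance = 4 * (a$mcse + c2$mcse))
})

test_that("TMRCA posterior matches the conditional-exponential pair case", {
  s2 <- haplotypeSample(matrix(integer(0), 0L, 2L))
  tm <- tmrcaPosterior(s2, 1, nParticles = 2e4, seed = 3)
  se <- 0.5 / sqrt(2e4)   # Exp(2) sd / sqrt(M)
  expect_lt(abs(tm@mean - 0.5), 3 * se)
  tm0 <- tmrcaPosterior(s2, 1e-8, nParticles = 2e4, seed = 4)
  expect_lt(abs(tm0@mean - 1), 3 / sqrt(2e4))
  expect_true(tm@ciLow <= tm@mean && tm@mean <= tm@ciHigh)
})

test_that("TMRCA posterior matches a rejection-sampling oracle", {
  # oracle: simulate genealogy + mutations forward, keep exact matches of
  # the unlabeled site-frequency configuration, average the kept heights
  target <- haplotypeSample(rbind(c(1L, 0L, 0L, 0L)))
  th <- 1
  set.seed(99)
  kept <- c()
  for (i in 1:20000) {
    sim <- simulateInfiniteSitesSample(4, th, seed = i)
    m <- sim$sample@siteMatrix
    if (nrow(m) == 1L && sum(m %*% sim$sample@multiplicities) == 1L)
      kept <- c(kept, sim$truth$tmrca)
  }
  tm <- tmrcaPosterior(target, th, nParticles = 5e4, seed = 17)
  seOracle <- sd(kept) / sqrt(length(kept))
  expect_gt(length(kept), 500)
  expect_lt(abs(tm@mean - mean(kept)), 4 * seOracle)
})

test_that("theta profile brackets a plausible estimate and reuses seeds", {
  sim <- simulateInfiniteSitesSample(30, 1.156, seed = 42)
  prof <- mlThetaProfile(sim$sample, nParticles = 2000, seed = 7)
  expect_s4_class(prof, "ThetaEstimate")
  expect_true(thetaHat(prof) > 0)
  # the 2-unit support interval of the profile contains the Ewens estimate
  ll <- prof@profile$loglik
  support <- range(prof@profile$theta[ll >= max(ll) - 2])
  ew <- ewensMLTheta(sim$sample@n, ncol(sim$sample@siteMatrix))$theta
  expect_true(ew >= support[1L] / 2 && ew <= support[2L] * 2)
  # monomorphic sample pins the estimate at the grid's lower bound
  mono <- haplotypeSample(matrix(integer(0), 0L, 10L))
  pm <- mlThetaProfile(mono, thetaGrid = c(0.1, 1, 10), nParticles = 200,
                       seed = 1, refine = FALSE)
  expect_identical(thetaHat(pm), 0.1)
})

test_that("rooted-incompatible samples get probability exactly zero", {
  # carriers of the two sites overlap without nesting: fine unrooted, but
  # impossible on a rooted perfect phylogeny with all-ancestral root
  s <- haplotypeSample(rbind(c(1L, 1L, 0L), c(1L, 0L, 1L)))
  expect_true(as.logical(checkInfiniteSites(s)))   # four-gamete passes
  r <- suppressWarnings(sisLoglik(s, 1, nParticles = 1000, seed = 1))
  expect_identical(r$loglik, -Inf)
  expect_identical(exactSampleProb(s, 1), 0)
})

test_that("incompatible samples are rejected by the SIS front ends", {
  bad <- haplotypeSample(rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
  expect_error(sisLoglik(bad, 1, 100, 1), "four-gamete")
  expect_error(tmrcaPosterior(bad, 1, 100, 1), "four-gamete")
})
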