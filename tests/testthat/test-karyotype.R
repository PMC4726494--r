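tab <- karyotypeTable()

test_that("haploid complements come straight from the reference table", {
  e <- haploidKaryotype("E", tab)
  expect_identical(unname(categoryCounts(e)), c(11L, 13L, 1L, 0L))
  expect_identical(chromosomeTotal(e), 25L)
  expect_identical(chromosomeTotal(haploidKaryotype("T", tab)), 24L)
  expect_identical(chromosomeTotal(haploidKaryotype("N", tab)), 25L)
  expect_error(haploidKaryotype("X", tab), "unknown genome code")
})

test_that("composed hybrid karyotypes are additive in the haploid sets", {
  en <- composeKaryotype("EN", tab)
  expect_identical(chromosomeTotal(en), 50L)
  expect_identical(en@meta, 16L)   # 11 E metacentrics + 5 N metacentrics
  expect_identical(chromosomeTotal(composeKaryotype("EET", tab)), 74L)
  expect_identical(categoryCounts(composeKaryotype("")),
                   setNames(rep(0L, 4L), karyoClock:::KARYOTYPE_CATEGORIES))
  expect_error(composeKaryotype("EXN", tab), "unknown letter")
  expect_error(composeKaryotype("EENN", tab), "triploid")
})

test_that("composition is order-invariant and matches every table column", {
  expect_identical(categoryCounts(composeKaryotype("EN", tab)),
                   categoryCounts(composeKaryotype("NE", tab)))
  for (comp in colnames(tab)) {
    expect_identical(unname(categoryCounts(composeKaryotype(comp, tab))),
                     unname(tab[, comp]), label = comp)
    expect_identical(chromosomeTotal(composeKaryotype(comp, tab)),
                     unname(attr(tab, "totals")[comp]), label = comp)
  }
})

test_that("additivity verification reports per-category differences", {
  obs <- Karyotype(tab["metacentric", "ET"], tab["submetacentric", "ET"],
                   tab["subtelocentric", "ET"], tab["acrocentric", "ET"])
  rep1 <- verifyAdditivity(obs, "ET", tab)
  expect_true(attr(rep1, "consistent"))
  expect_true(all(rep1$difference == 0L))

  extra <- Karyotype(obs@meta, obs@submeta, obs@subtelo, obs@acro + 1L)
  rep2 <- verifyAdditivity(extra, "ET", tab)
  expect_false(attr(rep2, "consistent"))
  expect_identical(rep2$difference[rep2$category == "acrocentric"], 1L)

  enn <- Karyotype(tab["metacentric", "ENN"], tab["submetacentric", "ENN"],
                   tab["subtelocentric", "ENN"], tab["acrocentric", "ENN"])
  expect_true(attr(verifyAdditivity(enn, "ENN", tab), "consistent"))
})

test_that("clean GISH signals recover the parental haploid sets", {
  chroms <- simulateGishChromosomes("E", "N", tab, meanGreen = 0.9,
                                    meanRed = 0.1, concentration = Inf,
                                    seed = 1)
  expect_identical(nrow(chroms), 50L)
  sets <- assignParentalSets(chroms, threshold = 0.5)
  expect_identical(unname(categoryCounts(sets$green)), c(11L, 13L, 1L, 0L))
  expect_identical(unname(categoryCounts(sets$red)), c(5L, 13L, 3L, 4L))
  expect_identical(chromosomeTotal(sets$ambiguous), 0L)
})

test_that("empty input, exact-threshold signals and conservation behave", {
  empty <- assignParentalSets(data.frame(category = character(0),
                                         green_fraction = numeric(0)))
  expect_identical(chromosomeTotal(empty$green), 0L)
  expect_identical(chromosomeTotal(empty$red), 0L)

  atThr <- data.frame(category = "metacentric", green_fraction = 0.5)
  sets <- assignParentalSets(atThr, threshold = 0.5)
  expect_identical(chromosomeTotal(sets$ambiguous), 1L)
  expect_identical(chromosomeTotal(sets$green) + chromosomeTotal(sets$red), 0L)

  expect_error(assignParentalSets(atThr, threshold = 0), "threshold")
  expect_error(assignParentalSets(atThr, threshold = 1), "threshold")
})

test_that("noisy Beta signals are assigned accurately against true labels", {
  # accuracy oracle: direct comparison with the generator's origin labels
  for (seed in 1:5) {
    chroms <- simulateGishChromosomes("EE", "N", tab, meanGreen = 0.85,
                                      meanRed = 0.15, concentration = 40,
                                      seed = seed)
    sets <- assignParentalSets(chroms, threshold = 0.5)
    total <- chromosomeTotal(sets$green) + chromosomeTotal(sets$red) +
      chromosomeTotal(sets$ambiguous)
    expect_identical(total, nrow(chroms))   # conservation
    called <- ifelse(chroms$green_fraction > 0.5, "green",
                     ifelse(chroms$green_fraction < 0.5, "red", "amb"))
    acc <- mean(called == chroms$origin)
    expect_gt(acc, 0.95)
    # the per-set counts must equal a brute-force relabeling by threshold
    brute <- table(factor(chroms$category[called == "green"],
                          levels = karyoClock:::KARYOTYPE_CATEGORIES))
    expect_identical(unname(categoryCounts(sets$green)),
                     as.integer(unname(brute)))
  }
})
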