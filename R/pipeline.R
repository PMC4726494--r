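PIPELINE_KEYS <- c("stages", "out_dir", "seed",
                   "karyotype_table", "karyotype_comp",
                   "cohort_table", "cohort_by",
                   "clone_n", "clone_theta", "clone_particles",
                   "calib_g", "calib_L", "calib_rate", "calib_outgroup_age",
                   "chronogram_tips", "chronogram_root_age",
                   "chronogram_lambda",
                   "msc_loci", "msc_locus_length", "msc_iterations")

#' Read a flat key=value run configuration
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Unknown keys are errors, not warnings.
#'
#' @param path config file.
#' @return named list of character values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  cfg <- lapply(kv, function(x) trimws(x[2L]))
  names(cfg) <- vapply(kv, function(x) trimws(x[1L]), character(1L))
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  invisible(cfg)
}

asNum <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on packaged fixtures
#' and synthetic data: karyotype additivity verification, cohort
#' aggregation, clone-age dating (theta profile + TMRCA + years), a
#' chronogram fit on a simulated clock phylogram, and a scaled-down MSC
#' dating run with absolute-time conversion. All randomness flows from the
#' single configured seed; results (with package version, config hash and
#' seeds) are written as JSON and returned.
#'
#' @param config named list (or path to a key=value file). Keys:
#'   \code{stages} (comma list among karyotype, cohort, clone_age,
#'   chronogram, msc; default all), \code{out_dir}, \code{seed}, and
#'   stage parameters (see \code{karyoClock:::PIPELINE_KEYS}). Unknown keys
#'   are rejected.
#' @return the result bundle, invisibly; written to
#'   \code{out_dir/results.json}.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  validatePipelineConfig(config)
  stages <- if (is.null(config$stages))
    c("karyotype", "cohort", "clone_age", "chronogram", "msc")
  else trimws(strsplit(config$stages, ",")[[1L]])
  known <- c("karyotype", "cohort", "clone_age", "chronogram", "msc")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  outDir <- if (is.null(config$out_dir)) tempfile("karyoClock_run")
            else config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)

  cfgFile <- file.path(outDir, "config_used.txt")
  hashed <- config[setdiff(names(config), "out_dir")]   # path-independent
  flat <- vapply(hashed, function(v) paste(as.character(v), collapse = ","),
                 character(1L))
  writeLines(paste0(sort(names(flat)), " = ", flat[sort(names(flat))]),
             cfgFile)
  res <- list(package = "karyoClock",
              version = as.character(packageVersion("karyoClock")),
              seed = seed,
              config_md5 = unname(tools::md5sum(cfgFile)))

  if ("karyotype" %in% stages) {
    tab <- karyotypeTable(path = if (is.null(config$karyotype_table))
      system.file("extdata", "karyotype_reference.tsv",
                  package = "karyoClock") else config$karyotype_table)
    comps <- colnames(tab)[nchar(colnames(tab)) > 1L]
    reports <- lapply(comps, function(cc) {
      obs <- Karyotype(tab["metacentric", cc], tab["submetacentric", cc],
                       tab["subtelocentric", cc], tab["acrocentric", cc],
                       label = cc)
      rep <- verifyAdditivity(obs, cc, tab)
      list(composition = cc, total = chromosomeTotal(obs),
           consistent = attr(rep, "consistent"))
    })
    res$karyotype <- list(compositions = reports,
                          all_consistent = all(vapply(reports, `[[`,
                                                      logical(1L),
                                                      "consistent")))
  }
  if ("cohort" %in% stages) {
    rec <- loadCohort(path = if (is.null(config$cohort_table))
      system.file("extdata", "cohort_sampling.tsv", package = "karyoClock")
      else config$cohort_table)
    hyb <- aggregateCohort(rec, "all_hybrids")
    res$cohort <- list(records = nrow(rec),
                       by_biotype = aggregateCohort(rec, "biotype"),
                       hybrids = as.list(hyb[1L, ]))
  }
  if ("clone_age" %in% stages) {
    n <- as.integer(if (is.null(config$clone_n)) 30L else config$clone_n)
    th <- asNum(config$clone_theta); if (is.null(th)) th <- 1.156
    np <- as.integer(if (is.null(config$clone_particles)) 2e4
                     else config$clone_particles)
    sim <- simulateInfiniteSitesSample(n, th, seed = seed)
    prof <- mlThetaProfile(sim$sample, nParticles = np, seed = seed + 1L)
    tm <- tmrcaPosterior(sim$sample, thetaHat(prof), nParticles = 5L * np,
                         seed = seed + 2L)
    params <- calibrationParams(
      g = if (is.null(config$calib_g)) 2 else asNum(config$calib_g),
      L = if (is.null(config$calib_L)) 1140 else asNum(config$calib_L),
      rate = if (is.null(config$calib_rate)) 0.0065
             else asNum(config$calib_rate))
    age <- cloneAgeYears(tm, thetaHat(prof), params)
    res$clone_age <- list(simulated_n = n, true_theta = th,
                          true_tmrca = sim$truth$tmrca,
                          theta_hat = thetaHat(prof),
                          tmrca_mean = tm@mean,
                          tmrca_ci = c(tm@ciLow, tm@ciHigh),
                          age_years = age$ageYears,
                          age_ci_years = age$ciYears,
                          Nf = age$Nf, seed = seed)
  }
  if ("chronogram" %in% stages) {
    set.seed(seed + 10L)
    rootAge <- if (is.null(config$chronogram_root_age)) 16
               else asNum(config$chronogram_root_age)
    nTips <- as.integer(if (is.null(config$chronogram_tips)) 8L
                        else config$chronogram_tips)
    tr <- ape::rphylo(nTips, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length * rootAge /
      max(ape::node.depth.edgelength(tr))
    sim <- simulatePhylogram(tr, "clock", rate = 0.0065, L = 1140,
                             seed = seed + 11L)
    lam <- if (is.null(config$chronogram_lambda)) 100
           else asNum(config$chronogram_lambda)
    fit <- fitChronogram(sim$phylogram, lam,
                         list(tips = tr$tip.label, age = rootAge),
                         L = 1140, seed = seed + 12L)
    res$chronogram <- list(lambda = lam, root_age = rootAge,
                           mean_rate = mean(branchRates(fit)),
                           lineage_average_rate =
                             lineageAverageRate(fit, tr$tip.label),
                           ages = nodeAges(fit), seed = seed + 10L)
  }
  if ("msc" %in% stages) {
    nl <- as.integer(if (is.null(config$msc_loci)) 9L else config$msc_loci)
    ll <- as.integer(if (is.null(config$msc_locus_length)) 300L
                     else config$msc_locus_length)
    iter <- as.integer(if (is.null(config$msc_iterations)) 3000L
                       else config$msc_iterations)
    truth <- MSCModel(tauTNE = 0.01, tauTN = 0.0026, thetaE = 0.002,
                      thetaT = 0.002, thetaN = 0.002, thetaTN = 0.002,
                      thetaTNE = 0.002)
    sim <- simulateMSCLoci(truth, nl, 2L, ll, seed = seed + 20L)
    post <- mcmcMSC(sim$loci, chain = list(iterations = iter, retain = 500L),
                    seed = seed + 21L)
    sm <- summarizePosterior(post)
    outAge <- if (is.null(config$calib_outgroup_age)) 16.17
              else asNum(config$calib_outgroup_age)
    tauOut <- 2 * truth@tauTNE     # synthetic outgroup split depth
    absT <- absoluteSpeciationTimes(post[, c("tau_TNE", "tau_TN")],
                                    tauOut, outAge)
    res$msc <- list(true_tau_TNE = truth@tauTNE, true_tau_TN = truth@tauTN,
                    posterior = cbind(parameter = rownames(sm@summary),
                                      sm@summary),
                    absolute_MYA = cbind(
                      parameter = rownames(absT$summary@summary),
                      absT$summary@summary),
                    outgroup_age = outAge, seed = seed + 20L)
  }
  deterministicJSON(res, file.path(outDir, "results.json"))
  invisible(res)
}
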