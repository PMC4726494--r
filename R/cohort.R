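AGE_CLASSES <- c("F1", "B1", "Holocene", "hybrid clade I", "none")
COHORT_COUNTS <- c("noi", "nomka", "noge", "noagm")

#' Load the sampling-design (cohort) table
#'
#' Reads the TSV mirroring the study's sampling table: one row per biotype x
#' locality with the clone age class and the counts of individuals (noi),
#' karyologically analysed metaphases (nomka), GISH experiments (noge) and
#' analysed GISH metaphases (noagm). Printed per-biotype "total" rows are
#' excluded from the returned records (they are recomputed, never trusted)
#' but kept in \code{attr(, "printedTotals")} for verification. Counts
#' printed as "-" are stored as \code{NA} ("absent") and treated as zero by
#' \code{\link{aggregateCohort}}.
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return data.frame of cohort records with attribute \code{printedTotals}.
#' @export
loadCohort <- function(path = system.file("extdata", "cohort_sampling.tsv",
                                          package = "karyoClock")) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "")
  need <- c("row_type", "biotype", "country", "locality", "lat", "long",
            "age_class", "noi", "probe_donors", COHORT_COUNTS[-1L])
  if (!identical(sort(colnames(raw)), sort(need)))
    stop("cohort table header must be: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- raw[, setdiff(need, "row_type"), drop = FALSE]
    for (cc in c(COHORT_COUNTS, "probe_donors")) out[[cc]] <- integer(0)
    attr(out, "printedTotals") <- out[0L, c("biotype", COHORT_COUNTS)]
    return(out)
  }

  parseCount <- function(x, col, rows) {
    out <- rep(NA_integer_, length(x))
    present <- !(is.na(x) | x == "-" | x == "")
    val <- suppressWarnings(as.numeric(x[present]))
    bad <- is.na(val) | val < 0 | val != floor(val)
    if (any(bad))
      stop("malformed count in column '", col, "', row ",
           paste(rows[present][bad], collapse = ", "),
           " (value '", x[present][bad][1L], "')")
    out[present] <- as.integer(val)
    out
  }

  rows <- seq_len(nrow(raw))
  for (cc in c(COHORT_COUNTS, "probe_donors"))
    raw[[cc]] <- parseCount(raw[[cc]], cc, rows)

  isTotal <- raw$row_type == "total"
  rec <- raw[!isTotal, setdiff(need, "row_type"), drop = FALSE]
  rownames(rec) <- NULL
  if (!all(rec$age_class %in% AGE_CLASSES))
    stop("unknown age_class; allowed: ", paste(AGE_CLASSES, collapse = ", "))
  parental <- vapply(rec$biotype, function(b) {
    l <- unique(strsplit(b, "")[[1L]]); length(l) == 1L
  }, logical(1L))
  if (any(!parental & rec$age_class == "none"))
    stop("age_class 'none' is only allowed for parental biotypes")
  attr(rec, "printedTotals") <-
    data.frame(biotype = raw$biotype[isTotal],
               raw[isTotal, COHORT_COUNTS, drop = FALSE],
               row.names = NULL)
  rec
}

isHybridBiotype <- function(biotype) {
  vapply(strsplit(biotype, ""), function(l) length(unique(l)) > 1L,
         logical(1L))
}

#' Aggregate cohort counts
#'
#' Sums the four count columns over groups. Absent counts (\code{NA},
#' printed "-") contribute zero. \code{by = "all_hybrids"} sums over hybrid
#' biotypes only (compositions with more than one distinct genome letter),
#' excluding the pure parental EE/TT/NN records.
#'
#' @param records data.frame from \code{\link{loadCohort}}.
#' @param by grouping: \code{"biotype"}, \code{"age_class"} or
#'   \code{"all_hybrids"}.
#' @return data.frame with one row per group and integer sums of noi,
#'   nomka, noge, noagm.
#' @export
aggregateCohort <- function(records, by = c("biotype", "age_class",
                                            "all_hybrids")) {
  by <- match.arg(by)
  sumCounts <- function(df) {
    vapply(COHORT_COUNTS,
           function(cc) as.integer(sum(df[[cc]], na.rm = TRUE)), integer(1L))
  }
  if (nrow(records) == 0L) {
    out <- data.frame(group = character(0))
    for (cc in COHORT_COUNTS) out[[cc]] <- integer(0)
    return(out)
  }
  if (by == "all_hybrids") {
    df <- records[isHybridBiotype(records$biotype), , drop = FALSE]
    s <- sumCounts(df)
    return(data.frame(group = "all_hybrids", noi = s["noi"],
                      nomka = s["nomka"], noge = s["noge"],
                      noagm = s["noagm"], row.names = NULL))
  }
  key <- records[[by]]
  groups <- unique(key)
  out <- do.call(rbind, lapply(groups, function(gk) {
    s <- sumCounts(records[key == gk, , drop = FALSE])
    data.frame(group = gk, noi = s["noi"], nomka = s["nomka"],
               noge = s["noge"], noagm = s["noagm"], row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
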