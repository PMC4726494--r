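#' Construct a Karyotype
#'
#' @param meta,submeta,subtelo,acro chromosome counts in the four Levan
#'   categories (metacentric, submetacentric, subtelocentric, acrocentric).
#' @param label optional genome-composition label.
#' @return a \code{Karyotype} object.
#' @examples
#' Karyotype(meta = 11, submeta = 13, subtelo = 1, acro = 0, label = "E")
#' @export
Karyotype <- function(meta = 0, submeta = 0, subtelo = 0, acro = 0,
                      label = NA_character_) {
  new("Karyotype", meta = as.integer(meta), submeta = as.integer(submeta),
      subtelo = as.integer(subtelo), acro = as.integer(acro),
      label = as.character(label))
}

#' Load a reference karyotype table
#'
#' Reads a TSV whose rows are the four Levan categories plus a "total" row
#' and whose columns are genome-composition codes (haploid letters and their
#' combinations, e.g. E, T, N, EE, ..., ENN). A "-" entry means zero
#' chromosomes in that category. The printed total row is checked against the
#' recomputed category sums, never trusted.
#'
#' @param path path to the TSV; defaults to the table shipped with the
#'   package.
#' @return integer matrix (4 categories x compositions) with a
#'   \code{"totals"} attribute holding the verified totals.
#' @export
karyotypeTable <- function(path = system.file("extdata",
                                              "karyotype_reference.tsv",
                                              package = "karyoClock")) {
  if (!file.exists(path)) stop("karyotype table not found: ", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(raw)[1L] != "category")
    stop("first column of the karyotype table must be 'category'")
  rn <- raw$category
  need <- c(KARYOTYPE_CATEGORIES, "total")
  if (!all(need %in% rn))
    stop("karyotype table must contain rows: ", paste(need, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals == "-"] <- "0"
  mode(vals) <- "integer"
  rownames(vals) <- rn
  counts <- vals[KARYOTYPE_CATEGORIES, , drop = FALSE]
  if (any(is.na(counts)) || any(counts < 0L))
    stop("karyotype table entries must be non-negative counts")
  totals <- colSums(counts)
  storage.mode(totals) <- "integer"
  printed <- vals["total", ]
  bad <- which(totals != printed)
  if (length(bad))
    stop("printed totals disagree with category sums for: ",
         paste(colnames(counts)[bad], collapse = ", "))
  attr(counts, "totals") <- totals
  counts
}

checkGenomeCode <- function(code) {
  if (length(code) != 1L || is.na(code) || !code %in% GENOME_CODES)
    stop("unknown genome code '", code, "'; must be one of ",
         paste(GENOME_CODES, collapse = ", "))
  code
}

#' Haploid karyotype of one parental genome
#'
#' @param code single genome letter (\code{"E"}, \code{"T"} or \code{"N"}).
#' @param table reference table from \code{\link{karyotypeTable}}.
#' @return a \code{Karyotype} with that genome's haploid category counts.
#' @examples
#' tab <- karyotypeTable()
#' chromosomeTotal(haploidKaryotype("E", tab))  # 25
#' @export
haploidKaryotype <- function(code, table = karyotypeTable()) {
  checkGenomeCode(code)
  if (!code %in% colnames(table))
    stop("genome code '", code, "' not present in the reference table")
  cc <- table[, code]
  Karyotype(cc["metacentric"], cc["submetacentric"], cc["subtelocentric"],
            cc["acrocentric"], label = code)
}

splitComposition <- function(comp) {
  if (length(comp) != 1L || is.na(comp)) stop("invalid genome composition")
  letters <- strsplit(comp, "")[[1L]]
  bad <- setdiff(letters, GENOME_CODES)
  if (length(bad))
    stop("invalid genome composition '", comp, "': unknown letter(s) ",
         paste(unique(bad), collapse = ", "))
  if (length(letters) > 3L)
    stop("composition '", comp, "' exceeds triploid (max 3 letters)")
  letters
}

#' Compose the expected karyotype of a genome combination
#'
#' Sums the haploid category counts of every letter of the composition; an
#' empty composition gives an all-zero karyotype. This is the additive
#' expectation against which observed hybrid karyotypes are compared.
#'
#' @param comp genome composition string, letters from E/T/N
#'   (e.g. \code{"EN"}, \code{"EEN"}).
#' @param table reference table from \code{\link{karyotypeTable}}.
#' @return a \code{Karyotype}.
#' @examples
#' tab <- karyotypeTable()
#' chromosomeTotal(composeKaryotype("EN", tab))   # 50
#' chromosomeTotal(composeKaryotype("EET", tab))  # 74
#' @export
composeKaryotype <- function(comp, table = karyotypeTable()) {
  letters <- if (identical(comp, "")) character(0) else splitComposition(comp)
  counts <- c(metacentric = 0L, submetacentric = 0L, subtelocentric = 0L,
              acrocentric = 0L)
  for (l in letters) counts <- counts + categoryCounts(haploidKaryotype(l, table))
  Karyotype(counts["metacentric"], counts["submetacentric"],
            counts["subtelocentric"], counts["acrocentric"],
            label = if (length(letters)) comp else "")
}

#' Verify additivity of an observed hybrid karyotype
#'
#' Compares an observed karyotype with the additive expectation for a genome
#' composition, category by category.
#'
#' @param observed observed \code{Karyotype}.
#' @param comp genome composition string.
#' @param table reference table from \code{\link{karyotypeTable}}.
#' @return data.frame with columns category, observed, expected, difference
#'   (observed - expected) and an attribute/column-independent logical
#'   \code{attr(, "consistent")} that is TRUE iff all differences are zero.
#' @export
verifyAdditivity <- function(observed, comp, table = karyotypeTable()) {
  stopifnot(is(observed, "Karyotype"))
  expected <- composeKaryotype(comp, table)
  obs <- categoryCounts(observed)
  exp <- categoryCounts(expected)
  rep <- data.frame(category = KARYOTYPE_CATEGORIES,
                    observed = as.integer(obs),
                    expected = as.integer(exp),
                    difference = as.integer(obs - exp),
                    row.names = NULL)
  attr(rep, "consistent") <- all(rep$difference == 0L)
  rep
}

#' Assign chromosomes to parental sets from GISH signal ratios
#'
#' Each chromosome carries a morphological category and the fraction of its
#' total two-channel GISH signal in the green channel. Chromosomes with
#' green fraction above \code{threshold + epsilon} go to the green-probe
#' genome's set, below \code{threshold - epsilon} to the red set; anything in
#' the dead zone (including exactly at the threshold) is reported as
#' ambiguous, never force-assigned.
#'
#' @param chromosomes data.frame with columns \code{category} (one of the
#'   Levan classes) and \code{green_fraction} in [0, 1].
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @param epsilon half-width of the ambiguity dead zone; default 0.
#' @return list with \code{Karyotype} elements \code{green}, \code{red},
#'   \code{ambiguous}.
#' @export
assignParentalSets <- function(chromosomes, threshold = 0.5, epsilon = 0) {
  if (!(is.numeric(threshold) && threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (nrow(chromosomes) == 0L)
    return(list(green = Karyotype(label = "green"),
                red = Karyotype(label = "red"),
                ambiguous = Karyotype(label = "ambiguous")))
  if (!all(c("category", "green_fraction") %in% colnames(chromosomes)))
    stop("chromosomes needs columns 'category' and 'green_fraction'")
  gf <- chromosomes$green_fraction
  if (any(gf < 0 | gf > 1)) stop("green_fraction must lie in [0, 1]")
  if (!all(chromosomes$category %in% KARYOTYPE_CATEGORIES))
    stop("unknown chromosome category; use ",
         paste(KARYOTYPE_CATEGORIES, collapse = ", "))
  grp <- ifelse(gf > threshold + epsilon, "green",
                ifelse(gf < threshold - epsilon, "red", "ambiguous"))
  countSet <- function(which) {
    cat <- factor(chromosomes$category[grp == which],
                  levels = KARYOTYPE_CATEGORIES)
    tt <- table(cat)
    Karyotype(tt["metacentric"], tt["submetacentric"], tt["subtelocentric"],
              tt["acrocentric"], label = which)
  }
  list(green = countSet("green"), red = countSet("red"),
       ambiguous = countSet("ambiguous"))
}
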