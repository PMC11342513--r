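#' Convert daily field measurements to per-ton emission-factor summaries
#'
#' Field campaigns report emission as a daily areal rate (kg ha^-1 day^-1).
#' The emission factor per ton of product is obtained by multiplying by the
#' cropping period and dividing by the yield:
#' \deqn{\bar f = \textrm{daily mean} \times \textrm{days} / \textrm{yield},}
#' and the standard deviation rescales by exactly the same constant (a
#' linear change of units).
#'
#' @param measurements a data frame with columns `site` (or `study`),
#'   `daily_mean`, `daily_sd`, `period_days`, `yield_t_ha`, and optionally
#'   `n`.
#' @param n optional common sample size to attach to every converted study;
#'   overrides an `n` column.
#' @return A [study_collection()] in kg per ton.
#' @examples
#' convert_units(data.frame(site = "C2", daily_mean = 1.444,
#'                          daily_sd = 0.058, period_days = 109,
#'                          yield_t_ha = 7.6), n = 10)
#' @export
convert_units <- function(measurements, n = NULL) {
  m <- as.data.frame(measurements)
  if (!("site" %in% names(m)) && "study" %in% names(m))
    names(m)[names(m) == "study"] <- "site"
  need <- c("site", "daily_mean", "daily_sd", "period_days", "yield_t_ha")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(m$period_days <= 0)) stop("period_days must be > 0")
  if (any(m$yield_t_ha <= 0)) stop("yield must be > 0")
  if (any(m$daily_sd < 0)) stop("daily_sd must be >= 0")
  fac <- m$period_days / m$yield_t_ha
  if (is.null(n) && "n" %in% names(m)) n <- m$n
  study_collection(m$site, n = n, mean = m$daily_mean * fac,
                   sd = m$daily_sd * fac)
}

#' The rice-methane case study collection
#'
#' Methane emission factors for three neighbouring rice-paddy sites (C2, C3,
#' C4) near Hue, central Vietnam, early 2018 season, measured by the closed
#' static-chamber technique (Vo et al. 2018) and converted to kg CH4 per ton
#' of rice. Each site was sampled on 10 dates, so \eqn{n_i = 10} and
#' \eqn{k = 3}, \eqn{N = 30}. The three site means (20.7, 28.6, 27.4 kg/ton)
#' disagree far beyond their within-site spreads, which is exactly the
#' situation the ANOVA variance estimator addresses.
#'
#' @return A [study_collection()] with k = 3 and N = 30.
#' @examples
#' ef_pool(rice_case_study())
#' @export
rice_case_study <- function() {
  path <- system.file("extdata", "vo2018_ch4_rice.csv", package = "efpool",
                      mustWork = TRUE)
  convert_units(utils::read.csv(path, comment.char = "#"))
}

#' Read study summaries from a delimited text file
#'
#' Expects a header with columns `study` (or `site`), `mean`, and optionally
#' `n` and `sd`; the delimiter (comma or tab) is auto-detected. A file
#' without an `sd` column yields a collection usable for [overall_mean()]
#' only; the variance estimators will then raise an informative error.
#'
#' @param path file path.
#' @param n optional common sample size when the file has no `n` column.
#' @return A [study_collection()].
#' @export
read_study_summaries <- function(path, n = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data in ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  d <- utils::read.table(text = lines, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         strip.white = TRUE)
  nm <- names(d)
  if (!("study" %in% nm) && "site" %in% nm) names(d)[nm == "site"] <- "study"
  if (!("study" %in% names(d))) stop("missing required column 'study'")
  if (!("mean" %in% names(d))) stop("missing required column 'mean'")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value in column '", col, "', data row ", bad[1],
           ": \"", d[[col]][bad[1]], "\"")
    v
  }
  study_collection(d$study,
                   n = if (!is.null(n)) n else if ("n" %in% names(d)) num("n") else NULL,
                   mean = num("mean"),
                   sd = if ("sd" %in% names(d)) num("sd") else NULL)
}

#' Write study summaries to a CSV file
#'
#' Values are written with 17 significant digits so that reading the file
#' back with [read_study_summaries()] reproduces the collection exactly.
#'
#' @param collection a [study_collection()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_study_summaries <- function(collection, path) {
  x <- as_study_collection(collection)
  fmt <- function(v) ifelse(is.na(v), "NA",
                            vapply(v, format, "", digits = 17))
  out <- data.frame(study = x$study, n = ifelse(is.na(x$n), "NA", x$n),
                    mean = fmt(x$mean), sd = fmt(x$sd))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
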