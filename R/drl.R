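# Diagnostic-reference-level statistics for CTDI_w surveys.
#
# National DRLs are third quartiles (type-7 linear-interpolation
# quantile) of per-hospital median CTDI_w; the indicative regional DRL
# is the median of the national values.  For even counts the regional
# median uses the lower-median convention by default: the survey's
# printed regional value for ten national entries corresponds to the
# lower order statistic, not the midpoint (17.7, where the midpoint
# would give 17.75).  The convention is exposed as an argument.

#' Surveyed national DRL aggregates
#'
#' Per-country third quartiles of median reported CTDI_w (mGy) for the
#' pelvic and prostate imaging protocols, as published by the European
#' survey this package models.
#'
#' @param site `"pelvis"` or `"prostate"`.
#' @return Named numeric vector of national CTDI_w third quartiles (mGy).
#' @export
builtin_national_drls <- function(site = c("pelvis", "prostate")) {
  site <- match.arg(site)
  switch(site,
    pelvis = c(A = 17.8, B = 16.9, C = 22.0, D = 16.0, E = 37.6, F = 15.6,
               G = 11.0, H = 17.7, K = 21.7, M = 22.0),
    prostate = c(C = 32.2, D = 16.0, F = 19.7, G = 11.0, H = 13.5, J = 3.7,
                 L = 16.0, M = 9.6, O = 11.3))
}

.check_records <- function(records) {
  req <- c("country", "hospital", "ctdiw_mGy")
  if (!all(req %in% names(records)))
    stop("survey records need columns ", paste(req, collapse = ", "))
  if (any(records$ctdiw_mGy <= 0)) stop("CTDI_w values must be positive")
  records
}

#' Per-hospital median CTDI_w
#'
#' @param records Survey record data frame (see
#'   [generate_survey_records()] for the schema).
#' @param site Optional site filter (matches the `site` column).
#' @return Data frame `country`, `hospital`, `median_ctdiw_mGy`; empty if
#'   no records match the site.
#' @export
hospital_medians <- function(records, site = NULL) {
  .check_records(records)
  if (!is.null(site) && "site" %in% names(records))
    records <- records[records$site == site, , drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(country = character(), hospital = character(),
                      median_ctdiw_mGy = numeric()))
  agg <- stats::aggregate(ctdiw_mGy ~ country + hospital, data = records,
                          FUN = stats::median)
  names(agg)[3] <- "median_ctdiw_mGy"
  agg[order(agg$country, agg$hospital), , drop = FALSE]
}

#' National DRL: third quartile of hospital medians
#'
#' 75th percentile with the type-7 (linear interpolation between order
#' statistics) quantile rule; a single hospital's median is its own
#' third quartile.
#'
#' @param hospital_medians Numeric vector of hospital median CTDI_w for
#'   one country, or the data frame from [hospital_medians()].
#' @param country Country code, required with the data-frame form.
#' @return National DRL in mGy.
#' @export
national_drl <- function(hospital_medians, country = NULL) {
  if (is.data.frame(hospital_medians)) {
    if (is.null(country)) stop("give `country` with a data frame input")
    hospital_medians <-
      hospital_medians$median_ctdiw_mGy[hospital_medians$country == country]
  }
  if (length(hospital_medians) < 1) stop("no hospital medians")
  unname(stats::quantile(hospital_medians, 0.75, type = 7))
}

#' Regional DRL: median of national values
#'
#' @param national_values Numeric vector of national DRLs (mGy).
#' @param convention Even-count median convention: `"lower"` (default,
#'   the lower order statistic) or `"midpoint"` (arithmetic mean of the
#'   two central order statistics).
#' @return Regional DRL in mGy; always within the range of the inputs.
#' @export
regional_drl <- function(national_values, convention = c("lower",
                                                         "midpoint")) {
  convention <- match.arg(convention)
  n <- length(national_values)
  if (n < 1) stop("need at least one national value")
  s <- sort(national_values)
  if (n %% 2 == 1) return(unname(s[(n + 1) / 2]))
  if (convention == "lower") unname(s[n / 2])
  else unname((s[n / 2] + s[n / 2 + 1]) / 2)
}

#' DRL summary report
#'
#' Computes per-country national DRLs (third quartiles of hospital
#' medians) and the regional DRL (median of national values), shaped like
#' the survey's published country tables.
#'
#' @param records Survey records; ignored when `national` is given.
#' @param national Optional named vector of pre-aggregated national
#'   values (e.g. [builtin_national_drls()]).
#' @param site Optional site filter for `records`.
#' @param convention Regional median convention, see [regional_drl()].
#' @return A `drl_summary`: data frame of per-country third quartiles
#'   with attribute `regional_mGy`; zero rows for empty input.
#' @export
drl_report <- function(records = NULL, national = NULL, site = NULL,
                       convention = "lower") {
  if (is.null(national)) {
    if (is.null(records)) stop("give `records` or `national`")
    hm <- hospital_medians(records, site = site)
    if (nrow(hm) == 0) {
      out <- data.frame(country = character(),
                        third_quartile_ctdiw_mGy = numeric())
      return(structure(out, regional_mGy = NA_real_, site = site,
                       class = c("drl_summary", "data.frame")))
    }
    countries <- sort(unique(hm$country))
    national <- vapply(countries, function(co) national_drl(hm, co),
                       numeric(1))
  }
  out <- data.frame(country = names(national),
                    third_quartile_ctdiw_mGy = round(unname(national), 1))
  structure(out,
            regional_mGy = regional_drl(unname(national), convention),
            site = site, class = c("drl_summary", "data.frame"))
}

#' @export
print.drl_summary <- function(x, ...) {
  cat("DRL summary", if (!is.null(attr(x, "site")))
    paste0("(", attr(x, "site"), ")"), "\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Regional (median of national values): %.1f mGy\n",
              attr(x, "regional_mGy")))
  invisible(x)
}

#' Write a DRL summary to CSV
#'
#' @param x A `drl_summary`.
#' @param path Output path; the regional value is appended as a final
#'   `REGIONAL` row.
#' @export
write_drl_report <- function(x, path) {
  out <- rbind(x, data.frame(country = "REGIONAL",
                             third_quartile_ctdiw_mGy =
                               attr(x, "regional_mGy")))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
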