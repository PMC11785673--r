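#' BBCH phases tracked by the spring survey
#'
#' The ten 3-digit BBCH codes used for hazelnut spring phenology: female
#' reproductive phases (61P begin of flowering ... 71P clusters visible) and
#' vegetative phases (03VP swollen buds ... 15V more leaves unfolded),
#' listed in developmental order within each category.
#'
#' @return data.frame with columns `code` and `category`
#'   (`"reproductive"`/`"vegetative"`).
#' @export
bbch_phases <- function() {
  data.frame(
    code = c("61P", "64P", "67P", "70P", "71P",
             "03VP", "07VP", "10V", "13V", "15V"),
    category = rep(c("reproductive", "vegetative"), each = 5)
  )
}

#' Default source-scale to BBCH mapping
#'
#' Ships as an editable CSV (`extdata/scale_mapping.csv`) with the ten
#' spring BBCH codes preloaded as identity entries; surveys coded on a
#' national scale can extend it with their own `source_code` rows.
#'
#' @return data.frame with columns `source_code`, `bbch_code`.
#' @export
default_scale_mapping <- function() {
  path <- system.file("extdata", "scale_mapping.csv", package = "phenomatch")
  if (nzchar(path)) utils::read.csv(path, colClasses = "character")
  else data.frame(source_code = bbch_phases()$code,
                  bbch_code = bbch_phases()$code)
}

#' Load and map ground phenology observations
#'
#' Reads weekly survey rows (orchard, date, phase code in the source scale),
#' maps codes to 3-digit BBCH, collapses duplicates (same orchard, date,
#' code) and rejects rows with unparseable dates. Unmapped codes are kept
#' with `bbch = NA` so they can be audited.
#'
#' @param table data.frame with columns `orchard_id`, `date`, `code` (or a
#'   CSV path).
#' @param mapping data.frame `source_code` -> `bbch_code`; defaults to
#'   [default_scale_mapping()].
#' @return list with `observations` (columns `orchard_id`, `date`,
#'   `raw_code`, `bbch`) and `report` (counts of mapped, unmapped,
#'   duplicates, rejected_dates).
#' @export
load_observations <- function(table, mapping = default_scale_mapping()) {
  if (is.character(table)) table <- utils::read.csv(table)
  need <- c("orchard_id", "date", "code")
  if (!all(need %in% names(table)))
    phen_error("phen_bad_input",
               paste("observation table needs columns:", paste(need, collapse = ", ")))
  dates <- as.Date(as.character(table$date), format = "%Y-%m-%d")
  rejected <- sum(is.na(dates))
  if (rejected > 0)
    message(sprintf("ground_obs: rejected %d rows with unparseable dates", rejected))
  keep <- !is.na(dates)
  obs <- data.frame(orchard_id = as.character(table$orchard_id)[keep],
                    date = dates[keep],
                    raw_code = as.character(table$code)[keep])
  dup <- duplicated(obs[c("orchard_id", "date", "raw_code")])
  n_dup <- sum(dup)
  obs <- obs[!dup, , drop = FALSE]
  obs$bbch <- mapping$bbch_code[match(obs$raw_code, mapping$source_code)]
  report <- list(mapped = sum(!is.na(obs$bbch)),
                 unmapped = sum(is.na(obs$bbch)),
                 duplicates = n_dup,
                 rejected_dates = rejected)
  list(observations = obs[order(obs$orchard_id, obs$date), , drop = FALSE],
       report = report)
}

#' Phenological-year assignment
#'
#' Female flowering brackets the calendar boundary, so December observations
#' belong to the following phenological year by default (an observation on
#' 2019-12-20 is part of the 2020 season). Controlled by `december_to_next`.
#'
#' @keywords internal
pheno_year <- function(date, december_to_next = TRUE) {
  y <- as.integer(format(date, "%Y"))
  if (december_to_next) y <- y + (as.integer(format(date, "%m")) == 12L)
  y
}

## DOY on the phenological-year axis: December days get negative values
## relative to the following January 1 so differences stay continuous.
pheno_doy <- function(date, december_to_next = TRUE) {
  y <- pheno_year(date, december_to_next)
  as.integer(date - as.Date(sprintf("%d-01-01", y))) + 1L
}

#' Reduce weekly observations to per-orchard-year phase onsets
#'
#' With the default `"first-seen"` rule the onset of a phase in an
#' orchard-year is the earliest day it was recorded; weekly survey cadence
#' bounds its overshoot of the true onset at 7 days. The `"median-seen"`
#' alternative takes the median recorded day. Phases never observed in an
#' orchard-year simply have no row.
#'
#' @param observations mapped observations from [load_observations()].
#' @param rule `"first-seen"` (default) or `"median-seen"`.
#' @param december_to_next assign December observations to the next
#'   phenological year (default TRUE).
#' @return data.frame `orchard_id`, `year`, `bbch`, `onset_doy`, `n_obs`.
#'   `onset_doy` is on the phenological-year axis (December = negative).
#' @export
phase_onsets <- function(observations, rule = c("first-seen", "median-seen"),
                         december_to_next = TRUE) {
  rule <- match.arg(rule)
  obs <- observations[!is.na(observations$bbch), , drop = FALSE]
  if (nrow(obs) == 0L)
    return(data.frame(orchard_id = character(), year = integer(),
                      bbch = character(), onset_doy = integer(),
                      n_obs = integer()))
  obs$year <- pheno_year(obs$date, december_to_next)
  obs$pdoy <- pheno_doy(obs$date, december_to_next)
  pick <- switch(rule,
                 "first-seen" = function(d) min(d),
                 "median-seen" = function(d) stats::median(d))
  agg <- stats::aggregate(pdoy ~ orchard_id + year + bbch, data = obs,
                          FUN = function(d) c(onset = pick(d), n = length(d)))
  out <- data.frame(orchard_id = agg$orchard_id, year = agg$year,
                    bbch = agg$bbch,
                    onset_doy = as.integer(round(agg$pdoy[, "onset"])),
                    n_obs = as.integer(agg$pdoy[, "n"]))
  out[order(out$orchard_id, out$year, out$bbch), , drop = FALSE]
}
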