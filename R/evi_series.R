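#' EVI time-series carrier
#'
#' The pipeline's carrier type: one pixel's dated vegetation-index values with
#' a quality flag per entry. Stored as a `data.frame` with columns `date`
#' (`Date`), `evi` (numeric) and `flag` (one of `"ok"`, `"discarded"`,
#' `"missing"`), plus `pixel_id` and `cadence` attributes.
#'
#' @param pixel_id identifier for the pixel.
#' @param date `Date` vector, strictly increasing.
#' @param evi numeric vector of index values; `NA` allowed for missing entries.
#' @param flag character vector of per-entry flags; defaults to `"ok"`
#'   (`"missing"` where `evi` is `NA`).
#' @param cadence nominal step between entries in days (8 for composites,
#'   1 for daily curves).
#' @return an `evi_ts` object (a data.frame).
#' @export
evi_series <- function(pixel_id, date, evi, flag = NULL, cadence = 8) {
  date <- as.Date(date)
  if (anyNA(date)) phen_error("phen_bad_input", "unparseable dates in series")
  if (is.unsorted(date, strictly = TRUE))
    phen_error("phen_bad_input", "dates must be strictly increasing per pixel")
  if (is.null(flag)) flag <- ifelse(is.na(evi), "missing", "ok")
  if (length(flag) == 1L) flag <- rep(flag, length(date))
  if (!all(flag %in% c("ok", "discarded", "missing")))
    phen_error("phen_bad_input", "flags must be ok/discarded/missing")
  stopifnot(length(evi) == length(date), length(flag) == length(date))
  ok <- flag == "ok" & !is.na(evi)
  if (any(ok & (evi < -1 | evi > 1)))
    phen_error("phen_bad_input", "ok entries must have EVI in [-1, 1]")
  structure(
    data.frame(date = date, evi = as.numeric(evi), flag = flag),
    pixel_id = pixel_id, cadence = cadence,
    class = c("evi_ts", "data.frame")
  )
}

#' @export
print.evi_ts <- function(x, ...) {
  cat(sprintf("<evi_ts> pixel %s: %d entries (%d ok), %s to %s, cadence %d d\n",
              attr(x, "pixel_id"), nrow(x), sum(x$flag == "ok"),
              min(x$date), max(x$date), attr(x, "cadence")))
  invisible(x)
}

## rebuild an evi_ts keeping identity attributes
evi_ts_like <- function(template, date, evi, flag, cadence = NULL) {
  structure(
    data.frame(date = as.Date(date), evi = as.numeric(evi), flag = flag),
    pixel_id = attr(template, "pixel_id"),
    cadence = cadence %||% attr(template, "cadence"),
    class = c("evi_ts", "data.frame")
  )
}
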