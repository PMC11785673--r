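#' Day of year of a date (Jan 1 = 1)
#' @param date a `Date` vector
#' @return integer vector
#' @keywords internal
doy <- function(date) as.integer(format(date, "%j"))

#' Number of days in a calendar year
#' @keywords internal
days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

## Deterministic per-(pixel, year) seed derivation. Counter-based so that
## adding pixels or years never shifts the substream of an earlier pixel-year.
## Kept well below .Machine$integer.max.
derive_seed <- function(base_seed, i, j = 0L) {
  (abs(as.integer(base_seed)) %% 60000L) * 32768L + (i %% 4096L) * 8L + (j %% 8L)
}

## Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phen_error <- function(class, message, ...) {
  stop(structure(class = c(class, "phenomatch_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
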