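#' Pair phenometrics with ground phase onsets
#'
#' Inner join of one phenometric column and one BBCH phase's onsets on
#' (orchard/pixel, year), through a pixel-to-orchard link table. Rows with a
#' missing side drop out of the pairing and are counted in the attached
#' report.
#'
#' @param metrics data.frame from [phenometric_table()] (one row per
#'   pixel-year, metric columns in DOY).
#' @param onsets data.frame from [phase_onsets()].
#' @param link data.frame `pixel_id`, `orchard_id`; defaults to the identity
#'   link (pixel ids are orchard ids).
#' @param metric metric column name (e.g. `"trs5_sos"`).
#' @param phase BBCH code (e.g. `"10V"`).
#' @return a `metric_phase_pairs` data.frame with columns `orchard_id`,
#'   `year`, `metric_doy`, `phase_doy` and attributes `metric`, `phase`,
#'   `n_unpaired`.
#' @export
pair_metric_phase <- function(metrics, onsets, metric, phase, link = NULL) {
  if (!metric %in% names(metrics))
    phen_error("phen_bad_input", paste("unknown metric:", metric))
  if (is.null(link))
    link <- data.frame(pixel_id = unique(metrics$pixel_id),
                       orchard_id = unique(metrics$pixel_id))
  m <- merge(metrics[c("pixel_id", "year", metric)], link, by = "pixel_id")
  m <- m[!is.na(m[[metric]]), , drop = FALSE]
  o <- onsets[onsets$bbch == phase & !is.na(onsets$onset_doy),
              c("orchard_id", "year", "onset_doy")]
  joined <- merge(m, o, by = c("orchard_id", "year"))
  out <- data.frame(orchard_id = joined$orchard_id, year = joined$year,
                    metric_doy = joined[[metric]],
                    phase_doy = joined$onset_doy)
  out <- out[order(out$orchard_id, out$year), , drop = FALSE]
  if (nrow(out) == 0L)
    warning(sprintf("no paired orchard-years for %s vs %s", metric, phase),
            call. = FALSE)
  structure(out, metric = metric, phase = phase,
            n_unpaired = (nrow(m) - nrow(out)) + (nrow(o) - nrow(out)),
            class = c("metric_phase_pairs", "data.frame"))
}

#' Bias of a metric against a ground phase
#'
#' Mean of (phenometric DOY - phase DOY): positive means the satellite
#' metric occurs later than the ground phase.
#'
#' @param pairs a [pair_metric_phase()] result (or any data.frame with
#'   `metric_doy` and `phase_doy`).
#' @return bias in days.
#' @export
bias_days <- function(pairs) {
  if (nrow(pairs) == 0L)
    phen_error("phen_undefined", "bias undefined on zero pairs")
  mean(pairs$metric_doy - pairs$phase_doy)
}

#' Root mean square deviation of a metric against a ground phase
#' @inheritParams bias_days
#' @return RMSD in days; always >= |bias|.
#' @export
rmsd_days <- function(pairs) {
  if (nrow(pairs) == 0L)
    phen_error("phen_undefined", "rmsd undefined on zero pairs")
  sqrt(mean((pairs$metric_doy - pairs$phase_doy)^2))
}

#' Spearman rank correlation with a small-sample exact p-value
#'
#' r_s is the Pearson correlation of average ranks. The two-sided p-value
#' uses the t approximation for n >= 10 and a permutation test below that
#' (all n! permutations when n <= 7, otherwise 1e5 seeded draws), because
#' per-cell sample sizes can be small after stratification.
#'
#' @inheritParams bias_days
#' @param n_perm permutation draws for 7 < n < 10 (default 1e5).
#' @param perm_seed seed for the sampled permutations (default 1).
#' @return list `r_s`, `p_value`, `n`, `method`.
#' @export
spearman_rs <- function(pairs, n_perm = 1e5, perm_seed = 1) {
  x <- pairs$metric_doy; y <- pairs$phase_doy
  n <- length(x)
  if (n < 3) phen_error("phen_undefined", "need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_s = NA_real_, p_value = NA_real_, n = n,
                method = "undefined_constant_column"))
  rs_of <- function(a, b) stats::cor(rank(a), rank(b))
  r <- rs_of(x, y)
  if (n >= 10) {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  } else if (n <= 7) {
    perms <- all_permutations(n)
    stat <- apply(perms, 1, function(idx) rs_of(x, y[idx]))
    p <- mean(abs(stat) >= abs(r) - 1e-12)
    method <- "exact-permutation"
  } else {
    stat <- with_seed(perm_seed, replicate(n_perm, rs_of(x, sample(y))))
    p <- (sum(abs(stat) >= abs(r) - 1e-12) + 1) / (n_perm + 1)
    method <- "sampled-permutation"
  }
  list(r_s = r, p_value = min(p, 1), n = n, method = method)
}

## all permutations of 1..n as a matrix (n! rows); n <= 7 keeps this small
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Distribution summary of transition dates
#'
#' 25th/50th/75th percentiles (linear interpolation) and mean, the summary
#' behind the violin-plot comparisons of ground phases and phenometrics.
#'
#' @param dates numeric vector of days of year.
#' @param label group label.
#' @return one-row data.frame `label`, `p25`, `p50`, `p75`, `mean`, `n`.
#' @export
summarize_dates <- function(dates, label = "") {
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0L)
    phen_error("phen_undefined", "cannot summarize an empty set of dates")
  q <- stats::quantile(dates, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(label = label, p25 = q[1], p50 = q[2], p75 = q[3],
             mean = mean(dates), n = length(dates))
}

#' Full metric-by-phase comparison table
#'
#' One row of (n, bias, RMSD, r_s, p, significance at 0.05) per
#' (phenometric, BBCH phase) combination with at least `min_n` paired
#' orchard-years, pooling years. Optionally stratifies by pixel hazelnut
#' coverage fraction (split at `coverage_split`, default 75%), and can apply
#' a Benjamini-Hochberg adjustment across cells (off by default, matching
#' per-cell significance flagging).
#'
#' @param metrics data.frame from [phenometric_table()].
#' @param onsets data.frame from [phase_onsets()].
#' @param link optional pixel-to-orchard link table.
#' @param metric_names metrics to compare (default all eight).
#' @param phases BBCH codes to compare (default the ten spring phases).
#' @param min_n minimum paired n per cell (default 3).
#' @param coverage optional data.frame `pixel_id`, `coverage`; when given,
#'   results are additionally stratified at `coverage_split`.
#' @param coverage_split coverage threshold for stratification (default 0.75).
#' @param p_adjust apply Benjamini-Hochberg across cells (default FALSE).
#' @return long data.frame: `metric`, `phase`, `stratum`, `n`, `bias`,
#'   `rmsd`, `r_s`, `p_value`, `significant_05`.
#' @export
compare_all <- function(metrics, onsets, link = NULL,
                        metric_names = .metric_names,
                        phases = bbch_phases()$code,
                        min_n = 3, coverage = NULL, coverage_split = 0.75,
                        p_adjust = FALSE) {
  strata <- list(all = metrics)
  if (!is.null(coverage)) {
    cov <- coverage$coverage[match(metrics$pixel_id, coverage$pixel_id)]
    strata <- c(strata,
                list("coverage_ge_split" = metrics[!is.na(cov) & cov >= coverage_split, ],
                     "coverage_lt_split" = metrics[!is.na(cov) & cov < coverage_split, ]))
  }
  rows <- list()
  for (stratum in names(strata)) {
    mt <- strata[[stratum]]
    for (metric in metric_names) for (phase in phases) {
      pairs <- suppressWarnings(
        pair_metric_phase(mt, onsets, metric, phase, link))
      if (nrow(pairs) < min_n) next
      sp <- spearman_rs(pairs)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, phase = phase, stratum = stratum,
        n = nrow(pairs), bias = bias_days(pairs), rmsd = rmsd_days(pairs),
        r_s = sp$r_s, p_value = sp$p_value)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(metric = character(), phase = character(),
                      stratum = character(), n = integer(), bias = numeric(),
                      rmsd = numeric(), r_s = numeric(), p_value = numeric(),
                      significant_05 = logical()))
  out <- do.call(rbind, rows)
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant_05 <- !is.na(out$p_value) & out$p_value < 0.05
  out
}
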