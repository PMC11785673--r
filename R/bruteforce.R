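#' Brute-force phenometric extraction on a dense grid
#'
#' An independent reference implementation of the eight phenometrics that
#' works purely from sampled curve values: the curve is evaluated on a dense
#' day grid (default step 0.01 d), derivatives and curvature are taken by
#' central finite differences, and every search is an exhaustive scan. It is
#' used as the numerical oracle for the analytic extractors and to compute
#' the generator's truth records; it shares no code with [extract_all()].
#'
#' @param curve_fn function of t returning curve values (e.g. a closure over
#'   [evaluate_curve()] or any smooth seasonal function).
#' @param t_range numeric length-2, grid range in days of year.
#' @param step grid step in days (default 0.01).
#' @return named numeric vector of the eight metrics (continuous days, not
#'   rounded), with `NA` where a metric does not exist.
#' @export
phenometrics_bruteforce <- function(curve_fn, t_range = c(-31, 397),
                                    step = 0.01) {
  t <- seq(t_range[1], t_range[2], by = step)
  v <- curve_fn(t)
  n <- length(t)
  peak_i <- which.max(v)
  trough_i <- which.min(v[seq_len(peak_i)])
  baseline <- v[trough_i]; peak <- v[peak_i]
  amp <- peak - baseline
  seg <- trough_i:peak_i
  ts <- t[seg]; vs <- v[seg]

  out <- stats::setNames(rep(NA_real_, 8),
                         c("der_sos", "der_pos", "trs2_sos", "trs5_sos",
                           "gu_ud", "gu_sd", "greenup", "maturity"))
  if (amp <= 0 || length(seg) < 5) return(out)
  out[["der_pos"]] <- t[peak_i]

  cross <- function(frac) {
    thr <- baseline + frac * amp
    i <- which(vs >= thr)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(ts[1])
    # linear interpolation between bracketing dense-grid samples
    ts[i - 1] + step * (thr - vs[i - 1]) / (vs[i] - vs[i - 1])
  }
  out[["trs2_sos"]] <- cross(0.2)
  out[["trs5_sos"]] <- cross(0.5)

  # numerical first derivative on the full grid (central differences)
  d1 <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * step), NA)
  d1s <- d1[seg]
  j <- which.max(d1s)
  t_star <- ts[j]
  out[["der_sos"]] <- t_star
  k <- d1s[j]
  if (is.finite(k) && k > 0) {
    v_star <- vs[j]
    out[["gu_ud"]] <- t_star + (baseline - v_star) / k
    out[["gu_sd"]] <- t_star + (peak - v_star) / k
  }

  # numerical curvature change rate on the rising limb
  d2 <- c(NA, (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / step^2, NA)
  K <- d2 / (1 + d1^2)^1.5
  Kp <- c(NA, (K[3:n] - K[1:(n - 2)]) / (2 * step), NA)
  kps <- Kp[seg]
  finite <- which(is.finite(kps))
  if (length(finite) > 4) {
    idx <- finite[-c(1, length(finite))]
    is_max <- kps[idx] > kps[idx - 1] & kps[idx] >= kps[idx + 1]
    loc <- idx[is_max]
    # drop numerically flat ripples in the tails: a genuine curvature-rate
    # maximum on the rising limb is a sizeable fraction of the global one
    loc <- loc[kps[loc] > 0.05 * max(kps, na.rm = TRUE)]
    if (length(loc) >= 1) {
      # floating-point ripple can split one maximum into several grid maxima
      # a fraction of a day apart: merge maxima within 2 days into clusters
      # and keep each cluster's highest point
      cluster <- cumsum(c(1, diff(ts[loc]) > 2))
      peaks <- vapply(split(loc, cluster),
                      function(ix) ix[which.max(kps[ix])], numeric(1))
      if (length(peaks) >= 2) {
        out[["greenup"]] <- ts[peaks[1]]
        out[["maturity"]] <- ts[peaks[2]]  # second sigmoid curvature-rate max
      }
    }
  }
  out
}
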