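#' Extract an ROI photon-count trace from a scan series
#'
#' Averages photon counts per pixel inside a fixed rectangular ROI for
#' every frame and normalises the series to the first frame (the same-size
#' box is applied to every frame of a movie).
#'
#' @param series a [scan_series].
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive).
#' @return A tibble of class `roi_trace` with columns `frame` (0-based),
#'   `t` (s), `mean_counts` (counts/pixel), `normalized`; attributes `roi`
#'   and `frame_interval`.
#' @export
roi_trace <- function(series, roi) {
  stopifnot(inherits(series, "scan_series"))
  d <- dim(series$frames)
  roi <- as.integer(roi)
  if (length(roi) != 4 || roi[1] < 1 || roi[3] < 1 ||
      roi[2] > d[1] || roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4]) {
    abort_rmquant("`roi` must be c(row_min, row_max, col_min, col_max) within the frame",
                  "rmquant_parameter_error")
  }
  means <- apply(series$frames[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE],
                 3, mean)
  if (means[1] == 0) {
    abort_rmquant("first-frame ROI mean is zero; cannot normalise",
                  "rmquant_normalization_error")
  }
  out <- tibble::tibble(frame = seq_along(means) - 1L, t = series$t,
                        mean_counts = means, normalized = means / means[1])
  attr(out, "roi") <- roi
  attr(out, "frame_interval") <- series$frame_interval
  class(out) <- c("roi_trace", class(out))
  out
}

#' Fit a single-exponential dissociation curve
#'
#' Fits `mean_counts = baseline + i0 * exp(-k * t)` by nonlinear least
#' squares in linear space (log-linear regression is biased by Poisson
#' noise at low counts), with `k` bounded at 0. With `baseline = FALSE` a
#' pure exponential `i0 * exp(-k * t)` is fitted instead.
#'
#' @param trace a `roi_trace`, `decay_series`, or any data frame with
#'   columns `t` and `mean_counts` (or `counts`).
#' @param baseline include an additive baseline term (default TRUE).
#' @param conf_level confidence level for the CI on `k`.
#' @return A list of class `decay_fit`: `k` (s^-1), `k_ci` (two-sided),
#'   `i0`, `baseline`, `residuals`, `fitted`, `data`, `flat` (TRUE when the
#'   series shows no decaying trend, in which case `k = 0` and `i0` is
#'   unidentifiable), and the underlying `fit` object.
#' @export
counts_column <- function(trace) {
  if ("mean_counts" %in% names(trace)) trace[["mean_counts"]]
  else if ("counts" %in% names(trace)) trace[["counts"]]
  else NULL
}

fit_dissociation <- function(trace, baseline = TRUE, conf_level = 0.95) {
  y <- counts_column(trace)
  t <- trace[["t"]]
  if (is.null(y) || is.null(t)) {
    abort_rmquant("`trace` needs columns t and mean_counts (or counts)",
                  "rmquant_parameter_error")
  }
  if (length(y) < 5) {
    abort_rmquant("need at least 5 frames to fit", "rmquant_fit_error")
  }
  if (stats::sd(y) == 0 || stats::cor(t, y) >= 0) {
    # constant or non-decaying series: k = 0, amplitude unidentifiable
    return(structure(
      list(k = 0, k_ci = c(NA_real_, NA_real_), k_se = NA_real_,
           i0 = NA_real_, baseline = mean(y),
           residuals = y - mean(y), fitted = rep(mean(y), length(y)),
           data = tibble::tibble(t = t, mean_counts = y),
           flat = TRUE, fit = NULL),
      class = "decay_fit"
    ))
  }
  b0 <- if (baseline) min(y) else 0
  i00 <- max(y) - b0
  pos <- which(y - b0 > i00 * 0.05)
  k0 <- tryCatch({
    lf <- stats::lm(log(y[pos] - b0 + 1e-9 * i00) ~ t[pos])
    max(-unname(stats::coef(lf)[2]), 1e-6)
  }, error = function(e) 1 / max(t))
  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (baseline) {
      minpack.lm::nlsLM(y ~ b + i0 * exp(-k * t), data = df,
                        start = list(b = b0, i0 = i00, k = k0),
                        lower = c(b = -Inf, i0 = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ i0 * exp(-k * t), data = df,
                        start = list(i0 = i00 + b0, k = k0),
                        lower = c(i0 = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort_rmquant(paste("exponential fit failed to converge:",
                        conditionMessage(e)), "rmquant_fit_error")
  })
  cf <- stats::coef(fit)
  k_se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["k"]], error = function(e) NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(k = unname(cf[["k"]]),
         k_ci = c(max(unname(cf[["k"]]) - z * k_se, 0),
                  unname(cf[["k"]]) + z * k_se),
         k_se = k_se,
         i0 = unname(cf[["i0"]]),
         baseline = if (baseline) unname(cf[["b"]]) else 0,
         residuals = stats::residuals(fit), fitted = stats::fitted(fit),
         data = tibble::tibble(t = t, mean_counts = y),
         flat = FALSE, fit = fit),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$flat) {
    cat("<decay_fit> flat series: k = 0 s^-1 (amplitude unidentifiable)\n")
  } else {
    cat(sprintf("<decay_fit> k = %.4g s^-1 [%.4g, %.4g], i0 = %.4g, baseline = %.4g\n",
                x$k, x$k_ci[1], x$k_ci[2], x$i0, x$baseline))
  }
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "i0", "baseline"),
    estimate = c(x$k, x$i0, x$baseline),
    std.error = c(x$k_se,
                  if (!is.null(x$fit)) sqrt(diag(stats::vcov(x$fit)))[["i0"]] else NA_real_,
                  if (!is.null(x$fit) && "b" %in% names(stats::coef(x$fit))) {
                    sqrt(diag(stats::vcov(x$fit)))[["b"]]
                  } else NA_real_)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(k = x$k, k_low = x$k_ci[1], k_high = x$k_ci[2],
                 i0 = x$i0, baseline = x$baseline,
                 sigma = stats::sd(x$residuals), n = length(x$residuals),
                 flat = x$flat)
}

#' Waiting time to first binding
#'
#' Automatic surrogate for the manual call of the binding start point: the
#' first frame whose ROI mean exceeds `mu_pre + k * sigma_pre`, where the
#' pre-binding statistics come from the first `n_pre` frames (the series is
#' assumed to start when the beads enter the protein channel). The waiting
#' time is `frame_interval` times the 0-based index of that frame.
#'
#' @param trace a `roi_trace` (or data frame with `t` and `mean_counts`).
#' @param n_pre number of leading frames taken as pre-binding.
#' @param k sd multiplier of the detection rule.
#' @return A list: `waiting_time_s`, `frame` (0-based), `threshold`.
#' @export
waiting_time <- function(trace, n_pre = 5, k = 5) {
  y <- counts_column(trace)
  t <- trace[["t"]]
  if (length(y) <= n_pre) {
    abort_rmquant("series shorter than the pre-binding window",
                  "rmquant_parameter_error")
  }
  mu <- mean(y[seq_len(n_pre)])
  sigma <- stats::sd(y[seq_len(n_pre)])
  thr <- mu + k * sigma
  hit <- which(y > thr)
  hit <- hit[hit > n_pre]
  if (length(hit) == 0) {
    abort_rmquant("no binding detected: trace never exceeds the threshold",
                  "rmquant_no_binding_error")
  }
  list(waiting_time_s = t[hit[1]], frame = hit[1] - 1L, threshold = thr)
}

#' Focal growth profiles by binding mode
#'
#' Averages normalised intensity versus time since binding detection for
#' groups of binding events, and separates flat profiles (condensate foci on
#' taut tethers) from growing profiles (foci at dangling DNA tips) by the
#' terminal/initial intensity ratio.
#'
#' @param traces data frame with columns `trace_id`, `group`, `t`, and
#'   `normalized` (each trace renormalised so its first frame after
#'   detection is 1).
#' @param ratio_threshold traces whose terminal/initial ratio exceeds this
#'   are classified `growing`, else `flat`.
#' @return A list of class `growth_profile`: `profile` tibble (`group`,
#'   `t`, `mean_normalized`, `sd_normalized`, `n`), `ratios` tibble
#'   (`trace_id`, `group`, `ratio`, `class`).
#' @export
focal_growth_profile <- function(traces, ratio_threshold = 1.5) {
  need <- c("trace_id", "group", "t", "normalized")
  if (!all(need %in% names(traces))) {
    abort_rmquant(paste("`traces` needs columns", paste(need, collapse = ", ")),
                  "rmquant_parameter_error")
  }
  profile <- traces |>
    dplyr::group_by(.data$group, .data$t) |>
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     sd_normalized = stats::sd(.data$normalized),
                     n = dplyr::n(), .groups = "drop")
  ratios <- traces |>
    dplyr::group_by(.data$trace_id, .data$group) |>
    dplyr::summarise(
      ratio = .data$normalized[which.max(.data$t)] /
        .data$normalized[which.min(.data$t)],
      .groups = "drop"
    ) |>
    dplyr::mutate(class = ifelse(.data$ratio > ratio_threshold,
                                 "growing", "flat"))
  structure(list(profile = profile, ratios = ratios,
                 ratio_threshold = ratio_threshold),
            class = "growth_profile")
}

#' @export
print.growth_profile <- function(x, ...) {
  cat("<growth_profile>\n")
  print(dplyr::count(x$ratios, .data$group, .data$class))
  invisible(x)
}
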