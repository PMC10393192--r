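#' Fraction of DNA bound from gel-lane intensities
#'
#' Fraction bound is computed by free-band depletion, `f = 1 - free/total`,
#' clamped to `[0, 1]`. Depletion is used rather than summing shifted
#' species because gels of cooperative binders show several shifted bands
#' plus well-trapped material; the per-lane total normalises loading.
#'
#' @param free free-band intensity (>= 0, <= total).
#' @param total total lane intensity (> 0).
#' @return fraction bound, dimensionless in `[0, 1]`. Vectorised.
#' @export
fraction_bound <- function(free, total) {
  if (any(!is.finite(total)) || any(total <= 0)) {
    abort_rmquant("`total` must be > 0", "rmquant_parameter_error")
  }
  if (any(free > total)) {
    abort_rmquant("`free` must not exceed `total`", "rmquant_parameter_error")
  }
  pmin(pmax(1 - free / total, 0), 1)
}

# first upward crossing of 0.5 in one replicate; errors when unreachable
c50_one_replicate <- function(conc, f) {
  o <- order(conc)
  conc <- conc[o]; f <- f[o]
  if (f[1] > 0.5) {
    abort_rmquant(
      sprintf("titration starts above 50%% bound (f = %.3g at %.3g nM)",
              f[1], conc[1]),
      "rmquant_presaturated_error"
    )
  }
  exact <- which(f == 0.5)
  if (length(exact) > 0) {
    i <- exact[1]
    return(list(c50 = conc[i], c_lo = conc[i], c_hi = conc[i]))
  }
  up <- which(f[-1] > 0.5 & f[-length(f)] < 0.5)
  if (length(up) == 0) {
    abort_rmquant(
      sprintf("titration never reaches 50%% bound (max f = %.3g)", max(f)),
      "rmquant_unsaturated_error"
    )
  }
  i <- up[1]
  c50 <- conc[i] + (0.5 - f[i]) / (f[i + 1] - f[i]) * (conc[i + 1] - conc[i])
  list(c50 = c50, c_lo = conc[i], c_hi = conc[i + 1])
}

#' C50 of a titration by linear interpolation
#'
#' The apparent-affinity statistic used for protein titration EMSAs: per
#' replicate, the concentration at which 50% of the substrate is bound,
#' located by linear interpolation at the first (lowest-concentration)
#' upward crossing of 0.5; replicates are aggregated with
#' [aggregate_replicates()].
#'
#' @param table a data frame with columns `concentration_nM` and either
#'   `fraction_bound` or both `free_intensity` and `total_intensity`; an
#'   optional `replicate` column separates replicate titrations.
#' @return A list of class `c50_result`: `c50` (aggregate mean, nM),
#'   `dispersion`, `dispersion_rule` (`"range"`, `"sd"` or
#'   `"single experiment"`), `replicates` tibble (`replicate`, `c50_nM`,
#'   `c_lo`, `c_hi`), `n_replicates`.
#' @export
c50 <- function(table) {
  if (!"concentration_nM" %in% names(table)) {
    abort_rmquant("`table` needs a concentration_nM column",
                  "rmquant_parameter_error")
  }
  if (!"fraction_bound" %in% names(table)) {
    if (!all(c("free_intensity", "total_intensity") %in% names(table))) {
      abort_rmquant("supply fraction_bound or free_intensity + total_intensity",
                    "rmquant_parameter_error")
    }
    table$fraction_bound <- fraction_bound(table$free_intensity,
                                           table$total_intensity)
  }
  if (!"replicate" %in% names(table)) table$replicate <- 1L
  reps <- table |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(d, key) {
      r <- c50_one_replicate(d$concentration_nM, d$fraction_bound)
      tibble::tibble(replicate = key$replicate, c50_nM = r$c50,
                     c_lo = r$c_lo, c_hi = r$c_hi)
    }) |>
    dplyr::bind_rows()
  agg <- aggregate_replicates(reps$c50_nM)
  structure(
    list(c50 = agg$mean, dispersion = agg$dispersion,
         dispersion_rule = agg$rule, replicates = reps,
         n_replicates = nrow(reps)),
    class = "c50_result"
  )
}

#' @export
print.c50_result <- function(x, ...) {
  if (x$dispersion_rule == "single experiment") {
    cat(sprintf("C50 = %.3g nM (single experiment)\n", x$c50))
  } else {
    cat(sprintf("C50 = %.3g nM +/- %.3g nM (mean +/- %s, n = %d)\n",
                x$c50, x$dispersion, x$dispersion_rule, x$n_replicates))
  }
  invisible(x)
}

#' Aggregate replicate C50 values
#'
#' Follows the replicate-count convention of the titration figures: two
#' replicates are reported as mean +/- range (here half of max - min),
#' three or more as mean +/- SD, and a single experiment is flagged.
#'
#' @param c50s numeric vector of per-replicate C50 values (nM).
#' @return A list with `mean`, `dispersion`, `rule`.
#' @export
aggregate_replicates <- function(c50s) {
  n <- length(c50s)
  if (n == 0) {
    abort_rmquant("no replicate C50 values", "rmquant_parameter_error")
  }
  if (n == 1) {
    list(mean = c50s, dispersion = NA_real_, rule = "single experiment")
  } else if (n == 2) {
    list(mean = mean(c50s), dispersion = diff(range(c50s)) / 2, rule = "range")
  } else {
    list(mean = mean(c50s), dispersion = stats::sd(c50s), rule = "sd")
  }
}

#' @export
tidy.c50_result <- function(x, ...) {
  x$replicates
}

#' @export
glance.c50_result <- function(x, ...) {
  tibble::tibble(c50_nM = x$c50, dispersion_nM = x$dispersion,
                 dispersion_rule = x$dispersion_rule,
                 n_replicates = x$n_replicates)
}
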