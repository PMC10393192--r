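#' Hill isotherm parameters
#'
#' Parameters for simulating an EMSA titration: fraction bound follows a
#' Hill curve `f(c) = c^n / (c^n + C50^n)` with optional additive noise,
#' clamped to `[0, 1]`. Defaults mirror the Rec114_C-Mei4_N titration on a
#' 150-bp substrate (half-saturation 90 nM, three replicates).
#'
#' @param c50_true true half-saturation concentration, nM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param concentrations strictly increasing protein concentrations in nM;
#'   the first may be 0 (no-protein lane).
#' @param noise_sd additive noise sd in fraction-bound units.
#' @param n_replicates replicate titrations to simulate.
#' @param seed integer seed.
#' @return A list of class `isotherm_params`.
#' @export
isotherm_params <- function(c50_true = 90, hill_n = 1,
                            concentrations = c(0, 12.5, 25, 50, 100, 200,
                                               400, 800),
                            noise_sd = 0, n_replicates = 3, seed = NULL) {
  check_positive(c50_true, "c50_true")
  check_positive(hill_n, "hill_n")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (any(concentrations < 0) || any(diff(concentrations) <= 0)) {
    abort_rmquant("`concentrations` must be non-negative and strictly increasing",
                  "rmquant_parameter_error")
  }
  structure(
    list(c50_true = c50_true, hill_n = hill_n,
         concentrations = concentrations, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "isotherm_params"
  )
}

#' Simulate an EMSA titration table
#'
#' @param ip an [isotherm_params] object.
#' @param substrate,construct labels carried into the table.
#' @return A tibble with columns `concentration_nM`, `replicate`,
#'   `fraction_bound`, `substrate`, `construct`, suitable for [c50()].
#' @export
simulate_titration <- function(ip, substrate = "150 bp",
                               construct = "Rec114C-Mei4N") {
  stopifnot(inherits(ip, "isotherm_params"))
  cc <- ip$concentrations
  f_true <- ifelse(cc == 0 & ip$c50_true > 0, 0,
                   cc^ip$hill_n / (cc^ip$hill_n + ip$c50_true^ip$hill_n))
  tab <- with_seed(ip$seed, {
    purrr::map_dfr(seq_len(ip$n_replicates), function(rep) {
      f <- f_true
      if (ip$noise_sd > 0) {
        f <- pmin(pmax(f + stats::rnorm(length(f), 0, ip$noise_sd), 0), 1)
      }
      tibble::tibble(concentration_nM = cc, replicate = rep,
                     fraction_bound = f)
    })
  })
  tab$substrate <- substrate
  tab$construct <- construct
  attr(tab, "isotherm") <- ip
  tab
}
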