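rm_config_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate_afm", "afm", "stoichiometry"),
    n_free = 10L,
    n_bound = 10L,
    particles_per_molecule = 2L,
    particle_volume = 145,     # nm^3, ~7 trimers of 20.7 nm^3
    particle_sigma = 4,        # nm, as-imaged footprint
    contour_length = 383,      # nm, the 1000-bp substrate
    persistence_length = 50,   # nm
    n_segments = 200L,
    image_size = 512L,
    rx = 1, ry = 1,
    dna_height = 2.5,
    psf_sigma = 2,
    background_sd = 0.05,
    k_sigma = 2,
    min_area = 20L,
    prune_len = 5L,
    smooth_window = 5L,
    end_tolerance = 20,
    V_p = 20.7,                # nm^3 per trimer
    out_dir = NULL
  )
}

#' Build a validated pipeline configuration
#'
#' All physical quantities are carried in nm / nm^3 / s; every parameter has
#' a documented default (see the source of `rm_config_defaults`). Unknown
#' keys are rejected by name. The configuration round-trips losslessly
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `rm_config`.
#' @export
rm_config <- function(...) {
  defaults <- rm_config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort_rmquant(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
                  "rmquant_config_error")
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  check_positive(cfg$contour_length, "contour_length")
  check_positive(cfg$persistence_length, "persistence_length")
  structure(cfg, class = "rm_config")
}

#' @rdname rm_config
#' @param config an `rm_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname rm_config
#' @export
read_config <- function(path) {
  rm_config(yaml::read_yaml(path))
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  substr(rlang::hash(cfg), 1, 12)
}

# deterministic particle placement: arclength fractions separated by at
# least `min_sep_frac` so rendered particles stay distinct regions
draw_fractions <- function(n, min_sep_frac = 0.12) {
  for (try in seq_len(200)) {
    f <- sort(stats::runif(n, 0.02, 0.98))
    if (n == 1 || min(diff(f)) >= min_sep_frac) return(f)
  }
  seq(0.1, 0.9, length.out = n)
}

simulate_one_molecule <- function(cfg, idx, n_particles) {
  wlc <- wlc_params(contour_length = cfg$contour_length,
                    persistence_length = cfg$persistence_length,
                    n_segments = cfg$n_segments)
  half <- cfg$image_size / 2
  for (attempt in seq_len(50)) {
    seed_i <- child_seed(cfg$seed, idx * 100 + attempt)
    chain <- sample_wlc_chain(wlc, seed = seed_i)
    chain$x <- chain$x - mean(chain$x) + half * cfg$rx
    chain$y <- chain$y - mean(chain$y) + half * cfg$ry
    pad <- 4 * cfg$psf_sigma + 8
    fits <- all(chain$x > pad & chain$x < cfg$image_size * cfg$rx - pad &
                  chain$y > pad & chain$y < cfg$image_size * cfg$ry - pad)
    if (fits) break
  }
  particles <- if (n_particles > 0) {
    fr <- with_seed(child_seed(cfg$seed, idx * 100 + 99),
                    draw_fractions(n_particles))
    purrr::map(fr, ~ particle_spec(.x, volume = cfg$particle_volume,
                                   footprint_sigma = cfg$particle_sigma))
  } else {
    list()
  }
  rp <- afm_render_params(rx = cfg$rx, ry = cfg$ry,
                          image_size = cfg$image_size,
                          dna_height = cfg$dna_height,
                          psf_sigma = cfg$psf_sigma,
                          background_sd = cfg$background_sd,
                          seed = child_seed(cfg$seed, idx))
  list(hm = render_afm_scene(list(chain), particles, rp),
       true_n_particles = n_particles)
}

#' Run the simulate-trace-quantify pipeline
#'
#' Executes the configured stages: renders free and protein-bound synthetic
#' AFM scenes (one molecule per scene), analyses every scene (background,
#' segmentation, skeleton trace, particle detection/classification, volume
#' integration), and estimates the trimer stoichiometry from the mean
#' bound-minus-free volume difference. Fully deterministic for a given
#' configuration: the seed fixes every random draw, and output files carry
#' the configuration hash.
#'
#' @param config an [rm_config()].
#' @return A list of class `rm_pipeline_result`: `molecules` tibble (per
#'   molecule: `molecule`, `true_n_particles`, contour/particle/volume
#'   measurements), `stoichiometry` tibble, `log` tibble of per-stage
#'   counts, `config`, `config_hash`. When `config$out_dir` is set, the
#'   molecule and stoichiometry tables are written there as CSV.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rm_config"))
  cfg <- config
  hash <- config_hash(cfg)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, message = msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort_rmquant(sprintf("stage '%s' failed: %s", stage,
                            conditionMessage(e)), "rmquant_stage_error")
    })
  }

  scenes <- NULL
  if ("simulate_afm" %in% cfg$stages) {
    scenes <- run_stage("simulate_afm", {
      n_p <- c(rep(0L, cfg$n_free), rep(cfg$particles_per_molecule, cfg$n_bound))
      purrr::imap(n_p, ~ simulate_one_molecule(cfg, .y, .x))
    })
    note("simulate_afm", sprintf("rendered %d scenes (%d free, %d bound)",
                                 length(scenes), cfg$n_free, cfg$n_bound))
  }

  molecules <- NULL
  if ("afm" %in% cfg$stages) {
    if (is.null(scenes)) {
      abort_rmquant("stage 'afm' failed: no scenes to analyse (include simulate_afm)",
                    "rmquant_stage_error")
    }
    molecules <- run_stage("afm", {
      purrr::imap_dfr(scenes, function(sc, i) {
        bg <- estimate_background(sc$hm)
        segs <- segment_molecules(sc$hm, bg, k_sigma = cfg$k_sigma,
                                  min_area = cfg$min_area)
        kept <- segs[segs$kept, ]
        if (nrow(kept) == 0) {
          abort_rmquant(sprintf("no molecule found in scene %d", i),
                        "rmquant_stage_error")
        }
        region <- kept$region[[which.max(kept$area_px)]]
        tr <- analyze_molecule(sc$hm, region, bg,
                               prune_len = cfg$prune_len,
                               smooth_window = cfg$smooth_window)
        dplyr::bind_cols(
          tibble::tibble(molecule = i,
                         true_n_particles = sc$true_n_particles),
          molecule_table(list(tr))[, -1]
        )
      })
    })
    note("afm", sprintf("analysed %d molecules", nrow(molecules)))
  }

  stoich <- NULL
  if ("stoichiometry" %in% cfg$stages && !is.null(molecules)) {
    stoich <- run_stage("stoichiometry", {
      free <- molecules[molecules$n_particles == 0, ]
      bound <- molecules[molecules$n_particles > 0, ]
      if (nrow(free) == 0 || nrow(bound) == 0) {
        abort_rmquant("need both free and bound molecules for stoichiometry",
                      "rmquant_stage_error")
      }
      V_d <- mean(bound$volume_nm3) - mean(free$volume_nm3)
      count_trimers(stoichiometry_inputs(V_d = V_d, V_p = cfg$V_p,
                                         N_p_mean = mean(bound$n_particles)))
    })
    note("stoichiometry",
         sprintf("V_d = %.1f nm^3, %.2f trimers/site",
                 stoich$V_d, stoich$trimers_per_site))
  }

  result <- structure(
    list(molecules = molecules, stoichiometry = stoich,
         log = dplyr::bind_rows(log), config = cfg, config_hash = hash),
    class = "rm_pipeline_result"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(molecules)) {
      write_results_csv(molecules, file.path(cfg$out_dir, "molecules.csv"),
                        units = "contour_length_nm nm; volume_nm3 nm^3",
                        seed = cfg$seed, config_hash = hash)
    }
    if (!is.null(stoich)) {
      write_results_csv(stoich, file.path(cfg$out_dir, "stoichiometry.csv"),
                        units = "V_d nm^3; V_p nm^3",
                        seed = cfg$seed, config_hash = hash)
    }
  }
  result
}

#' @export
print.rm_pipeline_result <- function(x, ...) {
  cat(sprintf("<rm_pipeline_result> config %s\n", x$config_hash))
  print(x$log)
  if (!is.null(x$stoichiometry)) print(x$stoichiometry)
  invisible(x)
}
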