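#' Contour-length statistics by particle count
#'
#' Groups traced molecules as free (no particles) or by the number of bound
#' particles (1, 2, 3, >3), reports per-group mean, SD and N, pairwise
#' two-tailed t statistics between groups, and a Kruskal-Wallis statistic
#' across groups — the comparison used to show DNA shortening upon protein
#' binding.
#'
#' @param molecules data frame with columns `contour_length_nm` and
#'   `n_particles` (e.g. from [molecule_table()]).
#' @param welch use Welch's t-test instead of Student's (equal-variance)
#'   t-test. Default `FALSE` (Student's).
#' @return A list of class `contour_length_stats`: `groups` tibble
#'   (`group`, `n`, `mean_nm`, `sd_nm`), `pairwise` tibble (`group1`,
#'   `group2`, `t`, `df`, `p_value`), and `kruskal_wallis` tibble
#'   (`statistic`, `df`, `p_value`).
#' @export
contour_length_stats <- function(molecules, welch = FALSE) {
  if (!all(c("contour_length_nm", "n_particles") %in% names(molecules))) {
    abort_rmquant("`molecules` needs columns contour_length_nm and n_particles",
                  "rmquant_parameter_error")
  }
  if (nrow(molecules) == 0) {
    abort_rmquant("no molecules supplied", "rmquant_parameter_error")
  }
  lv <- c("free", "1", "2", "3", ">3")
  df <- molecules |>
    dplyr::mutate(group = factor(dplyr::case_when(
      .data$n_particles == 0 ~ "free",
      .data$n_particles == 1 ~ "1",
      .data$n_particles == 2 ~ "2",
      .data$n_particles == 3 ~ "3",
      TRUE ~ ">3"
    ), levels = lv)) |>
    dplyr::filter(!is.na(.data$contour_length_nm))
  missing <- setdiff(lv, as.character(unique(df$group)))
  if (length(missing) > 0) {
    rlang::warn(paste("empty group(s) omitted:", paste(missing, collapse = ", ")))
  }
  df$group <- droplevels(df$group)
  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_nm = mean(.data$contour_length_nm),
                     sd_nm = stats::sd(.data$contour_length_nm),
                     .groups = "drop")
  present <- levels(df$group)
  pairwise <- list()
  if (length(present) >= 2) {
    combs <- utils::combn(present, 2)
    for (i in seq_len(ncol(combs))) {
      g1 <- df$contour_length_nm[df$group == combs[1, i]]
      g2 <- df$contour_length_nm[df$group == combs[2, i]]
      if (length(g1) < 2 || length(g2) < 2) next
      tt <- stats::t.test(g1, g2, var.equal = !welch)
      pairwise[[length(pairwise) + 1]] <- tibble::tibble(
        group1 = combs[1, i], group2 = combs[2, i],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
    }
  }
  pairwise <- if (length(pairwise) > 0) {
    dplyr::bind_rows(pairwise)
  } else {
    tibble::tibble(group1 = character(), group2 = character(),
                   t = numeric(), df = numeric(), p_value = numeric())
  }
  kw <- if (length(present) >= 2) {
    k <- stats::kruskal.test(contour_length_nm ~ group, data = df)
    tibble::tibble(statistic = unname(k$statistic),
                   df = unname(k$parameter), p_value = k$p.value)
  } else {
    tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  structure(list(groups = groups, pairwise = pairwise, kruskal_wallis = kw,
                 test = if (welch) "Welch" else "Student"),
            class = "contour_length_stats")
}

#' @export
print.contour_length_stats <- function(x, ...) {
  cat("Contour length by number of bound particles\n")
  print(x$groups)
  if (nrow(x$pairwise) > 0) {
    cat(sprintf("\nPairwise %s t-tests:\n", x$test))
    print(x$pairwise)
  }
  if (!is.na(x$kruskal_wallis$statistic[1])) {
    cat(sprintf("\nKruskal-Wallis: chi^2 = %.3g, df = %g, p = %.3g\n",
                x$kruskal_wallis$statistic, x$kruskal_wallis$df,
                x$kruskal_wallis$p_value))
  }
  invisible(x)
}
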