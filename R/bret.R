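# BRET signaling-signature statistics: uBRET standardisation,
# log(Emax/EC50) pathway summaries, relative efficacy versus a reference
# agonist with SEM propagation and pairwise tests, radar-plot export.

#' Universal BRET standardisation
#'
#' Maps raw BRET ratios onto a 0-10,000 scale anchored by the
#' negative-control (`a`) and positive-control (`b`) transfections:
#' `uBRET = (ratio - A) / (B - A) * 10,000`.
#'
#' @param bret_ratio Raw BRET ratio(s).
#' @param a_negative_control,b_positive_control Control BRET ratios; must
#'   differ.
#' @return Standardised uBRET units (vectorised over `bret_ratio`).
#' @examples
#' ubret(c(0.5, 1), a_negative_control = 0.5, b_positive_control = 1.5)
#' @export
ubret <- function(bret_ratio, a_negative_control, b_positive_control) {
  if (any(a_negative_control == b_positive_control)) {
    abort("Degenerate controls: negative and positive ratios are equal.")
  }
  (bret_ratio - a_negative_control) /
    (b_positive_control - a_negative_control) * 10000
}

#' Pathway activity ratio log10(Emax/EC50)
#'
#' The per-pathway agonist activity summary combining efficacy and
#' potency. Its absolute value depends on the units chosen for Emax and
#' EC50 (conventionally percent-of-reference and molar); the
#' between-compound difference used by [relative_efficacy()] is
#' unit-invariant.
#'
#' @param emax Maximal response (> 0), e.g. percent of reference.
#' @param ec50 Half-maximal concentration (> 0), e.g. molar.
#' @return `log10(emax / ec50)`, vectorised.
#' @export
log_r <- function(emax, ec50) {
  if (any(emax <= 0, na.rm = TRUE) || any(ec50 <= 0, na.rm = TRUE)) {
    abort("`emax` and `ec50` must be positive.")
  }
  log10(emax / ec50)
}

#' Standard error of a mean
#'
#' `sd / sqrt(n)`, the standard error of the mean of `n` independent
#' experiments.
#'
#' @param sd Standard deviation (>= 0).
#' @param n Number of experiments (>= 1).
#' @return The standard error, vectorised.
#' @export
sem_of_mean <- function(sd, n) {
  if (any(sd < 0, na.rm = TRUE)) abort("`sd` must be non-negative.")
  if (any(n < 1)) abort("`n` must be at least 1.")
  sd / sqrt(n)
}

#' Relative efficacy of compounds versus a reference agonist, per pathway
#'
#' For each compound and signaling pathway, computes the mean
#' `log10(Emax/EC50)` over independent experiments, its difference from
#' the reference compound on the same pathway
#' (`delta_log_r`), the propagated standard error
#' `sqrt(SEM_compound^2 + SEM_reference^2)`, the relative efficacy
#' `RE = 10^delta_log_r`, and a two-tailed unpaired t-test on the
#' per-experiment `log10(Emax/EC50)` values.
#'
#' @param data Tibble with columns `compound_id`, `pathway`,
#'   `experiment_id`, `emax`, `ec50` (one row per compound x pathway x
#'   experiment). Pathways with a flat/no-response fit should carry `NA`
#'   emax/ec50; their relative efficacy is reported as missing.
#' @param reference Compound id of the reference agonist (must be present
#'   in `data`).
#' @param var_equal Use the Student (equal-variance) t-test, the
#'   conventional two-tailed unpaired test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param p_adjust Multiplicity adjustment across pathways within each
#'   compound (`"none"` by default; e.g. `"holm"`).
#' @return Tibble with one row per compound x pathway: `compound_id`,
#'   `reference_id`, `pathway`, `n`, `delta_log_r`, `sem_delta`, `re`,
#'   `p_value`. The reference compared with itself gives
#'   `delta_log_r = 0`, `re = 1`.
#' @export
relative_efficacy <- function(data, reference, var_equal = TRUE,
                              p_adjust = "none") {
  check_columns(data, c("compound_id", "pathway", "experiment_id",
                        "emax", "ec50"), "relative_efficacy")
  if (!reference %in% data$compound_id) {
    abort(sprintf("Reference compound `%s` is absent from the data.",
                  reference))
  }
  logs <- as_tibble(data) |>
    mutate(log_r = ifelse(is.na(.data$emax) | is.na(.data$ec50),
                          NA_real_, log_r(.data$emax, .data$ec50)))
  summ <- logs |>
    filter(!is.na(.data$log_r)) |>
    group_by(.data$compound_id, .data$pathway) |>
    summarise(n = n(), mean_log_r = mean(.data$log_r),
              sd_log_r = sd(.data$log_r), .groups = "drop") |>
    mutate(sem = ifelse(.data$n > 1,
                        sem_of_mean(.data$sd_log_r, .data$n), NA_real_))
  ref <- summ |>
    filter(.data$compound_id == reference) |>
    select("pathway", ref_mean = "mean_log_r", ref_sem = "sem",
           ref_n = "n")
  per_exp <- logs |>
    filter(!is.na(.data$log_r)) |>
    group_by(.data$compound_id, .data$pathway) |>
    summarise(values = list(.data$log_r), .groups = "drop")
  ref_exp <- per_exp |>
    filter(.data$compound_id == reference) |>
    select("pathway", ref_values = "values")

  out <- summ |>
    left_join(ref, by = "pathway") |>
    left_join(per_exp, by = c("compound_id", "pathway")) |>
    left_join(ref_exp, by = "pathway") |>
    mutate(
      delta_log_r = .data$mean_log_r - .data$ref_mean,
      sem_delta = sqrt(.data$sem^2 + .data$ref_sem^2),
      re = 10^.data$delta_log_r,
      p_value = map2_dbl(.data$values, .data$ref_values, function(x, y) {
        if (is.null(x) || is.null(y) || length(x) < 2 || length(y) < 2) {
          return(NA_real_)
        }
        if (sd(c(x, y)) == 0) return(1)
        t.test(x, y, var.equal = var_equal)$p.value
      })
    ) |>
    mutate(reference_id = reference) |>
    select("compound_id", "reference_id", "pathway", "n",
           "delta_log_r", "sem_delta", "re", "p_value")
  if (!identical(p_adjust, "none")) {
    out <- out |>
      group_by(.data$compound_id) |>
      mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust)) |>
      ungroup()
  }
  out
}

#' Radar-plot table of relative efficacies
#'
#' Wide-format compound x pathway table of relative efficacies, with the
#' reference compound's row of 1s included, ready for radar plotting.
#'
#' @param re_data Output of [relative_efficacy()] (one row per compound x
#'   pathway; duplicates are an error).
#' @return Wide tibble: `compound_id` plus one column per pathway.
#' @export
radar_table <- function(re_data) {
  check_columns(re_data, c("compound_id", "pathway", "re"), "radar_table")
  if (anyDuplicated(re_data[, c("compound_id", "pathway")])) {
    abort("Duplicate compound x pathway entries in `re_data`.")
  }
  wide <- re_data |>
    select("compound_id", "pathway", "re") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "re")
  ref_id <- unique(re_data$reference_id %||% character(0))
  if (length(ref_id) == 1 && !ref_id %in% wide$compound_id) {
    ref_row <- wide[1, ]
    ref_row$compound_id <- ref_id
    ref_row[, -1] <- 1
    wide <- bind_rows(ref_row, wide)
  }
  wide
}

#' Radar plot of per-pathway relative efficacies
#'
#' @param re_data Output of [relative_efficacy()].
#' @return A ggplot: one polygon per compound over pathways (polar
#'   coordinates), relative efficacy 1 = reference-like.
#' @export
plot_radar <- function(re_data) {
  check_columns(re_data, c("compound_id", "pathway", "re"), "plot_radar")
  ggplot2::ggplot(re_data,
                  ggplot2::aes(x = .data$pathway, y = .data$re,
                               group = .data$compound_id,
                               colour = .data$compound_id)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "relative efficacy (RE)",
                  colour = "compound")
}
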