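# Behavioral summary metrics: therapeutic windows, conditioned place
# preference scores, and fold <-> binding free-energy conversion.

#' Therapeutic window between analgesia and a side effect
#'
#' The therapeutic index is the ratio of the minimum dose producing the
#' side-effect phenotype to the minimum dose producing the analgesic
#' phenotype. When no tested side-effect dose was significant, the
#' highest tested side-effect dose is used instead and the window is
#' flagged as a lower bound. Significance flags are inputs from the
#' caller's statistics (the underlying ANOVAs are not recomputed here).
#'
#' @param data Tibble with columns `endpoint`, `dose` (mg/kg, > 0) and
#'   `significant` (logical or 0/1), one row per tested dose per
#'   endpoint.
#' @param analgesia,side_effect Endpoint labels in `data`.
#' @return One-row tibble: `analgesia_onset_dose`, `side_effect_onset_dose`
#'   (`NA` when no side-effect dose was significant), `window_fold`,
#'   `lower_bound_only`.
#' @examples
#' doses <- tibble::tibble(
#'   endpoint = rep(c("tail_flick", "catalepsy"), each = 3),
#'   dose = rep(c(0.1, 0.5, 1), 2),
#'   significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
#' )
#' therapeutic_window(doses, "tail_flick", "catalepsy") # >= 10-fold
#' @export
therapeutic_window <- function(data, analgesia, side_effect) {
  check_columns(data, c("endpoint", "dose", "significant"),
                "therapeutic_window")
  if (any(data$dose <= 0)) abort("Doses must be positive.")
  pick <- function(label) {
    rows <- data[data$endpoint == label, , drop = FALSE]
    if (!nrow(rows)) {
      abort(sprintf("Endpoint `%s` is absent from `data`.", label))
    }
    if (anyDuplicated(rows$dose)) {
      abort(sprintf("Duplicate doses for endpoint `%s`.", label))
    }
    rows
  }
  an <- pick(analgesia)
  se <- pick(side_effect)
  an_sig <- an$dose[as.logical(an$significant)]
  if (!length(an_sig)) {
    abort("No significant analgesic dose; the window is undefined.")
  }
  onset_an <- min(an_sig)
  se_sig <- se$dose[as.logical(se$significant)]
  if (length(se_sig)) {
    onset_se <- min(se_sig)
    lower_bound <- FALSE
  } else {
    onset_se <- NA_real_
    lower_bound <- TRUE
  }
  numerator <- if (lower_bound) max(se$dose) else onset_se
  tibble(
    analgesia_onset_dose = onset_an,
    side_effect_onset_dose = onset_se,
    window_fold = numerator / onset_an,
    lower_bound_only = lower_bound
  )
}

#' Conditioned place preference scores
#'
#' Per-chamber time difference between the test and pretest sessions
#' (`CPP score = Test - Pretest`); a positive score for the drug-paired
#' chamber indicates preference (reward), a negative one aversion.
#'
#' @param data Tibble with columns `chamber`, `session` (values
#'   `"pretest"` and `"test"`) and `seconds`; each chamber must appear in
#'   both sessions.
#' @return Tibble with `chamber`, `pretest_s`, `test_s`, `score_s`.
#' @export
cpp_score <- function(data) {
  check_columns(data, c("chamber", "session", "seconds"), "cpp_score")
  if (!all(data$session %in% c("pretest", "test"))) {
    abort('`session` must contain only "pretest" and "test".')
  }
  wide <- as_tibble(data) |>
    tidyr::pivot_wider(names_from = "session", values_from = "seconds")
  if (!all(c("pretest", "test") %in% names(wide)) ||
      anyNA(wide$pretest) || anyNA(wide$test)) {
    abort("Chamber labels must match between pretest and test sessions.")
  }
  wide |>
    mutate(score_s = .data$test - .data$pretest) |>
    select("chamber", pretest_s = "pretest", test_s = "test", "score_s")
}

GAS_CONSTANT_KCAL <- 1.987e-3 # kcal mol^-1 K^-1

#' Convert an affinity fold change to a binding free-energy difference
#'
#' `ddG = -R T ln(fold)` with R = 1.987e-3 kcal/(mol K): an affinity gain
#' (fold > 1) gives a negative (favourable) free-energy change.
#'
#' @param fold Affinity ratio `Ki_parent / Ki_analog` (> 0), vectorised.
#' @param temperature_k Absolute temperature (default 298.15 K).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' fold_to_ddg(17) # about -1.7 kcal/mol
#' @export
fold_to_ddg <- function(fold, temperature_k = 298.15) {
  if (any(fold <= 0)) abort("`fold` must be positive.")
  check_number(temperature_k, "temperature_k", lower = 0,
               allow_zero = FALSE)
  -GAS_CONSTANT_KCAL * temperature_k * log(fold)
}

#' @rdname fold_to_ddg
#' @param ddg Free-energy difference in kcal/mol.
#' @export
ddg_to_fold <- function(ddg, temperature_k = 298.15) {
  check_number(temperature_k, "temperature_k", lower = 0,
               allow_zero = FALSE)
  exp(-ddg / (GAS_CONSTANT_KCAL * temperature_k))
}
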