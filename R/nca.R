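# Noncompartmental pharmacokinetic analysis with below-quantitation
# handling.

#' Noncompartmental analysis of a concentration-time profile
#'
#' Model-free PK summary: Cmax/Tmax from the maximum quantifiable
#' observation; terminal slope lambda_z from a log-linear regression on
#' terminal quantifiable points (window chosen by best adjusted R-squared
#' over candidate windows of at least 3 points after Tmax, overridable);
#' AUC to the last quantifiable point by the linear trapezoid rule; and
#' extrapolation to infinity as `AUC_inf = AUC_last + C_last / lambda_z`.
#'
#' Below-quantitation handling follows the standard bioanalytical rules:
#' values below the LLOQ before the first quantifiable point are set to
#' zero for the concentration summaries, and all below-LLOQ values are
#' treated as missing for the terminal-slope fit.
#'
#' @param data Tibble with `time` (minutes, strictly increasing) and
#'   `conc` columns; an optional `below_limit` logical column or the
#'   `lloq` argument flags unquantifiable points.
#' @param model `"extravascular"` (default; a (0, 0) anchor is prepended
#'   when no time-zero sample exists) or `"bolus"` (C0 back-extrapolated
#'   log-linearly from the first two quantifiable points).
#' @param lloq Lower limit of quantitation in concentration units
#'   (default 0: every positive observation quantifiable). Ignored when
#'   `data` carries a `below_limit` column.
#' @param lambda_z_points Optional fixed number of terminal points for the
#'   lambda_z fit, overriding the adjusted-R-squared rule.
#' @return A one-row `nca_result` tibble: `cmax`, `tmax`, `lambda_z`,
#'   `t_half`, `auc_last`, `auc_inf`, `n_lambda_points`,
#'   `extrapolated_fraction`, `lambda_z_diagnostic`.
#' @examples
#' prof <- sim_pk_profile(seed = 1)
#' nca(prof)
#' @export
nca <- function(data, model = c("extravascular", "bolus"), lloq = 0,
                lambda_z_points = NULL) {
  model <- match.arg(model)
  check_columns(data, c("time", "conc"), "nca")
  check_number(lloq, "lloq", lower = 0)
  t <- as.numeric(data$time)
  c_ <- as.numeric(data$conc)
  if (any(diff(t) <= 0)) abort("`time` must be strictly increasing.")
  blq <- if ("below_limit" %in% names(data)) {
    as.logical(data$below_limit)
  } else {
    c_ < lloq
  }

  quant <- which(!blq)
  if (length(quant) < 3) {
    abort("Fewer than 3 quantifiable points; NCA is not estimable.")
  }
  first_q <- quant[1]
  last_q <- quant[length(quant)]

  # concentration series for AUC: pre-first-quantifiable BLQ -> 0,
  # interior/trailing BLQ -> dropped as missing
  keep <- quant
  lead_zero <- setdiff(seq_len(first_q - 1), quant)
  auc_t <- c(t[lead_zero], t[keep])
  auc_c <- c(rep(0, length(lead_zero)), c_[keep])
  ord <- order(auc_t)
  auc_t <- auc_t[ord]
  auc_c <- auc_c[ord]

  if (model == "extravascular") {
    if (auc_t[1] > 0) {
      auc_t <- c(0, auc_t)
      auc_c <- c(0, auc_c)
    }
  } else if (auc_t[1] > 0) {
    # bolus: back-extrapolate C0 from the first two quantifiable points
    t12 <- t[quant[1:2]]
    c12 <- c_[quant[1:2]]
    c0 <- if (all(c12 > 0) && c12[2] < c12[1]) {
      exp(log(c12[1]) - t12[1] * (log(c12[2]) - log(c12[1])) /
            (t12[2] - t12[1]))
    } else {
      c12[1]
    }
    auc_t <- c(0, auc_t)
    auc_c <- c(c0, auc_c)
  }

  cmax_i <- which.max(c_[quant])
  cmax <- c_[quant][cmax_i]
  tmax <- t[quant][cmax_i]

  auc_last <- sum(diff(auc_t) * (head(auc_c, -1) + auc_c[-1]) / 2)

  # terminal slope on quantifiable points strictly after Tmax
  term_i <- quant[t[quant] > tmax & c_[quant] > 0]
  lambda_z <- NA_real_
  n_pts <- 0L
  diagnostic <- NA_character_
  if (length(term_i) < 3) {
    diagnostic <- "fewer than 3 quantifiable points after Tmax"
  } else {
    cand <- if (!is.null(lambda_z_points)) {
      k <- check_count(lambda_z_points, "lambda_z_points", min = 3L)
      if (k > length(term_i)) {
        abort("`lambda_z_points` exceeds the available terminal points.")
      }
      k
    } else {
      3:length(term_i)
    }
    best <- NULL
    for (k in cand) {
      idx <- utils::tail(term_i, k)
      fit <- lm(log(c_[idx]) ~ t[idx])
      # noise-free profiles fit exactly; the perfect-fit warning from
      # summary.lm is expected there
      r2 <- suppressWarnings(summary(fit)$adj.r.squared)
      if (is.null(best) || isTRUE(r2 > best$r2 + 1e-12)) {
        best <- list(r2 = r2, slope = unname(coef(fit)[2]), k = k)
      }
    }
    if (best$slope < 0) {
      lambda_z <- -best$slope
      n_pts <- best$k
    } else {
      diagnostic <- "non-negative terminal slope; half-life undefined"
    }
  }

  t_half <- if (is.finite(lambda_z)) log(2) / lambda_z else NA_real_
  c_last <- c_[last_q]
  auc_inf <- if (is.finite(lambda_z)) auc_last + c_last / lambda_z else
    NA_real_
  out <- tibble(
    cmax = cmax, tmax = tmax, lambda_z = lambda_z, t_half = t_half,
    auc_last = auc_last, auc_inf = auc_inf,
    n_lambda_points = n_pts,
    extrapolated_fraction = if (is.finite(auc_inf)) {
      (auc_inf - auc_last) / auc_inf
    } else {
      NA_real_
    },
    lambda_z_diagnostic = diagnostic
  )
  class(out) <- c("nca_result", class(out))
  attr(out, "model") <- model
  out
}

#' Convert mass concentration to molar concentration
#'
#' ng/mL to nM given the compound's molecular weight; mass-per-volume PK
#' readouts require a caller-supplied MW because it cannot be inferred
#' from the profile.
#'
#' @param ng_per_ml Concentration in ng/mL.
#' @param mw Molecular weight in g/mol.
#' @return Concentration in nmol/L (nM).
#' @export
ng_ml_to_nm <- function(ng_per_ml, mw) {
  check_number(mw, "mw", lower = 0, allow_zero = FALSE)
  ng_per_ml / mw * 1000
}
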