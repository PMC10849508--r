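# In vitro pharmacology: four-parameter logistic fitting, reference
# normalisation, Cheng-Prusoff conversion, percent activity, fold change.

#' Four-parameter logistic response at given concentrations
#'
#' `y = bottom + (top - bottom) / (1 + 10^((-pec50 - log10(c)) * hill))`:
#' the standard Prism-style 4PL on log10 concentration. With `hill > 0`
#' the curve rises with concentration and crosses its midpoint at
#' `c = 10^-pec50`.
#'
#' @param concentration Molar concentrations (> 0).
#' @param bottom,top Lower/upper plateaus.
#' @param pec50 -log10 molar EC50.
#' @param hill Hill slope.
#' @return Model responses.
#' @export
predict_4pl <- function(concentration, bottom, top, pec50, hill) {
  if (any(concentration <= 0)) {
    abort("Concentrations must be positive (molar).")
  }
  x <- log10(concentration)
  bottom + (top - bottom) / (1 + 10^((-pec50 - x) * hill))
}

#' Fit a four-parameter logistic concentration-response model
#'
#' Unweighted least-squares fit of the 4PL (bottom, top, pEC50, Hill) to
#' replicate-level responses on log10 concentration, via
#' Levenberg-Marquardt. Reports asymptotic (Wald) standard errors and 95%
#' confidence intervals. Flat curves (no concentration dependence) and
#' optimizer failures are reported as non-converged fits with a
#' diagnostic, not errors.
#'
#' @param data Tibble with `concentration` (molar, > 0) and `response`
#'   columns; replicate rows are fit as independent points.
#' @param bounds Optional named list with `lower` and/or `upper` numeric
#'   vectors of length 4 (order: bottom, top, pec50, hill).
#' @return A `fit_4pl` object; see [tidy()], [glance()], [autoplot()].
#' @examples
#' curve <- sim_dose_response(noise_sd = 0, seed = 1)
#' fit <- fit_4pl(curve)
#' glance(fit)
#' @export
fit_4pl <- function(data, bounds = NULL) {
  check_columns(data, c("concentration", "response"), "fit_4pl")
  conc <- data$concentration
  y <- data$response
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("Concentrations must be positive and finite (molar).")
  }
  if (length(unique(conc)) < 4) {
    abort("At least 4 distinct concentrations are needed to fit a 4PL.")
  }
  x <- log10(conc)
  n <- length(y)

  failed <- function(reason) {
    structure(
      list(estimates = tibble(term = c("bottom", "top", "pec50", "hill"),
                              estimate = NA_real_, std.error = NA_real_,
                              conf.low = NA_real_, conf.high = NA_real_),
           converged = FALSE, diagnostic = reason,
           residual_sd = NA_real_, n = n, data = as_tibble(data)),
      class = "fit_4pl"
    )
  }

  mean_by_conc <- tapply(y, x, mean)
  if (diff(range(y)) == 0 ||
      diff(range(mean_by_conc)) < 1e-9 * max(1, abs(median(y)))) {
    return(failed("flat curve: response shows no concentration dependence"))
  }

  # starting values: plateaus from response extremes, pEC50 from the
  # half-maximal crossing of the concentration means, Hill slope 1 with
  # the sign of the observed trend
  xs <- sort(unique(x))
  ms <- as.numeric(mean_by_conc[as.character(xs)])
  rising <- unname(coef(lm(ms ~ xs))[2]) >= 0
  half <- (min(ms) + max(ms)) / 2
  cross <- tryCatch(approx(ms, xs, xout = half, ties = mean)$y,
                    error = function(e) NA_real_)
  if (!is.finite(cross)) cross <- median(xs)
  start <- list(bottom = if (rising) min(ms) else max(ms),
                top = if (rising) max(ms) else min(ms),
                pec50 = -cross,
                hill = if (rising) 1 else -1)

  lower <- c(-Inf, -Inf, -Inf, -Inf)
  upper <- c(Inf, Inf, Inf, Inf)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower <- bounds$lower
    if (!is.null(bounds$upper)) upper <- bounds$upper
  }

  # primary heuristic start, then fallback starts if the optimizer
  # cannot take a step from it (e.g. singular gradient)
  hill_sign <- if (rising) 1 else -1
  starts <- c(
    list(start),
    lapply(stats::quantile(-xs, c(0.25, 0.5, 0.75), names = FALSE),
           function(p) {
             list(bottom = start$bottom, top = start$top, pec50 = p,
                  hill = hill_sign)
           }),
    lapply(c(0.5, 2), function(h) {
      list(bottom = start$bottom, top = start$top, pec50 = start$pec50,
           hill = hill_sign * h)
    })
  )
  fit <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((-pec50 - x) * hill)),
        data = data.frame(x = x, y = y),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        last_err <<- e
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(failed(paste("optimizer failure:", conditionMessage(last_err))))
  }

  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 4) else sqrt(pmax(diag(vc), 0))
  if (abs(est["top"] - est["bottom"]) <
      1e-6 * max(1, abs(est["top"]), abs(est["bottom"]))) {
    return(failed("flat curve: fitted span is zero"))
  }
  tcrit <- qt(0.975, df = max(n - 4, 1))
  structure(
    list(
      estimates = tibble(
        term = names(est),
        estimate = unname(est),
        std.error = unname(se),
        conf.low = unname(est - tcrit * se),
        conf.high = unname(est + tcrit * se)
      ),
      converged = TRUE, diagnostic = NA_character_,
      residual_sd = sqrt(sum(stats::resid(fit)^2) / max(n - 4, 1)),
      n = n, data = as_tibble(data)
    ),
    class = "fit_4pl"
  )
}

fit_4pl_param <- function(fit, term) {
  fit$estimates$estimate[match(term, fit$estimates$term)]
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("<4PL concentration-response fit>\n")
  if (x$converged) {
    print(x$estimates)
    cat(sprintf("EC50: %.3g M, residual SD %.3g, n = %d\n",
                10^(-fit_4pl_param(x, "pec50")), x$residual_sd, x$n))
  } else {
    cat("not converged:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' @rdname fit_4pl
#' @param x,object A `fit_4pl` object.
#' @param ... Unused.
#' @export
tidy.fit_4pl <- function(x, ...) {
  x$estimates
}

#' @rdname fit_4pl
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(
    converged = x$converged,
    diagnostic = x$diagnostic,
    bottom = fit_4pl_param(x, "bottom"),
    top = fit_4pl_param(x, "top"),
    pec50 = fit_4pl_param(x, "pec50"),
    hill = fit_4pl_param(x, "hill"),
    ec50 = 10^(-fit_4pl_param(x, "pec50")),
    residual_sd = x$residual_sd,
    n = x$n
  )
}

#' @rdname fit_4pl
#' @export
autoplot.fit_4pl <- function(object, ...) {
  pdata <- object$data
  gg <- ggplot2::ggplot(pdata,
                        ggplot2::aes(x = log10(.data$concentration),
                                     y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log10 concentration (M)", y = "response")
  if (object$converged) {
    grid <- tibble(concentration = 10^seq(log10(min(pdata$concentration)),
                                          log10(max(pdata$concentration)),
                                          length.out = 200))
    grid$response <- predict_4pl(grid$concentration,
                                 fit_4pl_param(object, "bottom"),
                                 fit_4pl_param(object, "top"),
                                 fit_4pl_param(object, "pec50"),
                                 fit_4pl_param(object, "hill"))
    gg <- gg + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  gg
}

#' Normalise responses to a reference compound's fitted span
#'
#' Rescales raw responses so the reference fit's bottom maps to 0% and its
#' top to 100% (normalisation to the best-fit values of the reference
#' agonist from the same experiment). If the reference fit did not
#' converge or is flat, the data pass through unchanged and the result is
#' flagged (`attr(, "normalized") = FALSE`), mirroring the rule that data
#' are left unnormalised when the reference shows no response.
#'
#' @param data Tibble with a `response` column.
#' @param reference_fit A converged [fit_4pl()] of the reference compound.
#' @return `data` with `response` rescaled to percent-of-reference (or
#'   passed through), with attribute `normalized`.
#' @export
normalize_to_reference <- function(data, reference_fit) {
  check_columns(data, "response", "normalize_to_reference")
  if (!inherits(reference_fit, "fit_4pl")) {
    abort("`reference_fit` must be a `fit_4pl` object.")
  }
  bottom <- fit_4pl_param(reference_fit, "bottom")
  top <- fit_4pl_param(reference_fit, "top")
  if (!isTRUE(reference_fit$converged) || !is.finite(top - bottom) ||
      abs(top - bottom) < 1e-9 * max(1, abs(top), abs(bottom))) {
    out <- as_tibble(data)
    attr(out, "normalized") <- FALSE
    return(out)
  }
  out <- as_tibble(data) |>
    mutate(response = 100 * (.data$response - bottom) / (top - bottom))
  attr(out, "normalized") <- TRUE
  out
}

#' Cheng-Prusoff conversion of competition IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for a competition binding experiment with
#' radioligand concentration `L` and radioligand affinity `Kd`.
#'
#' @param ic50 Competition IC50 (molar, > 0); vectorised.
#' @param radioligand_conc Radioligand concentration `L` (molar, >= 0).
#' @param radioligand_kd Radioligand dissociation constant `Kd`
#'   (molar, > 0).
#' @return Ki in the same units as `ic50`.
#' @examples
#' cheng_prusoff(3e-9, radioligand_conc = 1e-9, radioligand_kd = 0.5e-9)
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  if (any(ic50 <= 0)) abort("`ic50` must be positive.")
  if (any(radioligand_conc < 0)) {
    abort("`radioligand_conc` must be non-negative.")
  }
  if (any(radioligand_kd <= 0)) {
    abort("`radioligand_kd` must be positive.")
  }
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Percent activity relative to a reference compound's span
#'
#' `100 * (test - vehicle) / (reference_max - reference_baseline)`: the
#' plate-reader percent-activity equation, with the denominator read as
#' the reference compound's maximal signal minus its baseline (the
#' reading under which the reference itself scores 100%). The denominator
#' interpretation is recorded as an attribute.
#'
#' @param mean_rlu_test,mean_rlu_vehicle Mean signal of the test compound
#'   and of vehicle.
#' @param mean_rlu_ref_max,mean_rlu_ref_baseline Mean maximal and baseline
#'   signal of the reference compound.
#' @return Percent activity (vectorised over `mean_rlu_test`).
#' @export
percent_activity <- function(mean_rlu_test, mean_rlu_vehicle,
                             mean_rlu_ref_max, mean_rlu_ref_baseline) {
  denom <- mean_rlu_ref_max - mean_rlu_ref_baseline
  if (any(denom == 0)) {
    abort("Reference span is zero; percent activity is undefined.")
  }
  out <- 100 * (mean_rlu_test - mean_rlu_vehicle) / denom
  attr(out, "denominator") <- "reference_max - reference_baseline"
  out
}

#' Affinity fold change between a parent compound and an analog
#'
#' @param ki_parent,ki_analog Affinities in the same units (> 0).
#' @return One-row tibble with the exact `fold` (`ki_parent / ki_analog`)
#'   and `fold_reported` rounded to the nearest integer.
#' @examples
#' fold_change(700e-9, 44e-9) # the 16-fold optimisation step
#' @export
fold_change <- function(ki_parent, ki_analog) {
  if (any(c(ki_parent, ki_analog) <= 0)) {
    abort("Affinities must be positive.")
  }
  fold <- ki_parent / ki_analog
  tibble(fold = fold, fold_reported = round(fold))
}
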