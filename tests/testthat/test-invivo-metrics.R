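# Noncompartmental PK and behavioral summary metrics.

test_that("NCA summarises a toy profile by direct lookup", {
  prof <- tibble::tibble(time = c(0, 60, 120), conc = c(0, 10, 5))
  res <- nca(prof)
  expect_equal(res$cmax, 10)
  expect_equal(res$tmax, 60)
  # too few terminal points for a slope: half-life undefined with reason
  expect_true(is.na(res$t_half))
  expect_match(res$lambda_z_diagnostic, "fewer than 3")
})

test_that("NCA recovers closed-form monoexponential kinetics within 1%", {
  ke <- 0.00693 # half-life 100 min
  tt <- seq(0, 600, by = 20)
  prof <- tibble::tibble(time = tt, conc = 100 * exp(-ke * tt))
  res <- nca(prof, model = "bolus")
  expect_equal(res$t_half, log(2) / ke, tolerance = 0.01)
  expect_equal(res$auc_inf, 100 / ke, tolerance = 0.01)
  expect_gte(res$auc_inf, res$auc_last)
  expect_equal(res$extrapolated_fraction,
               (res$auc_inf - res$auc_last) / res$auc_inf)
})

test_that("AUC is invariant under insertion of collinear points", {
  prof <- tibble::tibble(time = c(0, 60, 120, 240),
                         conc = c(0, 12, 8, 2))
  base <- nca(prof)
  # insert midpoints lying exactly on the connecting segments
  dense <- tibble::tibble(
    time = c(0, 30, 60, 90, 120, 180, 240),
    conc = c(0, 6, 12, 10, 8, 5, 2)
  )
  expect_equal(nca(dense)$auc_last, base$auc_last, tolerance = 1e-12)
})

test_that("below-quantitation rules follow the stated substitutions", {
  # leading BLQ points count as zero; trailing BLQ points are dropped
  prof <- tibble::tibble(
    time = c(5, 15, 30, 60, 120, 240, 480),
    conc = c(0.5, 4, 10, 8, 4, 2, 0.4)
  )
  res <- nca(prof, lloq = 1)
  expect_equal(res$cmax, 10)
  # AUC with the leading point zeroed, trapezoids over the quantifiable span
  manual_t <- c(0, 5, 15, 30, 60, 120, 240)
  manual_c <- c(0, 0, 4, 10, 8, 4, 2)
  manual_auc <- sum(diff(manual_t) * (head(manual_c, -1) + manual_c[-1]) / 2)
  expect_equal(res$auc_last, manual_auc, tolerance = 1e-12)

  # all points below the limit: not estimable
  expect_error(nca(prof, lloq = 100), "quantifiable")
})

test_that("therapeutic windows reproduce the printed dose ratios", {
  mk <- function(analgesia_doses, analgesia_sig, side_doses, side_sig) {
    dplyr::bind_rows(
      tibble::tibble(endpoint = "analgesia", dose = analgesia_doses,
                     significant = analgesia_sig),
      tibble::tibble(endpoint = "side", dose = side_doses,
                     significant = side_sig)
    )
  }
  # heat analgesia at 0.1 vs catalepsy never significant up to 1: >= 10-fold
  tw1 <- therapeutic_window(
    mk(c(0.05, 0.1, 0.5, 1), c(FALSE, TRUE, TRUE, TRUE),
       c(0.1, 0.5, 1), c(FALSE, FALSE, FALSE)),
    "analgesia", "side")
  expect_equal(tw1$window_fold, 10)
  expect_true(tw1$lower_bound_only)

  # rotarod deficit at 0.5 vs analgesia at 0.1: five-fold
  tw2 <- therapeutic_window(
    mk(c(0.1, 0.5, 1), c(TRUE, TRUE, TRUE),
       c(0.1, 0.5, 1), c(FALSE, TRUE, TRUE)),
    "analgesia", "side")
  expect_equal(tw2$window_fold, 5)
  expect_false(tw2$lower_bound_only)

  # cold anti-allodynia at 0.05 vs catalepsy-like onset at 1: twenty-fold
  tw3 <- therapeutic_window(
    mk(c(0.05, 0.1, 1), c(TRUE, TRUE, TRUE),
       c(0.1, 0.5, 1), c(FALSE, FALSE, TRUE)),
    "analgesia", "side")
  expect_equal(tw3$window_fold, 20)

  # equal onsets: unit window
  tw4 <- therapeutic_window(
    mk(c(0.1, 0.5), c(TRUE, TRUE), c(0.1, 0.5), c(TRUE, TRUE)),
    "analgesia", "side")
  expect_equal(tw4$window_fold, 1)

  expect_error(
    therapeutic_window(mk(c(0.1), FALSE, c(0.1), TRUE),
                       "analgesia", "side"),
    "No significant analgesic dose")
})

test_that("therapeutic windows are scale-invariant in dose units", {
  d <- dplyr::bind_rows(
    tibble::tibble(endpoint = "analgesia", dose = c(0.1, 0.5, 1),
                   significant = c(TRUE, TRUE, TRUE)),
    tibble::tibble(endpoint = "side", dose = c(0.1, 0.5, 1),
                   significant = c(FALSE, TRUE, TRUE))
  )
  d10 <- dplyr::mutate(d, dose = dose * 10)
  expect_equal(therapeutic_window(d, "analgesia", "side")$window_fold,
               therapeutic_window(d10, "analgesia", "side")$window_fold)
})

test_that("CPP scores are per-chamber test-minus-pretest differences", {
  d <- tibble::tibble(
    chamber = rep(c("drug", "vehicle", "neutral"), 2),
    session = rep(c("pretest", "test"), each = 3),
    seconds = c(700, 800, 300, 900, 650, 250)
  )
  sc <- cpp_score(d)
  expect_equal(sc$score_s[sc$chamber == "drug"], 200)
  # identical sessions score zero everywhere
  same <- d
  same$seconds[same$session == "test"] <- same$seconds[same$session ==
                                                         "pretest"]
  expect_true(all(cpp_score(same)$score_s == 0))
  # chamber scores sum to the total time difference
  expect_equal(sum(sc$score_s),
               sum(d$seconds[d$session == "test"]) -
                 sum(d$seconds[d$session == "pretest"]))
  # mismatched chamber labels are an error
  bad <- d[-1, ]
  expect_error(cpp_score(bad), "match")
})

test_that("fold-to-free-energy conversion matches -RT ln(fold)", {
  expect_equal(fold_to_ddg(1), 0)
  # the 17-fold affinity gain corresponds to about -1.7 kcal/mol
  expect_equal(signif(fold_to_ddg(17), 2), -1.7)
  expect_equal(fold_to_ddg(10), -1.36, tolerance = 0.005)
  # inverse identity and additivity over multiplied folds
  expect_equal(ddg_to_fold(fold_to_ddg(23.7)), 23.7, tolerance = 1e-9)
  expect_equal(fold_to_ddg(4 * 5), fold_to_ddg(4) + fold_to_ddg(5),
               tolerance = 1e-12)
  expect_error(fold_to_ddg(0), "positive")
})

test_that("mass-to-molar conversion uses the supplied molecular weight", {
  # a 5.14 ng/mL plasma level reads as about 12 nM near MW 428
  expect_equal(ng_ml_to_nm(5.14, 428), 12.0, tolerance = 0.01)
})
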