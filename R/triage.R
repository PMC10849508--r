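# Post-docking hit triage: property windows, leader clustering, novelty
# rejection, analog retrieval and campaign bookkeeping.
#
# A library is a tibble of ligand records with columns `id`, `smiles`,
# `mw` (amu), `clogp`, `score` (docking-energy units, lower is better)
# and `rank`. All Tanimoto thresholds are applied with the package's own
# circular fingerprinter (see `fingerprint()`).

#' Filter a ligand library on physical-property windows
#'
#' Keeps records whose molecular weight and calculated logP fall inside
#' closed intervals, the "lead-like but lipophilic" window used to select
#' the docking library (350-500 amu, cLogP 3-5). Boundary values are kept.
#'
#' @param data Ligand tibble with `mw` and `clogp` columns.
#' @param mw_range,clogp_range Length-2 numeric `c(low, high)` closed
#'   intervals; defaults are the campaign windows.
#' @return The filtered tibble, input order preserved.
#' @examples
#' lib <- tibble::tibble(id = c("a", "b"), mw = c(350, 349.9),
#'                       clogp = c(3, 4))
#' property_filter(lib)
#' @export
property_filter <- function(data, mw_range = c(350, 500),
                            clogp_range = c(3, 5)) {
  check_columns(data, c("mw", "clogp"), "property_filter")
  stopifnot(length(mw_range) == 2, length(clogp_range) == 2,
            all(is.finite(c(mw_range, clogp_range))),
            mw_range[1] <= mw_range[2], clogp_range[1] <= clogp_range[2])
  as_tibble(data) |>
    filter(.data$mw >= mw_range[1], .data$mw <= mw_range[2],
           .data$clogp >= clogp_range[1], .data$clogp <= clogp_range[2])
}

# Fingerprints for a library tibble: named list keyed by id.
library_fingerprints <- function(data, radius = 2, n_bits = 2048) {
  check_columns(data, c("id", "smiles"), "library_fingerprints")
  smis <- setNames(data$smiles, data$id)
  fps <- fingerprint(smis, radius = radius, n_bits = n_bits)
  if (inherits(fps, "dockpharm_fp")) fps <- setNames(list(fps), data$id)
  fps
}

#' Greedy leader clustering of a score-ranked library
#'
#' Single-pass leader clustering in score order (best first): each record
#' joins the first existing cluster whose leader it matches at Tanimoto
#' `>= tc_threshold`, otherwise it founds a new cluster. Leaders are
#' therefore always the best-scoring member of their cluster, mirroring
#' "best-scoring member as cluster representative" triage of ranked
#' docking output.
#'
#' @param data Ligand tibble with `id`, `smiles`, `score` columns. Rows
#'   are processed in ascending `score` order (ties broken by ascending
#'   id); a pre-sorted tibble is processed as given.
#' @param tc_threshold Tanimoto threshold for joining a cluster
#'   (default 0.5).
#' @param fps Optional named list of fingerprints keyed by `id`
#'   (computed from `smiles` when omitted).
#' @return Input tibble with `cluster` (leader id) and `is_representative`
#'   columns added, sorted in processing order.
#' @export
leader_cluster <- function(data, tc_threshold = 0.5, fps = NULL) {
  check_columns(data, c("id", "smiles", "score"), "leader_cluster")
  check_number(tc_threshold, "tc_threshold", lower = 0, upper = 1)
  if (anyDuplicated(data$id)) {
    abort("`id` must be unique within a library.")
  }
  data <- as_tibble(data) |> arrange(.data$score, .data$id)
  if (is.null(fps)) {
    fps <- library_fingerprints(data)
  }
  missing <- setdiff(data$id, names(fps))
  if (length(missing)) {
    abort(sprintf("Missing fingerprint for id%s: %s",
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(data)
  leader_of <- character(n)
  leaders <- character(0)
  for (i in seq_len(n)) {
    id_i <- data$id[i]
    assigned <- NA_character_
    for (l in leaders) {
      if (tanimoto(fps[[id_i]], fps[[l]]) >= tc_threshold) {
        assigned <- l
        break
      }
    }
    if (is.na(assigned)) {
      leaders <- c(leaders, id_i)
      assigned <- id_i
    }
    leader_of[i] <- assigned
  }
  data |>
    mutate(cluster = leader_of,
           is_representative = .data$id == .data$cluster)
}

#' Novelty filter against a reference ligand set
#'
#' For each candidate, the maximum Tanimoto similarity to a set of known
#' reference ligands is computed; candidates at or above the rejection
#' threshold are flagged as not novel. The rejection side is inclusive:
#' a candidate with maximum Tc exactly at the threshold is rejected,
#' matching the campaign rule that molecules with Tc >= 0.38 to known
#' ligands were not pursued.
#'
#' @param data Candidate tibble with `id` and `smiles` columns.
#' @param reference_smiles Character vector of reference-ligand SMILES.
#'   An empty reference set keeps every candidate with `max_tc = 0`.
#' @param tc_threshold Rejection threshold (default 0.38).
#' @return Tibble with one row per candidate: `id`, `max_tc`,
#'   `nearest_reference`, `kept`.
#' @export
novelty_filter <- function(data, reference_smiles, tc_threshold = 0.38) {
  check_columns(data, c("id", "smiles"), "novelty_filter")
  check_number(tc_threshold, "tc_threshold", lower = 0, upper = 1)
  cand_fps <- library_fingerprints(data)
  if (length(reference_smiles) == 0L) {
    return(tibble(id = data$id, max_tc = 0,
                  nearest_reference = NA_character_, kept = TRUE))
  }
  ref_fps <- fingerprint(reference_smiles)
  if (inherits(ref_fps, "dockpharm_fp")) ref_fps <- list(ref_fps)
  ref_names <- names(ref_fps) %||% paste0("ref", seq_along(ref_fps))
  if (is.null(names(ref_fps)) || any(!nzchar(ref_names))) {
    ref_names <- paste0("ref", seq_along(ref_fps))
  }
  res <- map(data$id, function(id_i) {
    tcs <- tanimoto_many(cand_fps[[id_i]], ref_fps)
    best <- which.max(tcs)
    tibble(id = id_i, max_tc = tcs[best],
           nearest_reference = ref_names[best],
           kept = tcs[best] < tc_threshold)
  })
  bind_rows(res)
}

#' Analog retrieval around a hit
#'
#' Returns pool members whose Tanimoto similarity to the hit is at least
#' `tc_min` (the analog-by-catalog criterion, default 0.5), sorted by
#' descending similarity then ascending id.
#'
#' @param data Pool tibble with `id` and `smiles` columns.
#' @param hit_smiles SMILES of the query hit.
#' @param tc_min Minimum Tanimoto similarity (inclusive, default 0.5).
#' @return Filtered tibble with a `tc` column added.
#' @export
analog_search <- function(data, hit_smiles, tc_min = 0.5) {
  check_columns(data, c("id", "smiles"), "analog_search")
  check_number(tc_min, "tc_min", lower = 0, upper = 1)
  hit_fp <- fingerprint(hit_smiles)
  pool_fps <- library_fingerprints(data)
  tcs <- tanimoto_many(hit_fp, pool_fps[data$id])
  as_tibble(data) |>
    mutate(tc = unname(tcs)) |>
    filter(.data$tc >= tc_min) |>
    arrange(desc(.data$tc), .data$id)
}

#' Docking campaign sampling bookkeeping
#'
#' Derived pose-sampling totals for a docking campaign: mean poses per
#' molecule (orientations x conformations, also reported in millions to
#' three significant figures) and total sampled complexes.
#'
#' @param n_input Library size submitted to docking.
#' @param n_fit Number of molecules successfully fit/docked.
#' @param mean_orientations,mean_conformations Mean rigid-body
#'   orientations per molecule and conformations per orientation.
#' @return One-row tibble: the four inputs plus `mean_poses_per_molecule`,
#'   `mean_poses_millions` (3 significant figures) and `total_complexes`.
#' @examples
#' campaign_summary(74e6, 18e6, 4706, 645)
#' @export
campaign_summary <- function(n_input, n_fit, mean_orientations,
                             mean_conformations) {
  check_number(n_input, "n_input", lower = 0)
  check_number(n_fit, "n_fit", lower = 0)
  check_number(mean_orientations, "mean_orientations", lower = 0)
  check_number(mean_conformations, "mean_conformations", lower = 0)
  if (n_fit > n_input) {
    abort("`n_fit` cannot exceed `n_input`.")
  }
  poses <- mean_orientations * mean_conformations
  tibble(
    n_input = n_input,
    n_fit = n_fit,
    mean_orientations = mean_orientations,
    mean_conformations = mean_conformations,
    mean_poses_per_molecule = poses,
    mean_poses_millions = signif(poses / 1e6, 3),
    total_complexes = n_fit * poses
  )
}

#' Fulfilment rate of a make-on-demand synthesis order
#'
#' Percent of requested compounds successfully delivered, reported both
#' unrounded and to the nearest integer (e.g. 52 of 60 requested is an
#' 87% fulfilment).
#'
#' @param n_requested Compounds ordered for synthesis.
#' @param n_synthesized Compounds successfully made (`<= n_requested`).
#' @return One-row tibble: `n_requested`, `n_synthesized`,
#'   `rate_percent`, `rate_reported`.
#' @export
fulfilment_rate <- function(n_requested, n_synthesized) {
  n_requested <- check_count(n_requested, "n_requested")
  n_synthesized <- check_count(n_synthesized, "n_synthesized", min = 0L)
  if (n_synthesized > n_requested) {
    abort("`n_synthesized` cannot exceed `n_requested`.")
  }
  rate <- 100 * n_synthesized / n_requested
  tibble(n_requested = n_requested, n_synthesized = n_synthesized,
         rate_percent = rate, rate_reported = round(rate))
}

#' Single-point screening hit rate
#'
#' Counts compounds whose radioligand displacement is strictly above a
#' threshold ("displaced over 50%") and reports the hit rate.
#'
#' @param displacement Numeric vector of percent displacement values
#'   (values above 100 are clipped to 100).
#' @param threshold Displacement threshold in percent (strict, default 50).
#' @return One-row tibble: `n`, `n_hits`, `rate_percent` (unrounded) and
#'   `rate_reported` (nearest integer).
#' @examples
#' hit_rate(c(rep(80, 9), rep(10, 37)))
#' @export
hit_rate <- function(displacement, threshold = 50) {
  if (!is.numeric(displacement) || !length(displacement)) {
    abort("`displacement` must be a non-empty numeric vector.")
  }
  check_number(threshold, "threshold")
  displacement <- pmin(displacement, 100)
  n_hits <- sum(displacement > threshold)
  rate <- 100 * n_hits / length(displacement)
  tibble(n = length(displacement), n_hits = n_hits,
         rate_percent = rate, rate_reported = round(rate))
}
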