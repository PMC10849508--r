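# Seeded synthetic-data generators.
#
# Each generator emulates the statistical structure of one pipeline
# input: a score-ranked library with planted chemotype families, pose
# pairs with a known atom permutation and a known optimal-assignment
# RMSD, concentration-response curves from a known 4PL truth, and
# one-compartment PK time courses with a quantitation limit. All are
# deterministic given `seed` and restore the caller's RNG state.

# Scaffold library for family construction: chemically diverse cores,
# each written so that appending a substituent SMILES extends the
# molecule at a chemically sensible position. Chosen so that, under the
# package fingerprinter, molecules sharing a scaffold are typically
# Tc >= 0.5 to each other while molecules from different scaffolds are
# typically Tc < 0.38.
FAMILY_SCAFFOLDS <- c(
  "CC(C)Cc1ccc(cc1)C(C)C(=O)NC",
  "Fc1ccc(cc1)C(=O)N1CCCCC1C",
  "c1ccc2[nH]c(c(c2c1)C)C(=O)NC",
  "Cc1ccc2[nH]ncc2c1CNC",
  "CC(C)(C)c1ccc(cc1)OCC(=O)N",
  "c1ccc(cc1)C(=O)NCc1ccc(o1)C",
  "C1COCCN1S(=O)(=O)c1ccc(cc1)C",
  "Cn1cnc(c1)CC(=O)NC",
  "Clc1cccc(c1)NC(=O)C1CCC1",
  "c1cnc2ccccn2c1C(=O)N",
  "O1CCCC1CNC(=O)CC",
  "c1ccc(cc1)NC(=O)NCc1cccnc1",
  "c1ccc(cc1)CCOC(=O)CC",
  "O=C1CCCCN1Cc1ccccc1",
  "c1ccc2ccccc2c1OCC",
  "c1ccc(cc1)NC(=O)N1CCOCC1",
  "c1csc(n1)NC(=O)CC",
  "N#Cc1ccc(cc1)CNCC",
  "c1ccc(cc1)P(=O)(OC)OC",
  "O=C1CC(=NN1c1ccccc1)C",
  "c1ccc(cc1)OCCN1CCCC1",
  "c1ccc(cc1)C1CCN(CC1)CC"
)

FAMILY_SUBSTITUENTS <- c(
  "CC", "CCC", "CCO", "CCN", "CCF", "C(C)C", "COC"
)

#' Simulate a score-ranked docking library with planted chemotype families
#'
#' Generates `n_molecules` molecules as `n_families` structural families,
#' each family a shared scaffold with small enumerated substituents (so
#' that intra-family fingerprint similarity is typically above the 0.5
#' clustering threshold and inter-family similarity typically below the
#' 0.38 novelty threshold). Molecular weight and cLogP are sampled
#' uniformly inside the configured windows; docking scores are a
#' family-level base score plus Gaussian noise, and records are returned
#' best-score-first with ranks assigned.
#'
#' @param n_molecules,n_families Counts (families cannot exceed the
#'   built-in scaffold set of `r length(FAMILY_SCAFFOLDS)`).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param mw_range,clogp_range Closed sampling intervals (defaults: the
#'   350-500 amu, cLogP 3-5 docking-library windows).
#' @param score_noise_sd Gaussian score noise, docking-score units.
#' @param substituent_variation If `FALSE`, every family member is the
#'   bare scaffold (all pairwise Tc 1 within a family).
#' @return Ligand tibble: `id`, `smiles`, `family`, `mw`, `clogp`,
#'   `score`, `rank`, sorted by score (best = lowest first).
#' @examples
#' lib <- sim_library(50, n_families = 5, seed = 1)
#' @export
sim_library <- function(n_molecules, n_families, seed,
                        mw_range = c(350, 500), clogp_range = c(3, 5),
                        score_noise_sd = 2, substituent_variation = TRUE) {
  n_molecules <- check_count(n_molecules, "n_molecules")
  n_families <- check_count(n_families, "n_families")
  check_count(seed, "seed", min = 0L)
  check_number(score_noise_sd, "score_noise_sd", lower = 0)
  if (n_families > length(FAMILY_SCAFFOLDS)) {
    abort(sprintf("At most %d families are available.",
                  length(FAMILY_SCAFFOLDS)))
  }
  with_seed(seed, {
    scaffolds <- sample(FAMILY_SCAFFOLDS, n_families)
    base_score <- runif(n_families, -45, -25)
    family <- sort(rep_len(seq_len(n_families), n_molecules))
    subs <- if (substituent_variation) {
      sample(FAMILY_SUBSTITUENTS, n_molecules, replace = TRUE)
    } else {
      rep("", n_molecules)
    }
    out <- tibble(
      id = sprintf("lig%05d", seq_len(n_molecules)),
      smiles = paste0(scaffolds[family], subs),
      family = family,
      mw = runif(n_molecules, mw_range[1], mw_range[2]),
      clogp = runif(n_molecules, clogp_range[1], clogp_range[2]),
      score = base_score[family] + rnorm(n_molecules, sd = score_noise_sd)
    )
    out |>
      arrange(.data$score, .data$id) |>
      mutate(rank = row_number())
  })
}

#' Simulate a pose pair with a known atom permutation and known RMSD
#'
#' Builds a reference pose on a jittered lattice (atoms well separated),
#' then derives a second pose by (i) applying a random permutation among
#' atoms of the listed elements and (ii) adding an isotropic Gaussian
#' displacement rescaled so that the optimal-assignment RMSD equals
#' `rmsd_target` exactly. Displacements are kept below half the minimum
#' same-element atom separation, which guarantees by construction that the
#' planted matching is the optimal assignment (so `true_rmsd` is exact,
#' not approximate).
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param permuted_elements Elements whose atoms are permuted between the
#'   two poses (each gets at least two atoms); remaining atoms are carbon.
#' @param rmsd_target Target optimal-assignment RMSD in Angstrom (>= 0).
#' @param seed Integer RNG seed.
#' @return List with `pose_a`, `pose_b`, `true_rmsd`, and `permutation`
#'   (the planted atom mapping from `pose_a` rows to `pose_b` rows).
#' @export
sim_pose_pair <- function(n_atoms, permuted_elements = "O",
                          rmsd_target = 0.5, seed = 1) {
  n_atoms <- check_count(n_atoms, "n_atoms", min = 2L)
  check_number(rmsd_target, "rmsd_target", lower = 0)
  check_count(seed, "seed", min = 0L)
  k <- length(permuted_elements)
  if (n_atoms < 2 * k) {
    abort("`n_atoms` must allow at least two atoms per permuted element.")
  }
  elements <- rep("C", n_atoms)
  slot <- 1L
  for (e in permuted_elements) {
    elements[slot:(slot + 1L)] <- e
    slot <- slot + 2L
  }
  # extra atoms beyond 2 per permuted element stay carbon
  with_seed(seed, {
    # jittered lattice: spacing 3 A, jitter < 0.5 A => separation > 2 A
    side <- ceiling(n_atoms^(1 / 3))
    grid <- expand.grid(x = seq_len(side), y = seq_len(side),
                        z = seq_len(side)) * 3
    grid <- as.matrix(grid[seq_len(n_atoms), , drop = FALSE])
    coords_a <- grid + matrix(runif(3 * n_atoms, -0.4, 0.4), n_atoms, 3)

    min_sep <- Inf
    for (e in unique(elements)) {
      idx <- which(elements == e)
      if (length(idx) > 1) {
        min_sep <- min(min_sep, min(stats::dist(coords_a[idx, , drop = FALSE])))
      }
    }

    # permutation within permuted element classes only
    perm <- seq_len(n_atoms)
    for (e in permuted_elements) {
      idx <- which(elements == e)
      perm[idx] <- idx[sample(length(idx))]
    }

    disp <- matrix(0, n_atoms, 3)
    if (rmsd_target > 0) {
      ok <- FALSE
      for (try in 1:100) {
        raw <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
        raw <- raw * rmsd_target * sqrt(n_atoms) / sqrt(sum(raw^2))
        if (is.infinite(min_sep) ||
            max(sqrt(rowSums(raw^2))) < 0.49 * min_sep) {
          disp <- raw
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("`rmsd_target` is too large for the constructed geometry.")
      }
    }

    coords_b <- (coords_a + disp)[perm, , drop = FALSE]
    list(
      pose_a = pose(elements, coords_a[, 1], coords_a[, 2], coords_a[, 3],
                    ligand_id = "sim_a"),
      pose_b = pose(elements[perm], coords_b[, 1], coords_b[, 2],
                    coords_b[, 3], ligand_id = "sim_b"),
      true_rmsd = rmsd_target,
      permutation = perm
    )
  })
}

#' Simulate replicated concentration-response data from a 4PL truth
#'
#' @param bottom,top Lower/upper plateaus (response units, e.g. percent).
#' @param pec50 True -log10 molar EC50.
#' @param hill True Hill slope (> 0 for rising agonist curves).
#' @param concentrations Molar concentrations: at least 4 distinct values
#'   spanning at least 2 log units.
#' @param replicates Replicates per concentration.
#' @param noise_sd Gaussian noise SD as a fraction of the span
#'   `top - bottom`.
#' @param seed Integer RNG seed.
#' @return Tibble `concentration`, `replicate`, `response`, with the true
#'   parameters in `attr(, "true_params")`.
#' @export
sim_dose_response <- function(bottom = 0, top = 100, pec50 = 8, hill = 1,
                              concentrations = 10^seq(-12, -5, 1),
                              replicates = 3, noise_sd = 0.05, seed = 1) {
  replicates <- check_count(replicates, "replicates")
  check_count(seed, "seed", min = 0L)
  check_number(noise_sd, "noise_sd", lower = 0)
  conc <- sort(unique(concentrations))
  if (length(conc) < 4 || any(conc <= 0)) {
    abort("Need at least 4 distinct positive concentrations.")
  }
  if (log10(max(conc) / min(conc)) < 2) {
    abort("Concentrations must span at least 2 log units.")
  }
  mu <- predict_4pl(concentrations,
                    bottom = bottom, top = top, pec50 = pec50, hill = hill)
  with_seed(seed, {
    out <- tidyr::expand_grid(concentration = concentrations,
                              replicate = seq_len(replicates)) |>
      mutate(response = rep(mu, each = replicates) +
               rnorm(n(), sd = noise_sd * abs(top - bottom)))
    attr(out, "true_params") <- c(bottom = bottom, top = top,
                                  pec50 = pec50, hill = hill)
    out
  })
}

#' Simulate a one-compartment extravascular PK profile
#'
#' Concentrations follow the one-compartment first-order absorption model
#' `C(t) = F * Dose * ka / (V * (ka - ke)) * (exp(-ke t) - exp(-ka t))`,
#' with optional Gaussian noise, and a lower limit of quantitation below
#' which observations are flagged.
#'
#' @param times Sampling times in minutes, strictly increasing, >= 3
#'   points (default: the 5-1440 min sparse sampling design).
#' @param dose_mg_kg Dose in mg/kg (default 0.2, a low analgesic dose).
#' @param body_weight_g Body weight in grams (default 30, mouse).
#' @param ka,ke First-order absorption and elimination rates (1/min);
#'   defaults give a terminal half-life near 114 min. `ka == ke` is the
#'   degenerate model and errors.
#' @param volume_ml Apparent volume of distribution (mL); the default
#'   gives peak concentrations near 17 ng/mL, the brain-tissue exposure
#'   scale of a 0.2 mg/kg dose.
#' @param bioavailability Fraction absorbed `F`.
#' @param lloq Lower limit of quantitation (default 1, the lower edge
#'   of typical tissue LLOQs).
#' @param noise_sd Gaussian noise SD as a fraction of the model Cmax.
#' @param seed Integer RNG seed.
#' @return Tibble `time`, `conc`, `below_limit`, with true parameters in
#'   `attr(, "true_params")` and `attr(, "usable")` FALSE when every point
#'   is below the quantitation limit.
#' @export
sim_pk_profile <- function(times = c(5, 15, 30, 60, 120, 240, 360, 480, 1440),
                           dose_mg_kg = 0.2, body_weight_g = 30,
                           ka = 0.05, ke = log(2) / 114, volume_ml = 275,
                           bioavailability = 1, lloq = 1,
                           noise_sd = 0, seed = 1) {
  if (length(times) < 3 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with at least 3 points.")
  }
  check_number(ka, "ka", lower = 0, allow_zero = FALSE)
  check_number(ke, "ke", lower = 0, allow_zero = FALSE)
  if (ka == ke) {
    abort("`ka` equal to `ke` is the degenerate one-compartment model.")
  }
  check_number(lloq, "lloq", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_count(seed, "seed", min = 0L)
  dose_ng <- dose_mg_kg * body_weight_g * 1000 # mg/kg * g -> ng
  cmod <- function(t) {
    bioavailability * dose_ng * ka / (volume_ml * (ka - ke)) *
      (exp(-ke * t) - exp(-ka * t))
  }
  conc <- cmod(times)
  with_seed(seed, {
    if (noise_sd > 0) {
      conc <- pmax(0, conc + rnorm(length(times),
                                   sd = noise_sd * max(conc)))
    }
    out <- tibble(time = as.numeric(times), conc = conc,
                  below_limit = conc < lloq)
    attr(out, "true_params") <- c(ka = ka, ke = ke, t_half = log(2) / ke,
                                  dose_ng = dose_ng, volume_ml = volume_ml,
                                  lloq = lloq)
    attr(out, "usable") <- !all(out$below_limit)
    out
  })
}

#' Write a library to a .smi file (SMILES TAB id)
#'
#' @param data Ligand tibble with `smiles` and `id` columns.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_smi <- function(data, file) {
  check_columns(data, c("id", "smiles"), "write_smi")
  writeLines(paste(data$smiles, data$id, sep = "\t"), file)
  invisible(file)
}

#' Read a .smi file (SMILES TAB id) into a ligand tibble
#'
#' @param file Path to a .smi file.
#' @return Tibble with `id` and `smiles` columns.
#' @export
read_smi <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  tibble(
    id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1)),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}
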