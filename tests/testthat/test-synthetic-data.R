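# Generators: determinism, configured ranges, and the planted structure
# each downstream stage relies on.

test_that("generators are deterministic given a seed and differ across seeds", {
  expect_identical(sim_library(30, 3, seed = 1), sim_library(30, 3, seed = 1))
  expect_false(identical(sim_library(30, 3, seed = 1)$smiles,
                         sim_library(30, 3, seed = 2)$smiles))

  pp1 <- sim_pose_pair(6, "O", rmsd_target = 0.4, seed = 5)
  pp2 <- sim_pose_pair(6, "O", rmsd_target = 0.4, seed = 5)
  expect_identical(pp1, pp2)

  expect_identical(sim_dose_response(seed = 3), sim_dose_response(seed = 3))
  expect_identical(sim_pk_profile(seed = 4), sim_pk_profile(seed = 4))
})

test_that("library records respect configured property windows and ranking", {
  lib <- sim_library(200, 8, seed = 11,
                     mw_range = c(350, 500), clogp_range = c(3, 5))
  expect_true(all(lib$mw >= 350 & lib$mw <= 500))
  expect_true(all(lib$clogp >= 3 & lib$clogp <= 5))
  expect_false(is.unsorted(lib$score))
  expect_identical(lib$rank, seq_len(nrow(lib)))
  expect_false(anyDuplicated(lib$id) > 0)
  expect_error(sim_library(0, 1, seed = 1), "n_molecules")
  expect_error(sim_library(10, 0, seed = 1), "n_families")
})

test_that("a single family without substituent variation is all-identical", {
  lib <- sim_library(6, 1, seed = 2, substituent_variation = FALSE)
  fps <- fingerprint(setNames(lib$smiles, lib$id))
  for (i in 1:5) {
    expect_equal(tanimoto(fps[[i]], fps[[i + 1]]), 1.0)
  }
})

test_that("leader clustering recovers planted families (adjusted agreement)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    lib <- sim_library(500, n_families = 20, seed = s)
    cl <- leader_cluster(lib)
    mclust::adjustedRandIndex(cl$family, cl$cluster)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("pose pairs carry an exactly known optimal-assignment RMSD", {
  # zero displacement: any permutation of identical coordinates
  pp0 <- sim_pose_pair(6, "O", rmsd_target = 0, seed = 3)
  expect_equal(symmetry_rmsd(pp0$pose_a, pp0$pose_b), 0, tolerance = 1e-12)

  # uniform translation with no permutation: both RMSDs equal the shift
  pa <- sim_pose_pair(5, character(0), rmsd_target = 0, seed = 6)$pose_a
  pb <- pa
  pb$x <- pb$x + 0.7
  expect_equal(naive_rmsd(pa, pb), 0.7, tolerance = 1e-12)
  expect_equal(symmetry_rmsd(pa, pb), 0.7, tolerance = 1e-12)

  # generated pairs match the brute-force permutation oracle
  pp <- sim_pose_pair(6, "O", rmsd_target = 0.5, seed = 7)
  expect_equal(symmetry_rmsd(pp$pose_a, pp$pose_b), pp$true_rmsd,
               tolerance = 1e-6)
  expect_equal(brute_force_rmsd(pp$pose_a, pp$pose_b), pp$true_rmsd,
               tolerance = 1e-6)

  expect_error(sim_pose_pair(6, "O", rmsd_target = -1, seed = 1))
  expect_error(sim_pose_pair(1, "O", seed = 1))
})

test_that("noiseless dose-response curves are fit exactly", {
  curve <- sim_dose_response(bottom = 5, top = 95, pec50 = 7.5, hill = 1.2,
                             noise_sd = 0, seed = 1)
  truth <- attr(curve, "true_params")
  fit <- fit_4pl(curve)
  expect_true(fit$converged)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["pec50"]], truth[["pec50"]], tolerance = 1e-6)
  expect_equal(est[["hill"]], truth[["hill"]], tolerance = 1e-6)
  rss <- sum((curve$response -
                predict_4pl(curve$concentration, est[["bottom"]],
                            est[["top"]], est[["pec50"]],
                            est[["hill"]]))^2)
  span <- truth[["top"]] - truth[["bottom"]]
  expect_lt(rss, 1e-10 * span^2)
})

test_that("midpoint identity holds at the EC50 with hill = 1", {
  curve <- sim_dose_response(bottom = 0, top = 100, pec50 = 8, hill = 1,
                             concentrations = c(1e-10, 1e-9, 1e-8, 1e-7,
                                                1e-6),
                             noise_sd = 0, seed = 1)
  at_ec50 <- curve$response[curve$concentration == 1e-8]
  expect_equal(unique(round(at_ec50, 10)), 50)
})

test_that("dose-response generator validates its design", {
  expect_error(sim_dose_response(concentrations = c(1e-9, 1e-8, 1e-7),
                                 seed = 1),
               "4 distinct")
  expect_error(sim_dose_response(concentrations = c(1e-9, 2e-9, 3e-9,
                                                    4e-9), seed = 1),
               "2 log units")
})

test_that("fitted pEC50 is essentially unbiased at 5% replicate noise", {
  truth <- 8
  est <- vapply(1:100, function(s) {
    curve <- sim_dose_response(bottom = 0, top = 100, pec50 = truth,
                               hill = 1, noise_sd = 0.05, seed = s)
    fit <- fit_4pl(curve)
    fit$estimates$estimate[fit$estimates$term == "pec50"]
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 0.05)
})

test_that("PK profiles follow the one-compartment model and flag the LLOQ", {
  prof <- sim_pk_profile(times = c(0, 5, 15, 30, 60, 120, 240, 480),
                         seed = 1)
  expect_equal(prof$conc[prof$time == 0], 0) # extravascular: nothing yet
  expect_true(all(prof$below_limit == (prof$conc < 1)))

  # LLOQ above the peak: everything below limit, profile unusable
  hi <- sim_pk_profile(lloq = 1e6, seed = 1)
  expect_true(all(hi$below_limit))
  expect_false(attr(hi, "usable"))

  expect_error(sim_pk_profile(ka = 0.01, ke = 0.01, seed = 1),
               "degenerate")
  expect_error(sim_pk_profile(times = c(10, 5, 20), seed = 1))
})

test_that("NCA recovers the half-life of a noise-free generated profile", {
  prof <- sim_pk_profile(times = c(5, 15, 30, 60, 120, 240, 360, 480, 720,
                                   1440),
                         lloq = 0, noise_sd = 0, seed = 1)
  truth <- attr(prof, "true_params")
  res <- nca(prof)
  expect_equal(res$t_half, truth[["t_half"]], tolerance = 0.01)
})

test_that("smi files round-trip a library", {
  lib <- sim_library(10, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".smi")
  write_smi(lib, path)
  back <- read_smi(path)
  expect_equal(back$id, lib$id)
  expect_equal(back$smiles, lib$smiles)
})
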