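# Hit-triage cascade: property windows, fingerprints, similarity,
# clustering, novelty, analogs, campaign bookkeeping.

test_that("property windows are closed intervals applied in order", {
  lib <- tibble::tibble(
    id = paste0("m", 1:10),
    mw = c(350, 349.9, 500, 500.1, 420, 430, 300, 510, 480, 360),
    clogp = c(3, 3.5, 5, 4, 2.9, 5.1, 4, 4, 3.2, 4.8)
  )
  kept <- property_filter(lib)
  # brute-force predicate, record by record
  manual <- lib$id[lib$mw >= 350 & lib$mw <= 500 &
                     lib$clogp >= 3 & lib$clogp <= 5]
  expect_identical(kept$id, manual)
  # boundary molecules are kept, just-outside ones rejected
  expect_true("m1" %in% kept$id) # mw 350, clogp 3
  expect_true("m3" %in% kept$id) # mw 500, clogp 5
  expect_false("m2" %in% kept$id) # mw 349.9
  # idempotence
  expect_identical(property_filter(kept), kept)
})

test_that("fingerprints are deterministic and canonicalisation-invariant", {
  expect_identical(fingerprint("CCO")$bits, fingerprint("CCO")$bits)
  expect_identical(fingerprint("CCO")$bits, fingerprint("OCC")$bits)
  expect_identical(fingerprint("c1ccccc1C(=O)NC")$bits,
                   fingerprint("CNC(=O)c1ccccc1")$bits)
  # chemically unrelated molecules are dissimilar under this fingerprinter
  expect_lt(tanimoto(fingerprint("c1ccccc1"), fingerprint("CCCCCC")), 0.2)
  expect_error(fingerprint(character(0)))
})

test_that("tanimoto obeys its set identities", {
  a <- make_fp(c(1L, 5L, 9L, 100L))
  b <- make_fp(c(5L, 9L, 250L))
  expect_equal(tanimoto(a, b), 2 / 5) # |overlap| 2, |union| 5
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(make_fp(1:4), make_fp(5:8)), 0.0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_warning(z <- tanimoto(make_fp(integer(0)), make_fp(integer(0))),
                 "empty")
  expect_equal(z, 0.0)
  expect_error(tanimoto(a, make_fp(1:3, radius = 3)), "radius")
})

test_that("leader clustering handles degenerate libraries", {
  # all-identical molecules collapse to one cluster led by the best score
  lib <- tibble::tibble(id = paste0("m", 1:5),
                        smiles = rep("c1ccccc1C(=O)NCC", 5),
                        score = c(-30, -42, -35, -33, -38))
  cl <- leader_cluster(lib)
  expect_equal(unique(cl$cluster), "m2") # best score -42
  expect_equal(sum(cl$is_representative), 1L)

  # all-dissimilar molecules are singletons
  lib2 <- sim_library(5, 5, seed = 4, substituent_variation = FALSE)
  cl2 <- leader_cluster(lib2)
  expect_equal(cl2$cluster, cl2$id)
})

test_that("leader clustering matches an independent brute-force pass", {
  for (s in c(1, 7)) {
    lib <- sim_library(50, 6, seed = s)
    fps <- dockpharm:::library_fingerprints(lib)
    cl <- leader_cluster(lib, fps = fps)
    sim_fun <- function(i, j) tanimoto(fps[[i]], fps[[j]])
    oracle <- brute_force_leader(cl$id, sim_fun, 0.5)
    expect_identical(cl$cluster, oracle)
  }
})

test_that("leader clusters partition the input and satisfy the type invariants", {
  lib <- sim_library(80, 8, seed = 13)
  fps <- dockpharm:::library_fingerprints(lib)
  cl <- leader_cluster(lib, fps = fps)
  # partition: every record appears once
  expect_setequal(cl$id, lib$id)
  for (k in unique(cl$cluster)) {
    members <- cl[cl$cluster == k, ]
    # representative is a member with the best (lowest) score
    expect_true(k %in% members$id)
    expect_equal(min(members$score), members$score[members$id == k])
    # every member within the threshold of its representative
    expect_true(all(vapply(members$id, function(i) {
      tanimoto(fps[[i]], fps[[k]]) >= 0.5
    }, logical(1))))
  }
  expect_error(leader_cluster(lib, fps = fps[-1]), "Missing fingerprint")
})

test_that("novelty rejection is inclusive at the threshold", {
  lib <- sim_library(12, 2, seed = 21)
  # candidate identical to a reference: rejected at max_tc 1
  rep1 <- novelty_filter(lib[1, ], reference_smiles = lib$smiles[1])
  expect_equal(rep1$max_tc, 1.0)
  expect_false(rep1$kept)

  # empty reference set: everything kept at max_tc 0
  rep0 <- novelty_filter(lib, reference_smiles = character(0))
  expect_true(all(rep0$kept))
  expect_true(all(rep0$max_tc == 0))

  # a candidate whose max Tc lands exactly on the threshold is rejected
  refs <- lib$smiles[lib$family == 2][1]
  scan <- novelty_filter(lib, reference_smiles = refs, tc_threshold = 1)
  tc_obs <- scan$max_tc[scan$max_tc > 0 & scan$max_tc < 1][1]
  at_thr <- novelty_filter(lib, reference_smiles = refs,
                           tc_threshold = tc_obs)
  expect_false(all(at_thr$kept[at_thr$max_tc == tc_obs]))
  expect_true(all(at_thr$kept[at_thr$max_tc < tc_obs]))
})

test_that("novelty keep decisions are monotone in the threshold", {
  lib <- sim_library(20, 4, seed = 31)
  refs <- sim_library(5, 2, seed = 32)$smiles
  t1 <- novelty_filter(lib, refs, tc_threshold = 0.3)
  t2 <- novelty_filter(lib, refs, tc_threshold = 0.6)
  # anything kept at the stricter threshold stays kept at the looser one
  expect_true(all(!t1$kept | t2$kept))
})

test_that("analog retrieval returns the planted family, best first", {
  lib <- sim_library(60, 6, seed = 41)
  hit <- lib[lib$family == 3, ][1, ]
  pool <- lib
  res <- analog_search(pool, hit$smiles)
  # the hit itself leads with Tc 1
  expect_equal(res$tc[1], 1.0)
  # exactly the planted family is recovered
  expect_setequal(res$id, lib$id[lib$family == 3])
  expect_true(all(diff(res$tc) <= 0))

  # pool from other families only: no analogs at the default threshold
  other <- lib[lib$family != 3, ]
  expect_equal(nrow(analog_search(other, hit$smiles)), 0L)
})

test_that("campaign bookkeeping reproduces the printed sampling arithmetic", {
  cs <- campaign_summary(74e6, 18e6, 4706, 645)
  expect_equal(cs$mean_poses_per_molecule, 3035370)
  expect_equal(cs$mean_poses_millions, 3.04)
  expect_equal(cs$total_complexes, 18e6 * 3035370)

  expect_equal(campaign_summary(10, 10, 0, 100)$mean_poses_per_molecule, 0)
  expect_equal(campaign_summary(10, 10, 10, 10)$total_complexes, 1000)
  expect_error(campaign_summary(10, 20, 1, 1), "exceed")
})

test_that("hit rate counts strict exceedances and reports a rounded rate", {
  # 9 of 46 displacing over 50% is the campaign's 20% hit rate
  disp <- c(rep(80, 9), rep(30, 37))
  hr <- hit_rate(disp)
  expect_equal(hr$n_hits, 9L)
  expect_equal(hr$rate_reported, 20)
  expect_equal(hr$rate_percent, 100 * 9 / 46)

  expect_equal(hit_rate(c(10, 20))$rate_reported, 0)
  expect_equal(hit_rate(c(60, 70))$rate_reported, 100)
  # boundary: exactly at threshold does not count
  expect_equal(hit_rate(c(50, 90))$n_hits, 1L)
  # over-displacement clipped, still a single hit
  expect_equal(hit_rate(c(150))$n_hits, 1L)
  expect_error(hit_rate(numeric(0)))
})
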