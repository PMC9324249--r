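test_that("covariance construction places baseline couplings by class", {
  parc <- make_parcellation(12, lobe_fractions = c(frontal = 0.5,
                                                   temporal = 0.5))
  spec <- cohort_spec(n_per_group = c(HC = 2, LGG = 2, HGG = 2),
                      base_r_homotopic = 0.5)
  S <- build_covariance(parc, spec, effect_spec("HC"))
  expect_true(isSymmetric(S))
  expect_equal(diag(S), rep(1, 12))
  hp <- homotopic_pairs(parc)
  expect_equal(unname(S[cbind(hp[, 1] + 1, hp[, 2] + 1)]),
               rep(0.5, nrow(hp)))
  same_lobe_same_hemi <- parc$lobe[1] == parc$lobe[2] &&
    parc$hemisphere[1] == parc$hemisphere[2]
  expect_true(same_lobe_same_hemi)
  expect_equal(S[1, 2], spec$base_r_within_lobe)
})

test_that("LGG deltas shift left couplings and leave the right untouched", {
  parc <- make_parcellation(16)
  spec <- cohort_spec()
  S0 <- build_covariance(parc, spec, effect_spec("HC"))
  S1 <- build_covariance(parc, spec,
                         effect_spec("LGG", delta_left_global = 0.1))
  left <- parc$hemisphere == "L"
  inter_lobe <- outer(parc$lobe, parc$lobe, "!=")
  lmask <- outer(left, left, "&") & inter_lobe
  diag(lmask) <- FALSE
  expect_equal(S1[lmask], S0[lmask] + 0.1)
  rmask <- outer(!left, !left, "&")
  diag(rmask) <- FALSE
  expect_equal(S1[rmask], S0[rmask])
})

test_that("default group covariances are positive definite", {
  parc <- make_parcellation(136)
  spec <- cohort_spec()
  for (eff in default_effects()) {
    S <- build_covariance(parc, spec, eff)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("out-of-range deltas are rejected", {
  parc <- make_parcellation(8, lobe_fractions = c(frontal = 1))
  spec <- cohort_spec(base_r_within_lobe = 0.9)
  expect_error(build_covariance(parc, spec,
                                effect_spec("LGG", delta_local = 0.1)),
               "outside")
})

test_that("simulated series reproduce the planted covariance", {
  # planted r = 0.5 pair at scan length 160: Fisher-z sampling theory
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  r <- replicate(500, {
    x <- simulate_timeseries(S, 160, ar_coeff = 0,
                             seed = sample.int(1e6, 1))
    cor(x)[1, 2]
  })
  expect_lt(abs(mean(r) - 0.5), 0.02)
  z <- atanh(r)
  covered <- abs(z - atanh(0.5)) <= 1.96 / sqrt(157)
  expect_gt(mean(covered), 0.90)  # nominal 95 %
  # independence under the identity covariance
  x <- simulate_timeseries(diag(4), 2000, 0, seed = 11)
  rr <- cor(x)
  expect_lt(mean(abs(rr[upper.tri(rr)])), 0.05)
})

test_that("long-run sample moments match the generator's parameters", {
  parc <- make_parcellation(8)
  spec <- cohort_spec(ar_coeff = 0.4)
  S <- build_covariance(parc, spec, effect_spec("HC"))
  x <- simulate_timeseries(S, 5000, 0.4, seed = 5)
  R <- cor(x)
  expect_lt(max(abs(R - S)), 0.06)
  ac1 <- vapply(seq_len(ncol(x)), function(j) {
    cor(x[-1, j], x[-nrow(x), j])
  }, numeric(1))
  expect_true(all(abs(ac1 - 0.4) < 0.05))
})

test_that("identical seeds give identical draws and cohorts", {
  S <- diag(3)
  expect_identical(simulate_timeseries(S, 50, 0.3, seed = 9),
                   simulate_timeseries(S, 50, 0.3, seed = 9))
  parc <- make_parcellation(8)
  spec <- cohort_spec(n_per_group = c(HC = 2, LGG = 2, HGG = 2),
                      n_volumes = 20, master_seed = 77L)
  c1 <- generate_cohort(parc, spec)
  c2 <- generate_cohort(parc, spec)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("cohort has requested sizes, metadata and per-subject seeds", {
  parc <- make_parcellation(12)
  spec <- cohort_spec(n_volumes = 20, master_seed = 3L)
  cohort <- generate_cohort(parc, spec)
  man <- cohort_manifest(cohort)
  expect_equal(nrow(man), 80)
  expect_equal(unname(table(man$group)[c("HC", "LGG", "HGG")]),
               c(20L, 30L, 30L), ignore_attr = TRUE)
  expect_true(all(is.na(man$tumor_location[man$group == "HC"])))
  expect_true(all(!is.na(man$tumor_location[man$group != "HC"])))
  expect_true(all(is.na(man$tumor_size[man$group == "HC"])))
  expect_true(all(man$tumor_size[man$group != "HC"] > 0.5))
  # seeds are distinct and reproducible from subject ids
  expect_equal(length(unique(man$seed)), nrow(man))
  expect_equal(man$seed[1],
               (3 + gliomaconn:::stable_hash(man$subject_id[1])) %% 2147483647)
  # tiny cohort
  spec2 <- cohort_spec(n_per_group = c(HC = 2, LGG = 2, HGG = 2),
                       n_volumes = 20)
  expect_equal(length(generate_cohort(parc, spec2)$subjects), 6)
})

test_that("cohorts round-trip through the TSV layout", {
  parc <- make_parcellation(8)
  spec <- cohort_spec(n_per_group = c(HC = 2, LGG = 2, HGG = 2),
                      n_volumes = 15)
  cohort <- generate_cohort(parc, spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$subjects), names(cohort$subjects))
  s0 <- cohort$subjects[[1]]; s1 <- back$subjects[[1]]
  expect_equal(s1$data, s0$data, tolerance = 1e-12)
  expect_equal(s1$group, s0$group)
  expect_equal(s1$age, s0$age, tolerance = 1e-10)
})
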