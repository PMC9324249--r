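test_that("hemispheric analysis recovers the planted group signatures", {
  # one full-size cohort at the default planted effects
  out <- run_cohort_analysis(default_run_config(master_seed = 101L))
  h <- out$hemispheric
  pick <- function(scope, metric, ga, gb) {
    h[h$scope == scope & h$metric == metric & h$group_a == ga &
        h$group_b == gb, ]
  }
  r <- pick("L", "global_efficiency", "LGG", "HC")
  expect_equal(r$direction, 1)
  expect_lt(r$p_raw, 0.05)
  r <- pick("R", "cost", "HGG", "HC")
  expect_equal(r$direction, -1)
  expect_lt(r$p_raw, 0.05)
  r <- pick("R", "degree", "HGG", "HC")
  expect_equal(r$direction, -1)
  expect_lt(r$p_raw, 0.05)
  # left-vs-right within LGG: integration up, locality down
  r <- pick("L_vs_R", "global_efficiency", "LGG", "LGG")
  expect_equal(r$direction, 1); expect_lt(r$p_raw, 0.05)
  r <- pick("L_vs_R", "local_efficiency", "LGG", "LGG")
  expect_equal(r$direction, -1); expect_lt(r$p_raw, 0.05)
  r <- pick("L_vs_R", "clustering", "LGG", "LGG")
  expect_equal(r$direction, -1); expect_lt(r$p_raw, 0.05)

  # structural invariants of the emitted table
  expect_true(all(h$p_fdr >= h$p_raw - 1e-12))
  gated <- !is.na(h$jb_p_a) & !is.na(h$jb_p_b)
  expect_true(all((h$test_used == "t") ==
                    (gated & h$jb_p_a > 0.05 & h$jb_p_b > 0.05)))
})

test_that("null cohorts yield nominal raw-significance rates", {
  p <- unlist(lapply(1:40, function(i) {
    run_cohort_analysis(null_config(2000 + i))$hemispheric$p_raw
  }))
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("lobar analysis confines significance to the affected lobe", {
  focal <- list(
    HC = effect_spec("HC"),
    LGG = effect_spec("LGG", tumor_location = "frontal",
                      delta_left_global = 0.2, delta_local = 0.15)
  )
  weights <- list(LGG = c(frontal = 1, temporal = 1),
                  HGG = c(temporal = 1))
  parc <- make_parcellation(40)
  spec <- cohort_spec(n_per_group = c(HC = 10, LGG = 12, HGG = 2),
                      master_seed = 42L)
  cohort <- generate_cohort(parc, spec, focal, weights)
  man <- cohort_manifest(cohort)
  graphs <- lapply(cohort$subjects, function(s) {
    threshold_graph(connectivity_pipeline(s$data))
  })
  nodal <- lapply(graphs, nodal_metrics)
  lob <- suppressMessages(lobar_analysis(nodal, man, parc))

  # only lobes hosting >= 3 patients in some group are compared
  expect_setequal(unique(lob$lobe), c("frontal", "temporal"))
  expect_equal(sum(lob$lobe == "occipital"), 0)
  # tested nodes belong to the tested lobe (both hemispheres)
  for (lb in unique(lob$lobe)) {
    expect_true(all(lob$node[lob$lobe == lb] %in%
                      parc$roi_id[parc$lobe == lb]))
  }
  sig <- lob[!is.na(lob$p_fdr) & lob$p_fdr < 0.05, ]
  expect_true(all(sig$lobe == "frontal"))
  expect_gt(nrow(sig), 0)
})

test_that("connectograms count group-level significant targets", {
  # all-zero connectivity: empty target set
  zero <- lapply(1:5, function(i) {
    structure(list(z = matrix(0, 6, 6), T_effective = 100L,
                   subject_id = paste0("s", i)), class = "conn_matrix")
  })
  names(zero) <- paste0("s", 1:5)
  man0 <- data.frame(subject_id = names(zero), group = "HC")
  cg0 <- connectogram(zero, man0, seed_roi = 0, group = "HC")
  expect_equal(cg0$count, 0)
  expect_equal(length(cg0$significant_targets), 0)

  # planted homotopic coupling is recovered at n = 20
  parc <- make_parcellation(8)
  spec <- cohort_spec(n_per_group = c(HC = 20, LGG = 2, HGG = 2),
                      base_r_homotopic = 0.6, master_seed = 9L)
  cohort <- generate_cohort(parc, spec)
  hc_ids <- names(cohort$subjects)[vapply(cohort$subjects, `[[`, "",
                                          "group") == "HC"]
  conns <- lapply(cohort$subjects[hc_ids], function(s) {
    connectivity_pipeline(s$data, subject_id = s$subject_id)
  })
  man <- cohort_manifest(cohort)
  hp <- homotopic_pairs(parc)
  seed_roi <- hp[1, "left"]
  cg <- connectogram(conns, man, seed_roi = seed_roi, group = "HC")
  expect_true(hp[1, "right"] %in% cg$significant_targets)

  # identical count distributions compare as null
  expect_equal(connectogram_count_compare(c(3, 3, 3), c(3, 3, 3))$p, 1)
  cmp <- connectogram_count_compare(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(cmp$p, 0.99)
})

test_that("confound screen flags planted dependencies and passes null ones", {
  # identical group structure, so covariates are independent of the
  # metrics by construction and the screen should stay quiet
  out <- run_cohort_analysis(null_config(7, n_roi = 20, n_hc = 10,
                                         n_lgg = 25, n_hgg = 25,
                                         n_volumes = 120))
  sm <- out$scope_means
  man <- out$manifest
  scr <- confound_screen(sm, man)
  expect_true(all(!scr$flagged | is.na(scr$correlation)))
  # metric smuggled in as covariate: perfect correlation
  wb <- sm[sm$scope == "whole_brain", ]
  man2 <- man
  man2$age <- wb$degree[match(man2$subject_id, wb$subject_id)]
  scr2 <- confound_screen(sm, man2, covariates = "age")
  expect_equal(scr2$correlation[scr2$metric == "degree"], 1,
               tolerance = 1e-12)
  expect_true(scr2$flagged[scr2$metric == "degree"])
  man2$age <- -man2$age
  scr3 <- confound_screen(sm, man2, covariates = "age")
  expect_equal(scr3$correlation[scr3$metric == "degree"], -1,
               tolerance = 1e-12)
  # constant covariate reported as undefined
  man2$age <- 50
  scr4 <- confound_screen(sm, man2, covariates = "age")
  expect_true(all(is.na(scr4$correlation)))
  expect_match(scr4$note[1], "undefined")
})
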