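test_that("presets carry the published biological parameter values", {
  ctl <- phenotype_preset("Control")
  expect_equal(unlist(ctl$proliferation[c("target_uM", "width_uM",
                                          "multiplier")]),
               c(target_uM = 200, width_uM = 100, multiplier = 6))
  expect_equal(unlist(ctl$death[c("target_uM", "width_uM", "multiplier")]),
               c(target_uM = 0, width_uM = 50, multiplier = 6))
  # each variation changes exactly one biological parameter from Control
  expect_equal(phenotype_preset("Shift 1")$proliferation$target_uM, 210)
  expect_equal(phenotype_preset("Shift 2")$proliferation$target_uM, 205)
  expect_equal(phenotype_preset("Decrease 1")$proliferation$multiplier, 4)
  expect_equal(phenotype_preset("Decrease 2")$proliferation$multiplier, 2)
  expect_equal(phenotype_preset("Shrink 1")$proliferation$width_uM, 80)
  expect_equal(phenotype_preset("Shrink 2")$proliferation$width_uM, 90)
  expect_equal(phenotype_preset("Increase 1")$death$multiplier, 8)
  expect_equal(phenotype_preset("Increase 2")$death$multiplier, 7)
  expect_equal(phenotype_preset("Expand 1")$death$width_uM, 100)
  expect_equal(phenotype_preset("Expand 2")$death$width_uM, 75)
  expect_error(phenotype_preset("Nope"), "available")
  # run lengths follow the protocol per profile
  expect_identical(default_total_kmcs("Control"), 100L)
  expect_identical(default_total_kmcs("Decrease 1"), 150L)
  expect_identical(default_total_kmcs("Decrease 2"), 250L)
})

test_that("initial state places intact cells on a uniform field", {
  cfg <- run_config("Control", lattice_side = 64, total_kmcs = 1)
  init <- initialize_state(cfg)
  expect_identical(nrow(init$state$agents), 5L)
  expect_true(all(init$state$agents$n_sites == 36L))
  expect_identical(sum(init$state$labels != 0L), 180L)
  expect_true(all(init$field == 0.2))
  expect_silent(validate_lattice_state(init$state))

  one <- initialize_state(run_config("Control", lattice_side = 64,
                                     n_initial_cells = 1, total_kmcs = 1))
  expect_identical(nrow(one$state$agents), 1L)

  expect_error(run_config("Control", lattice_side = 10, total_kmcs = 1),
               "small")
  tight <- run_config("Control", lattice_side = 21, total_kmcs = 1)
  tight$lattice_side <- 12L   # force an over-tight domain past validation
  expect_error(initialize_state(tight), "exceed|overlap")
})

test_that("a smoke run writes every artifact kind and is reproducible", {
  out1 <- tempfile("runA"); out2 <- tempfile("runB")
  cfg <- function(out) run_config("Control", lattice_side = 48,
                                  total_kmcs = 2, seed = 3,
                                  output_dir = out, write_snapshots = TRUE)
  r1 <- run_experiment(cfg(out1))
  r2 <- run_experiment(cfg(out2))

  expect_true(file.exists(file.path(out1, "growth_curve.csv")))
  expect_true(file.exists(file.path(out1, "series.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "snapshot_002000_labels.txt.gz")))
  expect_true(file.exists(file.path(out1,
                                    "snapshot_002000_manifest.json")))

  # identical seeds give byte-identical growth curves
  expect_identical(readLines(file.path(out1, "growth_curve.csv")),
                   readLines(file.path(out2, "growth_curve.csv")))
  expect_identical(r1$curve, r2$curve)
  expect_identical(r1$state$labels, r2$state$labels)

  # curve rows at every sampling interval including MCS 0
  expect_identical(r1$curve$mcs, c(0L, 1000L, 2000L))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the scheduler only changes cell counts through logged events", {
  cfg <- run_config("Control", lattice_side = 48, total_kmcs = 3, seed = 7)
  run <- run_experiment(cfg)
  births <- if (is.null(run$events)) 0L else
    sum(run$events$kind == "proliferate")
  deaths <- if (is.null(run$events)) 0L else sum(run$events$kind == "die")
  n_final <- sum(run$state$agents$type == "live")
  expect_identical(n_final, 5L + births - deaths)
})

test_that("synthetic fixture curves honour their contract", {
  a <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.05,
                             seed = 21)
  b <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.05,
                             seed = 21)
  expect_identical(a, b)
  clean <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0,
                                 origin_kmcs = 12)
  # counts cross 15 exactly at the requested origin
  expect_identical(attr(set_growth_origin(clean), "origin_mcs"), 12000L)
  # noiseless samples lie exactly on the model curve
  t_adj <- (clean$mcs / 1000) - 12
  expect_equal(clean$area_mm2[t_adj >= 0],
               urichards(t_adj[t_adj >= 0], 0.12, 0.005, 0.027, 1.4))
})

test_that("trial aggregation reproduces the reference summary table", {
  tab <- aggregate_fit_table(reference_fits())
  ctl <- tab[tab$profile == "Control", ]
  expect_identical(ctl$n_trials, 3L)
  # three-trial means in the printed 10^-3 mm^2 scaling
  expect_equal(round(ctl$A_e3mm2, 1), 123.1)
  expect_equal(round(ctl$G_mean, 3), 2.687)
  expect_equal(round(ctl$S_mean, 3), 1.393)
  dec <- tab[tab$profile == "Decrease 1", ]
  expect_equal(round(dec$A_e3mm2, 1), 119.8)
  expect_equal(round(dec$S_mean, 3), 1.504)
  # standard deviations stay below 13% of their means for these sets
  expect_lt(ctl$S_sd / ctl$S_mean, 0.13)
  expect_lt(dec$S_sd / dec$S_mean, 0.13)
})
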