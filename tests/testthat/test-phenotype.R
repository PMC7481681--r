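test_that("biological parametrization reproduces target and cutoff exactly", {
  # round-trip for every preset: peak at the target, 1e-6 at target +/- width
  for (nm in preset_names()) {
    prof <- phenotype_preset(nm)
    for (side in c("proliferation", "death")) {
      rs <- prof[[side]]
      expect_equal(response_probability(rs$target_uM, rs), rs$peak_prob_q)
      expect_equal(response_probability(rs$target_uM + rs$width_uM, rs),
                   1e-6, tolerance = 1e-12)
      expect_equal(response_probability(rs$target_uM - rs$width_uM, rs),
                   1e-6, tolerance = 1e-12)
    }
  }
})

test_that("peak probability and Gaussian scale match hand evaluation", {
  rs <- response_spec(0, 50, 6)
  expect_equal(rs$peak_prob_q, 6^(1 / 10000) - 1)
  # high-precision: expm1(log(6)/1e4) = 1.791920e-4 (the first-order
  # approximation log(6)/1e4 = 1.79176e-4 differs in the sixth digit)
  expect_equal(rs$peak_prob_q, 1.791920e-4, tolerance = 1e-6)
  expect_equal(rs$gaussian_sigma_uM,
               50 / sqrt(log(rs$peak_prob_q) - log(1e-6)))
  expect_equal(rs$gaussian_sigma_uM, 21.95, tolerance = 1e-3)
  # half-width offset evaluates the Gaussian directly
  expect_equal(response_probability(25, rs),
               rs$peak_prob_q * exp(-(25 / rs$gaussian_sigma_uM)^2))
  expect_error(response_spec(0, 50, 1.0000001), "cutoff")
})

test_that("population multipliers imply exponential growth over 10 kMCS", {
  # birth-only Markov chain at the target concentration multiplies the
  # population by n over 10000 MCS, within 3 SE
  for (n_mult in c(4, 6)) {
    rs <- response_spec(200, 100, n_mult)
    q <- rs$peak_prob_q
    expect_equal((1 + q)^10000, n_mult, tolerance = 1e-9)
    set.seed(n_mult)
    N0 <- 400
    N <- N0
    for (k in 1:10000) N <- N + stats::rbinom(1, N, q)
    # branching-process variance: Var(N/N0) ~ n(n-1)/N0 for small q
    se <- sqrt(n_mult * (n_mult - 1) / N0)
    expect_lt(abs(N / N0 - n_mult), 3 * se)
  }
})

test_that("decrease-1 vs control multipliers give a 4/6 population ratio", {
  qc <- phenotype_preset("Control")$proliferation$peak_prob_q
  qd <- phenotype_preset("Decrease 1")$proliferation$peak_prob_q
  expect_equal((1 + qd)^10000 / (1 + qc)^10000, 4 / 6, tolerance = 1e-9)
})

test_that("response sampling draws death before proliferation per cell", {
  st <- rect_cell_state(nr = 16, nc = 16, r0 = 6, c0 = 6, h = 6, w = 6)
  f <- oxygen_field(st)

  # effectively-zero responses yield an empty event list
  far <- response_spec(1e6, 1e-3, 6)   # Gaussian underflows at 200 uM
  set.seed(1)
  none <- sample_responses(st, f, phenotype_profile(far, far))
  expect_identical(nrow(none), 0L)

  # certain death: never a proliferation event for the dying cell
  sure <- response_spec(200, 100, 6)
  sure$peak_prob_q <- 1   # force q = 1 to make the death draw deterministic
  sure_death <- phenotype_profile(proliferation = response_spec(200, 100, 6),
                                  death = sure)
  set.seed(1)
  ev <- sample_responses(st, f, sure_death)
  expect_identical(ev$kind, "die")

  # dead cells are never sampled
  stdead <- kill_cell(st, 1L)
  set.seed(1)
  expect_identical(nrow(sample_responses(stdead, f, sure_death)), 0L)

  # empirical event frequency at the target matches the peak probability
  prof <- phenotype_profile(response_spec(200, 100, 6),
                            response_spec(0, 50, 6))
  set.seed(2)
  hits <- 0L
  n <- 2e4
  for (i in 1:n)
    hits <- hits + nrow(sample_responses(st, f, prof))
  q <- prof$proliferation$peak_prob_q
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(hits / n - q), 3 * se)
})

test_that("division cuts along the minor axis and conserves sites", {
  # 2x6 rectangle: major axis along its length, daughters are two 2x3 blocks
  st <- lattice_state({m <- matrix(0L, 12, 12); m[3:4, 3:8] <- 1L; m})
  st2 <- divide_cell(st, 1L)
  expect_identical(sort(st2$agents$n_sites), c(6L, 6L))
  cols1 <- unique(which(st2$labels == 1L, arr.ind = TRUE)[, 2])
  cols2 <- unique(which(st2$labels == 2L, arr.ind = TRUE)[, 2])
  expect_identical(sort(cols1), 3:5)
  expect_identical(sort(cols2), 6:8)

  # 6x6 square (degenerate axes): deterministic 18/18 split
  sq <- rect_cell_state(nr = 14, nc = 14, r0 = 4, c0 = 4, h = 6, w = 6)
  sq2 <- divide_cell(sq, 1L)
  expect_identical(sort(sq2$agents$n_sites), c(18L, 18L))

  # conservation on irregular shapes, and fresh ids
  set.seed(3)
  for (i in 1:20) {
    lab <- matrix(0L, 14, 14)
    pts <- cbind(sample(3:12, 30, TRUE), sample(3:12, 30, TRUE))
    lab[pts] <- 7L
    stx <- lattice_state(lab, types = c("7" = "live"))
    before <- stx$agents$n_sites
    stx2 <- divide_cell(stx, 7L)
    expect_identical(sum(stx2$agents$n_sites), before)
    expect_identical(max(stx2$agents$id), 8L)
    expect_silent(validate_lattice_state(stx2))
  }

  # minimum-size guard
  tiny <- lattice_state({m <- matrix(0L, 6, 6); m[3, 3:4] <- 1L; m})
  skipped <- divide_cell(tiny, 1L)
  expect_true(isTRUE(attr(skipped, "skipped")))
  expect_identical(nrow(skipped$agents), 1L)
})

test_that("killed cells stop respiring and are removed by the dynamics", {
  st <- rect_cell_state(nr = 20, nc = 20, r0 = 8, c0 = 8, h = 6, w = 6)
  stdead <- kill_cell(st, 1L)
  expect_identical(stdead$agents$type, "dead")
  expect_true(all(source_raster(stdead) == 0))
  expect_warning(kill_cell(stdead, 1L), "already dead")

  # reference-run statistic: a lone dead 36-site cell loses all its sites
  # within 5 kMCS in >= 95% of seeded runs
  p <- cpm_params()
  gone <- logical(20)
  for (seed in 1:20) {
    set.seed(seed)
    stx <- kill_cell(rect_cell_state(nr = 20, nc = 20, r0 = 8, c0 = 8,
                                     h = 6, w = 6), 1L)
    for (k in 1:5000) {
      stx <- monte_carlo_step(stx, p)
      if (nrow(stx$agents) == 0L) break
    }
    gone[seed] <- nrow(stx$agents) == 0L
  }
  expect_gte(mean(gone), 0.95)
})
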