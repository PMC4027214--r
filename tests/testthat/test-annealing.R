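tiny_schedule <- function(nsteps = 30, dt = 1, T = 300, k = 30,
                          n_min = 20, avg = 0L) {
  structure(list(
    stages = data.frame(temperature = T, duration_ps = nsteps * dt / 1000,
                        dt_fs = dt, nsteps = as.integer(nsteps),
                        k_noe_start = k, k_noe_end = k,
                        k_hbond_start = 2 * k, k_hbond_end = 2 * k,
                        average = avg),
    n_min = as.integer(n_min), scale = 1), class = "annealing_schedule")
}

small_restraints <- function() {
  calibrate(simulate_noesy(fx_small(), noise_sd = 0, seed = 1))
}

test_that("the default schedule encodes the staged protocol", {
  sch <- default_schedule()
  st <- sch$stages
  # 28 cooling cycles of 25 K at 3 fs, ending at 300 K
  cool <- st$dt_fs == 3
  expect_equal(sum(cool), (1000 - 300) / 25)
  expect_equal(st$temperature[cool], seq(975, 300, by = -25))
  expect_true(all(st$nsteps[cool] == 1000))
  expect_equal(min(st$temperature), 300)
  # initial 300 K / 20 ps equilibration with restraint k = 1
  expect_equal(st$temperature[1], 300)
  expect_equal(st$duration_ps[1], 20)
  expect_equal(st$k_noe_start[1], 1)
  # ramp reaches the final 30 / 60 kcal/mol/A^2
  expect_equal(max(st$k_noe_end), 30)
  expect_equal(max(st$k_hbond_end), 60)
  # 3 ps averaging window and 250 minimization steps
  expect_equal(st$duration_ps[st$average == 1], 3)
  expect_equal(sch$n_min, 250)
  expect_true(all(st$dt_fs <= 3))

  scaled <- scale_schedule(sch, 0.1)
  expect_equal(sum(scaled$stages$nsteps), sum(round(st$nsteps * 0.1)))
  expect_equal(scaled$n_min, 250)
})

test_that("a zero-length schedule with no minimization is the identity", {
  s <- fx_small()
  ens <- run_annealing(s, small_restraints(),
                       tiny_schedule(nsteps = 0, n_min = 0),
                       n_models = 1, seed = 1)
  expect_equal(dnarmd:::coords(ens$models[[1]]), dnarmd:::coords(s),
               tolerance = 1e-12)
})

test_that("annealing is deterministic given the seed", {
  s <- perturb_structure(fx_small(), rms = 0.3, seed = 2)
  r <- small_restraints()
  a <- run_annealing(s, r, tiny_schedule(50), n_models = 2, seed = 5)
  b <- run_annealing(s, r, tiny_schedule(50), n_models = 2, seed = 5)
  expect_identical(dnarmd:::coords(a$models[[2]]), dnarmd:::coords(b$models[[2]]))
  c <- run_annealing(s, r, tiny_schedule(50), n_models = 1, seed = 6)
  expect_false(identical(dnarmd:::coords(a$models[[1]]),
                         dnarmd:::coords(c$models[[1]])))
})

test_that("the thermostat holds the stage temperature", {
  s <- fx_small()
  sch <- tiny_schedule(nsteps = 200, T = 500, n_min = 0)
  ens <- run_annealing(s, small_restraints(), sch, n_models = 1, seed = 3)
  log <- ens$logs[[1]]
  expect_equal(log$T_mean, 500, tolerance = 0.05 * 500)
})

test_that("refinement does not increase the restraint energy (5 seeds)", {
  r <- small_restraints()
  sch <- tiny_schedule(nsteps = 120, n_min = 120)
  drops <- vapply(1:5, function(sd) {
    start <- perturb_structure(fx_small(), rms = 0.7, seed = 40 + sd)
    ens <- run_annealing(start, r, sch, n_models = 1, seed = 40 + sd)
    total_restraint_energy(start, r) -
      total_restraint_energy(ens$models[[1]], r)
  }, numeric(1))
  expect_true(all(drops >= 0))
})

test_that("model selection is lexicographic with a stable tie-break", {
  mk_ens <- function(viol, energy) {
    gt <- fx_small()
    dnarmd:::.new_ensemble(replicate(length(viol), gt, simplify = FALSE),
                           data.frame(model = seq_along(viol),
                                      energy = energy,
                                      restraint_energy = 0,
                                      violations = viol,
                                      seed = seq_along(viol),
                                      aborted = FALSE))
  }
  set.seed(55)
  for (k in 1:5) {
    n <- 20
    viol <- sample(0:4, n, TRUE)
    energy <- round(rnorm(n), 2)
    sel <- select_models(mk_ens(viol, energy), 10)
    oracle <- order(viol, energy, seq_len(n))[1:10]
    expect_equal(sel$info$model, oracle)
  }
  # all identical: first 10 by index
  sel <- select_models(mk_ens(rep(1, 20), rep(5, 20)), 10)
  expect_equal(sel$info$model, 1:10)
  expect_error(select_models(mk_ens(rep(1, 5), rep(1, 5)), 10), "at least")
})

test_that("a single desk-scale run recovers the gap geometry from a jittered start", {
  spec <- fx_gt_spec()
  gt <- fx_gt()
  start <- perturb_structure(gt, rms = 1.0, seed = 7)
  ens <- run_annealing(start, fx_restraints0(),
                       scale_schedule(default_schedule(), 0.1),
                       n_models = 1, seed = 7)
  expect_false(ens$info$aborted)
  m <- ens$models[[1]]
  st <- step_parameters(compute_frames(m, spec$topology))
  expect_lt(max(abs(st$rise[c(5, 7, 9, 11)] - c(5.95, 6.01, 6.34, 5.86))), 0.3)
  expect_lte(restraint_violations(m, fx_restraints0())$n_violations, 5)
  # the full protocol lowered the restraint energy of the jittered start
  expect_lt(total_restraint_energy(m, fx_restraints0()),
            total_restraint_energy(start, fx_restraints0()))
})
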