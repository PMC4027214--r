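rigid_move <- function(s, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rz <- dnarmd:::.rot_z(ang[1] * 180 / pi)
  Rx <- diag(3); Rx[2:3, 2:3] <- matrix(c(cos(ang[2]), -sin(ang[2]),
                                          sin(ang[2]), cos(ang[2])), 2, 2)
  R <- Rz %*% Rx
  t <- runif(3, -20, 20)
  xyz <- dnarmd:::coords(s) %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  dnarmd:::`coords<-`(s, xyz)
}

test_that("pair frames sit in the build plane with unit normals", {
  top <- fx_topology()
  fr <- compute_frames(build_bdna(top), top)
  expect_length(fr, 15)
  expect_equal(fr[[1]]$axes[, 3], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr[[1]]$origin[3], 0, tolerance = 1e-9)
  for (f in fr) {
    expect_equal(crossprod(f$axes), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("step parameters are invariant under global rigid motion", {
  top <- fx_topology()
  gt <- fx_gt()
  st0 <- step_parameters(compute_frames(gt, top))
  for (seed in 1:3) {
    st1 <- step_parameters(compute_frames(rigid_move(gt, seed), top))
    expect_equal(st1$rise, st0$rise, tolerance = 1e-8)
    expect_equal(st1$twist, st0$twist, tolerance = 1e-8)
  }
})

test_that("site unwinding sums per-step twist deficits", {
  top <- build_duplex("ACGT")
  s <- dnarmd:::.build_helix(top, rep(3.4, 3), c(30, 30, 36))
  st <- step_parameters(compute_frames(s, top))
  expect_equal(site_unwinding(st, 1:3), 12, tolerance = 1e-6)

  uniform <- step_parameters(compute_frames(build_bdna(top), top))
  expect_equal(site_unwinding(uniform, 1:3), 0, tolerance = 1e-6)
  expect_error(site_unwinding(uniform, integer(0)), "empty")
})

test_that("optimal superposition matches its definition and a brute-force oracle", {
  gt <- fx_gt()
  expect_equal(superpose_rmsd(gt, gt), 0, tolerance = 1e-10)
  expect_equal(superpose_rmsd(gt, rigid_move(gt, 4)), 0, tolerance = 1e-8)

  # one atom displaced by d among N: RMSD bounded by d/sqrt(N)
  s <- fx_small()
  heavy <- sum(s$element != "H")
  s2 <- s
  xyz <- dnarmd:::coords(s2)
  i <- which(s2$element != "H")[1]
  xyz[i, ] <- xyz[i, ] + c(1, 0, 0)
  s2 <- dnarmd:::`coords<-`(s2, xyz)
  r <- superpose_rmsd(s, s2)
  expect_lte(r, 1 / sqrt(heavy) + 1e-8)
  expect_gt(r, 0.5 / sqrt(heavy))

  # random small structures vs direct minimization over rotations
  set.seed(77)
  for (k in 1:3) {
    a <- fx_small()
    b <- perturb_structure(a, rms = 0.8, seed = 70 + k)
    expect_equal(superpose_rmsd(a, b, "all"),
                 oracle_superpose_rmsd(dnarmd:::coords(a), dnarmd:::coords(b)),
                 tolerance = 1e-4)
  }
})

test_that("ensemble statistics behave on degenerate and satisfied inputs", {
  gt <- fx_gt()
  ens <- dnarmd:::.new_ensemble(
    list(gt, gt, gt),
    data.frame(model = 1:3, energy = 0, restraint_energy = 0,
               violations = 0L, seed = 1:3))
  st <- ensemble_stats(ens, fx_noe0())
  expect_equal(st$pairwise_rmsd_mean, 0, tolerance = 1e-10)
  # restraints were calibrated from this very structure: all satisfied
  expect_equal(st$violations_mean, 0)
  expect_equal(st$violation_rmsd_mean, 0)

  # atom mismatch across models is an error
  bad <- dnarmd:::.new_ensemble(
    list(gt, build_bdna(fx_topology())),
    data.frame(model = 1:2, energy = 0, restraint_energy = 0,
               violations = 0L, seed = 1:2))
  expect_error(ensemble_stats(bad, fx_noe0()), "mismatch")
})

test_that("gap detection separates intercalation steps from B-form steps", {
  st <- step_parameters(compute_frames(fx_gt(), fx_topology()))
  gap_steps <- c(5, 7, 9, 11)
  expect_true(all(st$rise[gap_steps] > 5))
  expect_true(all(st$rise[-gap_steps] < 4.5))
})
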