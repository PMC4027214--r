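test_that("forces are the exact gradient of the energy (finite differences)", {
  s <- perturb_structure(fx_small(), rms = 0.4, seed = 21)
  # a few restraints, including a pseudo-atom group (thymine methyl)
  pk <- simulate_noesy(fx_small(), noise_sd = 0, seed = 1)
  set <- calibrate(pk)[1:25, ]
  sys <- build_ff_system(fx_small(), dnarmd:::.new_restraint_set(as.data.frame(set)))
  ev <- ff_eval(sys, s)
  xyz <- dnarmd:::coords(s)
  h <- 1e-6
  set.seed(31)
  for (k in sample(length(xyz), 20)) {
    xp <- xyz; xp[k] <- xp[k] + h
    xm <- xyz; xm[k] <- xm[k] - h
    num <- (ff_eval(sys, xp)$E_total - ff_eval(sys, xm)$E_total) / (2 * h)
    expect_equal(-ev$forces[k], num, tolerance = 1e-4)
  }
})

test_that("net force vanishes for the translation-invariant field", {
  s <- perturb_structure(fx_small(), rms = 0.6, seed = 22)
  ev <- ff_eval(fx_small_sys(), s)
  net <- colSums(ev$forces)
  mean_f <- mean(sqrt(rowSums(ev$forces^2)))
  expect_lt(max(abs(net)), 1e-6 * max(mean_f, 1))
})

test_that("energy is invariant under rigid motion", {
  s <- fx_small()
  sys <- fx_small_sys()
  e0 <- ff_eval(sys, s)$E_total
  xyz <- dnarmd:::coords(s) %*% t(dnarmd:::.rot_z(33))
  xyz <- sweep(xyz, 2, c(-5, 3, 11))
  e1 <- ff_eval(sys, xyz)$E_total
  expect_equal(e0, e1, tolerance = 1e-9 * max(1, abs(e0)))
})

test_that("the idealized build is a minimum of the covalent terms", {
  ev <- ff_eval(fx_small_sys(), fx_small())
  expect_equal(ev$E_bond, 0, tolerance = 1e-12)
  expect_equal(ev$E_angle, 0, tolerance = 1e-12)
  expect_equal(ev$E_torsion, 0, tolerance = 1e-10)
  expect_equal(ev$E_tether, 0, tolerance = 1e-12)
})

test_that("system assembly covers bonds, charges and exclusions sensibly", {
  gt <- fx_gt()
  sys <- build_ff_system(gt, NULL)
  expect_equal(sys$n_atoms, nrow(gt))
  # phosphates negative, protonated linker amines positive
  expect_true(all(sys$charges[gt$atom == "P"] < 0))
  expect_true(all(sys$charges[gt$resname == "XR" &
                              gt$atom %in% c("NG1", "NG2")] > 0))
  # one O3'-P tether per dinucleotide step per strand
  expect_equal(nrow(sys$tethers), 2 * (15 - 1))
  # bonded pairs are excluded from the nonbonded terms
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_true(all(key(sys$bonds) %in% key(sys$excl)))
})
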