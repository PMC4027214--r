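make_peaks <- function(volumes, ids = NULL, resnames = NULL) {
  n <- length(volumes)
  if (is.null(ids)) ids <- cbind(paste0(1, ":A", seq_len(n)),
                                 paste0(2, ":B", seq_len(n)))
  if (is.null(resnames)) resnames <- cbind(rep("DA", n), rep("DT", n))
  df <- data.frame(proton_i = c("5:H5", ids[, 1]),
                   proton_j = c("5:H6", ids[, 2]),
                   resname_i = c("DC", resnames[, 1]),
                   resname_j = c("DC", resnames[, 2]),
                   volume = c(1, volumes), mixing_time_ms = 150,
                   stringsAsFactors = FALSE)
  structure(df, class = c("noe_peaks", "data.frame"),
            reference_peak = c("5:H5", "5:H6"), cutoff = 5.5, seed = 1L)
}

test_that("calibration maps the reference volume to exactly 2.45 A with 20% bounds", {
  set <- calibrate(make_peaks(1))
  expect_equal(set$r[2], 2.45, tolerance = 1e-12)
  expect_equal(set$lower[2], 1.96, tolerance = 1e-12)
  expect_equal(set$upper[2], 2.94, tolerance = 1e-12)

  # V_ref / 64 -> r doubles (r^-6 arithmetic)
  set64 <- calibrate(make_peaks(1 / 64))
  expect_equal(set64$r[2], 4.90, tolerance = 1e-12)

  # monotone decreasing in volume
  v <- c(0.01, 0.1, 1, 10, 1000)
  r <- calibrate(make_peaks(v))$r[-1]
  expect_true(all(diff(r) < 0))
})

test_that("non-positive volumes are rejected with a warning count", {
  pk <- make_peaks(c(1, -2, 0, 3))
  expect_warning(set <- calibrate(pk), "rejected")
  expect_equal(nrow(set), 3)  # reference + 2 valid
  expect_equal(attr(set, "n_rejected"), 2)
})

test_that("noise-free synthetic peaks round-trip to the true distances", {
  set <- fx_noe0()
  d <- restraint_distances(fx_gt(), set)
  expect_lt(max(abs(d - set$r) / d), 1e-10)
})

test_that("methyl pseudo-atom peaks get a +1 A upper-bound correction", {
  pk <- make_peaks(1, ids = cbind("4:M7", "4:H6"), resnames = cbind("DT", "DT"))
  set <- calibrate(pk)
  expect_equal(set$pseudo_correction[2], 1.0)
  expect_equal(set$upper[2], 1.2 * 2.45 + 1.0, tolerance = 1e-12)
})

test_that("true distances fall inside the 20% bounds under 10% volume noise", {
  gt <- fx_gt()
  truth <- restraint_distances(gt, fx_noe0())
  frac_in <- vapply(1:20, function(s) {
    set <- calibrate(simulate_noesy(gt, noise_sd = 0.1, seed = 100 + s))
    mean(truth >= set$lower & truth <= set$upper)
  }, numeric(1))
  expect_gte(min(frac_in), 0.95)
})

test_that("classification re-derives the five categories and flags bad atoms", {
  top <- fx_topology()
  empty <- calibrate(make_peaks(numeric(0)))[0, ]
  empty <- dnarmd:::.new_restraint_set(as.data.frame(empty))
  expect_equal(unname(classify(empty, top)), rep(0L, 6))

  set <- fx_noe0()
  counts <- classify(set, top)
  # independent brute-force re-derivation of the category of every row
  oracle <- character(nrow(set))
  for (k in seq_len(nrow(set))) {
    li <- set$resname_i[k] == "XR"; lj <- set$resname_j[k] == "XR"
    oracle[k] <- if (li && lj) "drug" else if (li || lj) "drug_dna"
      else if (set$resno_i[k] == set$resno_j[k]) "intraresidue"
      else "sequential"
  }
  expect_equal(unname(counts[c("intraresidue", "sequential", "drug",
                               "drug_dna")]),
               unname(c(sum(oracle == "intraresidue"),
                        sum(oracle == "sequential"),
                        sum(oracle == "drug"), sum(oracle == "drug_dna"))))
  expect_equal(unname(counts["total"]), nrow(set))

  bad <- set[1, ]; bad$resno_i <- 99L
  expect_error(classify(dnarmd:::.new_restraint_set(as.data.frame(bad)), top),
               "99")
})

test_that("hydrogen-bond restraints come two per selected pair", {
  top <- fx_topology()
  hb <- make_hbond_restraints(top, tff1_hbond_pairs())
  expect_equal(nrow(hb), 24)
  expect_true(all(hb$category == "hydrogen_bond"))
  expect_equal(nrow(make_hbond_restraints(top, integer(0))), 0)
  for (k in c(1, 3, 7)) {
    subset <- sample(2:14, k)
    expect_equal(nrow(make_hbond_restraints(top, subset)), 2 * k)
  }
  # targets are near-satisfied on the idealized build
  v <- restraint_violations(build_bdna(top), hb)
  expect_equal(v$n_violations, 0)
})

test_that("the restraint well is flat inside bounds and quadratic outside", {
  r <- data.frame(lower = 2.0, upper = 3.0, type = "noe")
  p <- restraint_params(k_noe = 30, k_hbond = 60)
  expect_equal(restraint_energy(seq(2, 3, by = 0.1), r, p), rep(0, 11))
  expect_equal(restraint_energy(3.1, r, p), 0.30, tolerance = 1e-12)
  expect_equal(restraint_energy(1.9, r, p), 0.30, tolerance = 1e-12)

  rh <- data.frame(lower = 2.0, upper = 3.0, type = "hbond")
  expect_equal(restraint_energy(3.1, rh, p), 0.60, tolerance = 1e-12)

  # skew applies separately above/below
  ps <- restraint_params(skew_upper = 2, skew_lower = 0.5)
  expect_equal(restraint_energy(3.1, r, ps), 0.60, tolerance = 1e-12)
  expect_equal(restraint_energy(1.9, r, ps), 0.15, tolerance = 1e-12)

  # strictly increasing outside the bounds
  up <- restraint_energy(seq(3.01, 4, by = 0.01), r, p)
  expect_true(all(diff(up) > 0))

  # gradient matches finite differences, including at the bounds
  h <- 1e-7
  for (d in c(1.5, 1.999, 2.5, 2.999, 3.001, 3.7)) {
    num <- (restraint_energy(d + h, r, p) - restraint_energy(d - h, r, p)) / (2 * h)
    expect_equal(restraint_gradient(d, r, p), num, tolerance = 1e-5)
  }
  # continuity at the bounds
  expect_equal(restraint_energy(3 + 1e-9, r, p), 0, tolerance = 1e-12)
  expect_equal(restraint_gradient(3 + 1e-9, r, p), 0, tolerance = 1e-6)
})
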