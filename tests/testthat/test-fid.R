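test_that("fluorescence correction maps the assay limits correctly", {
  expect_equal(correct_fluorescence(1000, f0 = 1000, blank_etbr = 50), 0)
  expect_equal(correct_fluorescence(80, f0 = 1000, blank_etbr = 50,
                                    drug_dna_background = 30), 1)
  expect_error(correct_fluorescence(10, f0 = 40, blank_etbr = 50), "exceed")

  # algebraic inverse round trip
  set.seed(8)
  frac <- runif(20, 0, 1)
  f0 <- 1200; blank <- 75
  raw <- blank + (1 - frac) * (f0 - blank)
  expect_equal(correct_fluorescence(raw, f0 = f0, blank_etbr = blank), frac,
               tolerance = 1e-12)
})

test_that("free-ligand mass balance matches the quadratic closed form", {
  # limits
  expect_equal(free_ligand(5e-5, 0, 1e-6), 5e-5)
  expect_equal(free_ligand(0, 1e-5, 1e-6), 0)
  expect_equal(free_ligand(5e-5, 1.67e-5, 1e3), 5e-5, tolerance = 1e-6)

  quad_root <- function(xt, t0, kd, b) {
    bq <- kd + 2 * t0 * b - xt
    (-bq + sqrt(bq^2 + 4 * xt * kd)) / 2
  }
  set.seed(9)
  for (k in 1:50) {
    xt <- runif(1, 0, 2e-4)
    t0 <- runif(1, 0, 5e-5)
    kd <- 10^runif(1, -8, -4)
    b <- runif(1, 0.3, 1.05)
    got <- free_ligand(xt, t0, kd, b)
    expect_equal(got, quad_root(xt, t0, kd, b),
                 tolerance = 1e-8)
    expect_gte(got, 0)
    expect_lte(got, xt)
  }
})

test_that("the bound fraction is monotone with the half-saturation point at K_D", {
  kd <- 9.65e-7; b <- 0.97
  x <- 10^seq(-9, -3.5, length.out = 60)
  f <- b * x / (kd + x)
  expect_true(all(diff(f) > 0))
  expect_equal(b * kd / (kd + kd), b / 2)
})

test_that("noise-free titrations are fit back to the exact K_D", {
  tab <- simulate_fid(titration_spec(noise_sd = 0))
  fit <- fit_kd(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_D - 9.65e-7) / 9.65e-7, 1e-6)
  expect_equal(fit$B, 1, tolerance = 1e-5)
})

test_that("scaling the fractions rescales B but not K_D (free-drug regime)", {
  # with negligible duplex the free concentration equals the total and the
  # saturation model factorizes, so a scaled response only rescales B
  tab <- simulate_fid(titration_spec(noise_sd = 0, amplitude_B = 1,
                                     duplex_total = 0))
  tab2 <- tab
  tab2$fraction <- 0.8 * tab2$fraction
  fit <- fit_kd(tab2, duplex_total = 0)
  expect_lt(abs(fit$K_D - 9.65e-7) / 9.65e-7, 1e-4)
  expect_equal(fit$B, 0.8, tolerance = 1e-4)
})

test_that("degenerate titrations are rejected and bootstrap brackets the truth", {
  tab <- simulate_fid(titration_spec(noise_sd = 0))
  few <- tab[tab$drug_total_M %in% unique(tab$drug_total_M)[1:2], ]
  attr(few, "spec") <- attr(tab, "spec")
  expect_error(fit_kd(few), "4 distinct")

  noisy <- simulate_fid(titration_spec(noise_sd = 0.02, seed = 3))
  fit <- fit_kd(noisy, n_boot = 100, seed = 1)
  expect_length(fit$ci, 2)
  expect_lt(fit$ci[1], 9.65e-7 * 1.5)
  expect_gt(fit$ci[2], 9.65e-7 * 0.5)
})
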