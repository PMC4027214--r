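test_that("ground-truth builder hits the requested gap geometry exactly", {
  st <- step_parameters(compute_frames(fx_gt(), fx_topology()))
  expect_lt(max(abs(st$rise[c(5, 7, 9, 11)] - c(5.95, 6.01, 6.34, 5.86))), 0.05)
  expect_lt(abs(site_unwinding(st, 5:7) - 32), 0.5)
  expect_lt(abs(site_unwinding(st, 9:11) - 28), 0.5)

  # drug-free empty site list: plain B-DNA
  spec0 <- ground_truth_spec(fx_topology(),
                             sites = data.frame(step = integer(),
                                                rise = numeric(),
                                                unwinding = numeric()))
  st0 <- step_parameters(compute_frames(make_ground_truth(spec0), fx_topology()))
  expect_equal(st0$rise, rep(3.4, 14), tolerance = 1e-6)
})

test_that("a single unwound site reduces total twist by exactly its unwinding", {
  top <- build_duplex("GCGCAATTGCGC")
  spec <- ground_truth_spec(top,
                            sites = data.frame(step = 6, rise = 6.0,
                                               unwinding = 10),
                            neighbor_unwinding = FALSE)
  tw_gap <- sum(step_parameters(compute_frames(make_ground_truth(spec), top))$twist)
  tw_ref <- sum(step_parameters(compute_frames(build_bdna(top), top))$twist)
  expect_equal(tw_ref - tw_gap, 10, tolerance = 1e-6)
})

test_that("ground-truth spec validates sites", {
  top <- fx_topology()
  expect_error(ground_truth_spec(top, data.frame(step = c(5, 6), rise = 6,
                                                 unwinding = 10)),
               "overlapping")
  expect_error(ground_truth_spec(top, data.frame(step = 5, rise = 4.2,
                                                 unwinding = 10)),
               "\\[5, 8\\]")
  expect_error(ground_truth_spec(top, data.frame(step = c(5, 5), rise = 6,
                                                 unwinding = 10)),
               "distinct")
})

test_that("NOESY volumes follow the r^-6 law with an exact reference", {
  peaks <- fx_peaks0()
  ref <- attr(peaks, "reference_peak")
  hit <- peaks$proton_i == ref[1] & peaks$proton_j == ref[2] |
         peaks$proton_i == ref[2] & peaks$proton_j == ref[1]
  expect_true(any(hit))
  expect_equal(peaks$volume[hit][1], 1, tolerance = 1e-12)

  # volume ratio of two peaks equals (r2/r1)^6 exactly at zero noise
  set <- fx_noe0()
  d <- restraint_distances(fx_gt(), set)
  expect_equal(peaks$volume[1] / peaks$volume[2], (d[2] / d[1])^6,
               tolerance = 1e-9)

  # no cytosine: cannot reference
  atat <- build_bdna(build_duplex("ATAT"))
  expect_error(simulate_noesy(atat), "cytosine")
})

test_that("peak count equals a brute-force within-cutoff enumeration", {
  gt <- fx_gt()
  peaks <- fx_peaks0()
  # independent enumeration: all H except imino, methyls as centroids
  h <- gt[gt$element == "H", ]
  h <- h[!(h$resname == "DG" & h$atom == "H1"), ]
  h <- h[!(h$resname == "DT" & h$atom == "H3"), ]
  groups <- paste0(h$resno, ":", ifelse(
    h$resname == "DT" & h$atom %in% c("H71", "H72", "H73"), "M7",
    ifelse(h$resname == "XR" & grepl("^HM", h$atom),
           paste0("M", substr(h$atom, 4, 4)), h$atom)))
  cx <- tapply(h$x, groups, mean)
  cy <- tapply(h$y, groups, mean)
  cz <- tapply(h$z, groups, mean)
  n_expected <- sum(dist(cbind(cx, cy, cz)) <= attr(peaks, "cutoff"))
  expect_equal(nrow(peaks), n_expected)
})

test_that("peak simulation is deterministic given the seed", {
  a <- simulate_noesy(fx_gt(), noise_sd = 0.1, seed = 9)
  b <- simulate_noesy(fx_gt(), noise_sd = 0.1, seed = 9)
  c <- simulate_noesy(fx_gt(), noise_sd = 0.1, seed = 10)
  expect_identical(a$volume, b$volume)
  expect_false(identical(a$volume, c$volume))
})

test_that("FID simulation obeys the binding model limits", {
  sp <- titration_spec(noise_sd = 0)
  tab <- simulate_fid(sp)
  expect_equal(tab$fraction[tab$drug_total_M == 0], rep(0, 3))

  # a total chosen so the free concentration equals K_D gives B/2
  xt_half <- sp$true_KD + sp$duplex_total * sp$amplitude_B
  sp2 <- titration_spec(noise_sd = 0, drug_total_grid = c(0, xt_half, 5e-5,
                                                          1e-4), replicates = 1)
  tab2 <- simulate_fid(sp2)
  expect_equal(tab2$fraction[tab2$drug_total_M == xt_half],
               sp2$amplitude_B / 2, tolerance = 1e-9)
})

test_that("the restraint-inventory fixture matches the published category counts", {
  inv <- synthetic_restraint_inventory(fx_gt())
  counts <- classify(inv, fx_topology())
  expect_equal(unname(counts[c("intraresidue", "sequential", "hydrogen_bond",
                               "drug", "drug_dna", "total")]),
               c(357, 153, 24, 79, 56, 669))
  # shipped fixture agrees with the generator
  path <- system.file("extdata", "table1_inventory_synthetic.tsv",
                      package = "dnarmd")
  expect_true(nzchar(path))
  expect_equal(unname(classify(read_restraints(path), fx_topology())),
               unname(counts))
})

test_that("synthetic reference ensemble reproduces the designed spread", {
  ens <- synthetic_reference_ensemble(n_models = 6, seed = 11)
  expect_length(ens, 6)
  # same seed reproduces bit-identically
  ens2 <- synthetic_reference_ensemble(n_models = 6, seed = 11)
  expect_identical(dnarmd:::coords(ens$models[[3]]),
                   dnarmd:::coords(ens2$models[[3]]))
})
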