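test_that("duplex topology pairs and numbers the TFF1 15-mer correctly", {
  top <- build_duplex("AGGTCACGGTGGCCA")
  expect_equal(top$complement, "TGGCCACCGTGACCT")
  expect_equal(top$n, 15)
  expect_equal(nrow(top$pairs), 15)
  expect_equal(top$pairs$comp_res, 30:16)
  expect_setequal(top$residues$resno, 1:30)
  # every residue appears in exactly one pair
  expect_equal(sort(c(top$pairs$sense_res, top$pairs$comp_res)), 1:30)

  tiny <- build_duplex("A")
  expect_equal(tiny$complement, "T")
  expect_equal(nrow(tiny$pairs), 1)

  expect_error(build_duplex("ACGX"), "non-ACGT")
  expect_error(build_duplex(""), "non-empty")
})

test_that("reverse complement is an involution (string oracle)", {
  set.seed(101)
  for (k in 1:25) {
    s <- random_seq(sample(4:20, 1))
    top <- build_duplex(s)
    expect_equal(top$complement, oracle_revcomp(s))
    expect_equal(build_duplex(top$complement)$complement, s)
  }
})

test_that("imino-proton accounting matches the TFF1 duplex and a per-pair oracle", {
  expect_equal(unname(count_imino_protons(fx_topology())), c(3, 10))

  atat <- build_duplex("ATAT")
  expect_equal(unname(count_imino_protons(atat, exclude_terminal = FALSE)),
               c(4, 0))

  set.seed(202)
  for (k in 1:100) {
    s <- random_seq(sample(3:18, 1))
    top <- build_duplex(s)
    for (excl in c(TRUE, FALSE)) {
      got <- count_imino_protons(top, exclude_terminal = excl)
      # brute force: one imino per pair, typed by the pair
      bases <- strsplit(s, "")[[1]]
      if (excl && length(bases) > 2) bases <- bases[-c(1, length(bases))]
      expect_equal(unname(got),
                   c(sum(bases %in% c("A", "T")), sum(bases %in% c("G", "C"))))
    }
  }
})

test_that("idealized B-DNA round-trips rise and twist through the analyzer", {
  s <- build_bdna(fx_topology())
  st <- step_parameters(compute_frames(s, fx_topology()))
  expect_equal(mean(st$twist), 36, tolerance = 1e-9)
  expect_equal(mean(st$rise), 3.4, tolerance = 1e-9)
  expect_equal(max(abs(st$twist - 36)), 0, tolerance = 1e-3)

  # arbitrary twist values in (0, 45] round-trip too
  for (tw in c(5, 20, 33.7, 45)) {
    st2 <- step_parameters(compute_frames(
      build_bdna(build_duplex("GCATGC"), twist_per_step = tw),
      build_duplex("GCATGC")))
    expect_equal(st2$twist, rep(tw, 5), tolerance = 1e-3)
  }

  # 2-bp duplex at twist 0: pair x-axes parallel
  two <- build_bdna(build_duplex("AT"), twist_per_step = 0)
  fr <- compute_frames(two, build_duplex("AT"))
  expect_equal(sum(fr[[1]]$axes[, 1] * fr[[2]]$axes[, 1]), 1, tolerance = 1e-9)
})

test_that("helix end-to-end length follows the geometric closed form", {
  set.seed(303)
  for (k in 1:5) {
    n <- sample(4:12, 1)
    rise <- runif(1, 2.8, 4.2)
    top <- build_duplex(random_seq(n))
    fr <- compute_frames(build_bdna(top, rise_per_step = rise), top)
    len <- sqrt(sum((fr[[n]]$origin - fr[[1]]$origin)^2))
    expect_equal(len, (n - 1) * rise, tolerance = 0.01 * (n - 1) * rise)
  }
})

test_that("ligand placement fills opened gaps and rejects closed ones", {
  # no sites: structure unchanged
  plain <- build_bdna(fx_topology())
  expect_identical(place_ligands(plain, ligand_topology(), list()), plain)

  # placement into a closed (3.4 A) step is a geometry error
  expect_error(place_ligands(plain, ligand_topology(), list(c(5, 7))),
               "opened gap")

  # both sites of the stated world: 2 ligands, ring centroids at the
  # gap midpoints
  gt <- fx_gt()
  expect_equal(sum(tapply(gt$resname, gt$resno, function(r) r[1] == "XR")), 2)
  frames <- compute_frames(gt, fx_topology())
  lig <- ligand_topology()
  ring_centroid <- function(resno, unit) {
    ring_atoms <- unlist(lig$rings[if (unit == "A") 1:3 else 4:6])
    sel <- gt$resno == resno & gt$atom %in% ring_atoms
    colMeans(dnarmd:::coords(gt)[sel, ])
  }
  gaps <- list(c(101, "A", 5), c(101, "B", 7), c(102, "A", 9), c(102, "B", 11))
  for (g in gaps) {
    s <- as.integer(g[3])
    mid <- (frames[[s]]$origin + frames[[s + 1]]$origin) / 2
    cen <- ring_centroid(as.integer(g[1]), g[2])
    expect_lt(sqrt(sum((cen - mid)^2)), 1.0)
  }
})

test_that("ligand topology is two planar named ring systems plus a charged linker", {
  lig <- ligand_topology()
  expect_setequal(names(lig$units), c("A", "B"))
  for (u in c("A", "B")) {
    expect_true(all(paste0("H", c(2, 3, 4, 6, 7, 8), u) %in% lig$units[[u]]))
    expect_true(paste0("CM", u) %in% lig$units[[u]])
  }
  expect_setequal(lig$charged, c("NG1", "NG2"))
  expect_false(anyDuplicated(lig$atoms$atom) > 0)
  # each ring system planar: ring atoms' best plane residuals ~ 0
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  for (ring in lig$rings) {
    sel <- match(ring, lig$atoms$atom)
    sub <- sweep(xyz[sel, ], 2, colMeans(xyz[sel, ]))
    expect_lt(min(svd(sub)$d), 1e-6)
  }
})
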