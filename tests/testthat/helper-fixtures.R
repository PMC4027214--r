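# Shared fixtures, built once per test run.  Everything is generated in
# code from seeds; nothing is downloaded.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_topology <- function() fx("topology", tff1_duplex)

fx_gt_spec <- function() fx("gt_spec", function() tff1_ground_truth_spec(1L))

# the TFF1 ground-truth complex (gaps opened, ligands placed, relaxed)
fx_gt <- function() fx("gt", function() make_ground_truth(fx_gt_spec()))

# noise-free peak list and its calibrated restraints
fx_peaks0 <- function() fx("peaks0", function() {
  simulate_noesy(fx_gt(), noise_sd = 0, seed = 1L)
})

fx_noe0 <- function() fx("noe0", function() calibrate(fx_peaks0()))

fx_hbonds <- function() fx("hbonds", function() {
  make_hbond_restraints(fx_topology(), tff1_hbond_pairs())
})

fx_restraints0 <- function() fx("restraints0", function() {
  dnarmd:::.new_restraint_set(rbind(as.data.frame(fx_noe0()),
                                    as.data.frame(fx_hbonds())))
})

# small 4-bp duplex and force-field system for fast engine tests
fx_small <- function() fx("small", function() {
  build_bdna(build_duplex("ACGT"))
})

fx_small_sys <- function() fx("small_sys", function() {
  build_ff_system(fx_small(), NULL)
})

# independent reverse complement (string oracle, no Biostrings)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force optimal-superposition RMSD by direct minimization over
# Euler angles + translation (independent of the Kabsch implementation)
oracle_superpose_rmsd <- function(x, y) {
  rotmat <- function(a) {
    Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0,
                   -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]),
                   0, sin(a[3]), cos(a[3])), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  x0 <- sweep(x, 2, colMeans(x))
  y0 <- sweep(y, 2, colMeans(y))
  obj <- function(a) sqrt(mean(rowSums((x0 %*% t(rotmat(a)) - y0)^2)))
  best <- Inf
  for (s in list(c(0, 0, 0), c(pi / 2, 0.3, -0.4), c(-1, 2, 1), c(2, -2, 0.5))) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  best
}
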