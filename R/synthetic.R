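# Synthetic-data generators: ground-truth complexes with opened
# intercalation gaps, NOESY peak lists under the r^-6 isolated-spin-pair
# model, FID titrations under the equal-site binding model, and the
# restraint-inventory fixture.  Everything is seeded and deterministic.

#' Ground-truth complex specification
#'
#' Describes the "stated world" from which synthetic data are generated:
#' which dinucleotide steps carry intercalation gaps (enlarged rise,
#' local unwinding), whether unwinding spills into the +-1 neighbour
#' steps, and where the two ring systems of each ligand sit.
#'
#' @param topology a `duplex_topology`
#' @param sites data.frame with columns `step` (gap between pairs step and
#'   step+1), `rise` (target rise in A, within 5-8), `unwinding` (local
#'   twist deficit in degrees at that step)
#' @param ligand_sites list of 2-vectors of step indices, one per ligand
#'   molecule (or empty list for a drug-free duplex)
#' @param neighbor_unwinding if TRUE (default), each gap additionally
#'   unwinds its +-1 neighbour steps by `neighbor_deg`
#' @param neighbor_deg neighbour-step unwinding in degrees (4.5)
#' @param seed integer seed recorded with the spec
#' @return object of class `ground_truth_spec`
#' @export
ground_truth_spec <- function(topology, sites,
                              ligand_sites = list(),
                              neighbor_unwinding = TRUE,
                              neighbor_deg = 4.5,
                              seed = 1L) {
  stopifnot(inherits(topology, "duplex_topology"))
  if (nrow(sites) > 0) {
    stopifnot(all(c("step", "rise", "unwinding") %in% names(sites)))
    if (anyDuplicated(sites$step)) stop("intercalation steps must be distinct")
    if (any(diff(sort(sites$step)) < 2)) {
      stop("overlapping intercalation sites: adjacent steps share a base pair")
    }
    if (any(sites$rise < 5 | sites$rise > 8)) {
      stop("target rise must lie in [5, 8] Angstrom")
    }
    if (any(sites$step < 1 | sites$step > topology$n - 1)) {
      stop("site step outside the duplex")
    }
  }
  structure(list(topology = topology, sites = sites,
                 ligand_sites = ligand_sites,
                 neighbor_unwinding = neighbor_unwinding,
                 neighbor_deg = neighbor_deg, seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' The TFF1-ERE / bis-intercalator ground truth
#'
#' The default stated world: gaps at the four intercalation steps C5pA6,
#' C7pG8, G9pT10 and G11pG12 with rises 5.95, 6.01, 6.34 and 5.86 A, gap
#' unwinding chosen so that (with the 4.5 degree neighbour rule) the two
#' 3-step binding sites unwind by 32 and 28 degrees in total, and the two
#' ligands bis-intercalated at steps (5, 7) and (9, 11).
#' @param seed integer seed
#' @return a `ground_truth_spec`
#' @export
tff1_ground_truth_spec <- function(seed = 1L) {
  ground_truth_spec(
    tff1_duplex(),
    sites = data.frame(step = c(5, 7, 9, 11),
                       rise = c(5.95, 6.01, 6.34, 5.86),
                       unwinding = c(11.5, 11.5, 9.5, 9.5)),
    ligand_sites = list(XR1 = c(5, 7), XR2 = c(9, 11)),
    seed = seed)
}

#' Build the ground-truth complex structure
#'
#' Constructs an idealized B-DNA duplex, opens the specified intercalation
#' gaps (enlarged rise, reduced twist, optional +-1 neighbour unwinding)
#' and rigid-places the ligand ring systems into the gaps. Analyzer-
#' measured rises and twists match the spec by construction.
#'
#' @param spec a [ground_truth_spec()]
#' @return a `dna_structure`
#' @examples
#' gt <- make_ground_truth(tff1_ground_truth_spec())
#' step_parameters(compute_frames(gt))$rise[c(5, 7, 9, 11)]
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  top <- spec$topology
  n <- top$n
  rises <- rep(3.4, n - 1)
  unwind <- rep(0, n - 1)
  if (nrow(spec$sites) > 0) {
    for (k in seq_len(nrow(spec$sites))) {
      s <- spec$sites$step[k]
      rises[s] <- spec$sites$rise[k]
      unwind[s] <- unwind[s] + spec$sites$unwinding[k]
      if (spec$neighbor_unwinding) {
        for (nb in c(s - 1, s + 1)) {
          if (nb >= 1 && nb <= n - 1 && !(nb %in% spec$sites$step)) {
            unwind[nb] <- unwind[nb] + spec$neighbor_deg
          }
        }
      }
    }
  }
  s <- .build_helix(top, rises, 36 - unwind)
  if (length(spec$ligand_sites) > 0) {
    s <- place_ligands(s, ligand_topology(), spec$ligand_sites)
  }
  # Relax construction strain (linker conformation, backbone contacts at
  # the opened gaps) while freezing the atoms that define the stated
  # geometry: DNA base rings and the rigid-placed ligand ring systems.
  # Analyzer-measured rises/twists are untouched by construction.
  if (nrow(spec$sites) > 0) {
    s <- .relax_structure(s, .geometry_defining_atoms(s), n_steps = 400)
  }
  s
}

# row indices of atoms that define the measured geometry: DNA base ring
# atoms (used by the frame fitter) and ligand ring-system atoms
.geometry_defining_atoms <- function(structure) {
  ids <- atom_ids(structure)
  fixed <- character(0)
  top <- attr(structure, "topology")
  for (rn in unique(structure$resno[structure$resname != "XR"])) {
    base <- residue_base(top, rn)
    fixed <- c(fixed, paste0(rn, ":", .residue_template(base)$base_atoms))
  }
  lig <- .ligand_template()
  for (rn in unique(structure$resno[structure$resname == "XR"])) {
    fixed <- c(fixed, paste0(rn, ":", c(lig$units$A, lig$units$B)))
  }
  which(ids %in% fixed)
}

# steepest-descent relaxation of the unfixed atoms under the bare force
# field (no restraints); used to remove construction strain
.relax_structure <- function(structure, fixed, n_steps = 400) {
  sys <- build_ff_system(structure, NULL)
  xyz <- coords(structure)
  ev <- engine_eval(sys, xyz, 0, 0)
  E <- ev$E_total
  alpha <- 0.01
  for (it in seq_len(n_steps)) {
    f <- ev$forces
    f[fixed, ] <- 0
    fmax <- max(abs(f))
    if (fmax < 1e-4) break
    xtry <- xyz + (alpha / max(fmax, 1)) * f
    evt <- engine_eval(sys, xtry, 0, 0)
    if (is.finite(evt$E_total) && evt$E_total < E) {
      xyz <- xtry; ev <- evt; E <- evt$E_total; alpha <- alpha * 1.2
    } else {
      alpha <- alpha * 0.5
    }
  }
  coords(structure) <- xyz
  structure
}

# ---- NOESY simulation -------------------------------------------------------

# observable proton table: non-exchangeable H, with methyls collapsed to
# pseudo-atom centroids; returns data.frame(id, resno, resname, atom, x, y, z)
.proton_table <- function(structure) {
  h <- structure[structure$element == "H", ]
  # drop exchangeable imino protons
  h <- h[!(h$resname == "DG" & h$atom == "H1"), ]
  h <- h[!(h$resname == "DT" & h$atom == "H3"), ]
  pseudo <- list(list(resname = "DT", name = "M7"),
                 list(resname = "XR", name = "MA"),
                 list(resname = "XR", name = "MB"))
  keep <- rep(TRUE, nrow(h))
  extra <- list()
  for (p in pseudo) {
    members <- .pseudo_members(p$resname, p$name)
    for (rn in unique(h$resno[h$resname == p$resname])) {
      sel <- h$resno == rn & h$resname == p$resname & h$atom %in% members
      if (sum(sel) == 3) {
        keep[sel] <- FALSE
        extra[[length(extra) + 1]] <- data.frame(
          resno = rn, resname = p$resname, atom = p$name,
          x = mean(h$x[sel]), y = mean(h$y[sel]), z = mean(h$z[sel]),
          stringsAsFactors = FALSE)
      }
    }
  }
  h <- h[keep, c("resno", "resname", "atom", "x", "y", "z")]
  if (length(extra)) h <- rbind(h, do.call(rbind, extra))
  h$id <- paste0(h$resno, ":", h$atom)
  rownames(h) <- NULL
  h
}

#' Simulate a NOESY peak list
#'
#' Generates one crosspeak per proton pair closer than `cutoff`, with
#' volume C r^-6 scaled so that the cytosine H5-H6 reference distance
#' (2.45 A) has unit mean volume, under multiplicative log-normal noise:
#' V = (2.45/r)^6 * exp(eps), eps ~ Normal(0, noise_sd). Methyl groups are
#' observed as pseudo-atom centroids; exchangeable imino protons are not
#' observed (D2O convention). The reference peak is always emitted.
#'
#' @param structure a `dna_structure` containing at least one cytosine
#' @param cutoff NOE observation cutoff in Angstrom (default 5.5)
#' @param noise_sd relative (log-scale) volume noise (default 0.1)
#' @param seed integer seed
#' @param mixing_time_ms nominal mixing time recorded with the peaks
#' @return object of class `noe_peaks`: data.frame `proton_i`, `proton_j`,
#'   `resname_i`, `resname_j`, `volume`, `mixing_time_ms`, with attributes
#'   `reference_peak`, `cutoff`, `seed`
#' @export
simulate_noesy <- function(structure, cutoff = 5.5, noise_sd = 0.1,
                           seed = 1L, mixing_time_ms = 150) {
  pt <- .proton_table(structure)
  cyt <- pt[pt$resname == "DC" & pt$atom %in% c("H5", "H6"), ]
  if (nrow(cyt) < 2) stop("structure contains no cytosine H5/H6 reference")
  ref_res <- min(cyt$resno[duplicated(cyt$resno) |
                           rev(duplicated(rev(cyt$resno)))])
  ref <- c(paste0(ref_res, ":H5"), paste0(ref_res, ":H6"))
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  r <- dm[pairs]
  set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(r), 0, noise_sd) else numeric(length(r))
  out <- data.frame(proton_i = pt$id[i], proton_j = pt$id[j],
                    resname_i = pt$resname[i], resname_j = pt$resname[j],
                    volume = (2.45 / r)^6 * exp(eps),
                    mixing_time_ms = mixing_time_ms,
                    stringsAsFactors = FALSE)
  structure(out, class = c("noe_peaks", "data.frame"),
            reference_peak = ref, cutoff = cutoff, seed = as.integer(seed),
            noise_sd = noise_sd)
}

# ---- FID titration simulation ----------------------------------------------

#' FID titration specification
#'
#' The fluorescent-intercalator-displacement assay world: a fixed duplex
#' concentration titrated with drug, read out as fraction bound under the
#' equal-site model f = B [X] / (K_D + [X]) with 2:1 drug:duplex
#' stoichiometry. Defaults follow the assay conditions: 16.7 uM duplex,
#' drug 0-100 uM (13 points), three replicates.
#'
#' @param true_KD dissociation constant in molar (default 9.65e-7)
#' @param amplitude_B saturation amplitude (default 1)
#' @param duplex_total duplex concentration in molar (16.7e-6)
#' @param drug_total_grid total drug concentrations in molar
#' @param noise_sd replicate noise, sd relative to B (default 0.02)
#' @param replicates samples per concentration (3)
#' @param seed integer seed
#' @return object of class `titration_spec`
#' @export
titration_spec <- function(true_KD = 9.65e-7, amplitude_B = 1,
                           duplex_total = 16.7e-6,
                           drug_total_grid = seq(0, 100e-6, length.out = 13),
                           noise_sd = 0.02, replicates = 3, seed = 1L) {
  stopifnot(true_KD > 0, amplitude_B > 0, duplex_total >= 0,
            all(drug_total_grid >= 0), noise_sd >= 0, replicates >= 1)
  structure(list(true_KD = true_KD, amplitude_B = amplitude_B,
                 duplex_total = duplex_total,
                 drug_total_grid = drug_total_grid,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "titration_spec")
}

#' Simulate an FID titration table
#'
#' For each total drug concentration the free concentration is solved from
#' the 2:1 mass balance ([free_ligand()]), the true bound fraction is
#' B [X] / (K_D + [X]), and i.i.d. Normal(0, noise_sd * B) noise is added
#' per replicate.
#'
#' @param spec a [titration_spec()]
#' @return object of class `titration_table`: data.frame `drug_total_M`,
#'   `replicate`, `fraction`, with the spec stored as attribute
#' @export
simulate_fid <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  free <- vapply(spec$drug_total_grid, free_ligand,
                 numeric(1),
                 duplex_total = spec$duplex_total,
                 K_D = spec$true_KD, B = spec$amplitude_B)
  f_true <- spec$amplitude_B * free / (spec$true_KD + free)
  set.seed(spec$seed)
  rows <- expand.grid(replicate = seq_len(spec$replicates),
                      idx = seq_along(spec$drug_total_grid))
  noise <- if (spec$noise_sd > 0) {
    stats::rnorm(nrow(rows), 0, spec$noise_sd * spec$amplitude_B)
  } else rep(0, nrow(rows))
  out <- data.frame(drug_total_M = spec$drug_total_grid[rows$idx],
                    replicate = rows$replicate,
                    fraction = f_true[rows$idx] + noise)
  out <- out[order(out$drug_total_M, out$replicate), ]
  rownames(out) <- NULL
  structure(out, class = c("titration_table", "data.frame"), spec = spec)
}

# ---- reference-style fixtures ----------------------------------------------

#' Synthetic restraint inventory matching the published Table-1 counts
#'
#' Builds a concrete restraint set over the TFF1 ground-truth complex with
#' exactly the published category inventory: 357 intraresidue, 153
#' sequential, 24 hydrogen-bond, 79 drug and 56 drug-DNA restraints (669
#' total). Pairs are selected deterministically (closest distances first)
#' from the synthetic complex; this is a synthetic stand-in for the
#' unpublished experimental restraint list, suitable for exercising the
#' classification and bookkeeping machinery.
#'
#' @param structure optional pre-built ground-truth complex
#' @return a `restraint_set` of 669 restraints
#' @export
synthetic_restraint_inventory <- function(structure = NULL) {
  if (is.null(structure)) structure <- make_ground_truth(tff1_ground_truth_spec())
  pt <- .proton_table(structure)
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[pairs]
  i <- pairs[, 1]; j <- pairs[, 2]
  cat_v <- .category_for(pt$resname[i], pt$resno[i], pt$resname[j], pt$resno[j])
  take <- function(category, k, cut = 7.0) {
    sel <- which(cat_v == category & d <= cut)
    sel <- sel[order(d[sel], pt$id[i[sel]], pt$id[j[sel]])]
    if (length(sel) < k) stop("not enough candidate pairs for ", category)
    sel[seq_len(k)]
  }
  # the drug category needs the wider net: within one ring system the
  # proton pairs span the full tricyclic (~9 A)
  sel <- c(take("intraresidue", 357), take("sequential", 153),
           take("drug", 79, cut = 10.0), take("drug_dna", 56))
  r <- d[sel]
  corr <- mapply(.pseudo_correction, pt$resname[i[sel]], pt$atom[i[sel]]) +
          mapply(.pseudo_correction, pt$resname[j[sel]], pt$atom[j[sel]])
  noe <- data.frame(
    resno_i = pt$resno[i[sel]], atom_i = pt$atom[i[sel]],
    resname_i = pt$resname[i[sel]],
    resno_j = pt$resno[j[sel]], atom_j = pt$atom[j[sel]],
    resname_j = pt$resname[j[sel]],
    r = r, lower = 0.8 * r, upper = 1.2 * r + corr,
    pseudo_correction = as.numeric(corr),
    category = cat_v[sel], type = "noe", stringsAsFactors = FALSE)
  hb <- make_hbond_restraints(attr(structure, "topology"), tff1_hbond_pairs())
  .new_restraint_set(rbind(noe, as.data.frame(hb)))
}

#' Synthetic stand-in for the deposited 10-model ensemble
#'
#' Constructs a 10-model ensemble around the TFF1 ground-truth complex by
#' jittering each model with isotropic Gaussian noise whose per-coordinate
#' sd is fixed a priori at `mean_pairwise_rmsd / sqrt(6)`, the closed-form
#' value for which the expected pairwise heavy-atom RMSD between two
#' models equals `mean_pairwise_rmsd` (0.78 A, the published ensemble
#' spread). This is a labelled synthetic surrogate for the deposited
#' ensemble, used to exercise the ensemble-analysis machinery offline; it
#' reproduces the printed gap rises, site unwinding and ensemble spread by
#' construction, not by measurement.
#'
#' @param n_models number of models (10)
#' @param seed integer seed
#' @param mean_pairwise_rmsd target expected pairwise RMSD in Angstrom
#' @return a `dna_ensemble`
#' @export
synthetic_reference_ensemble <- function(n_models = 10, seed = 1L,
                                         mean_pairwise_rmsd = 0.78) {
  gt <- make_ground_truth(tff1_ground_truth_spec())
  # per-atom RMS displacement = sqrt(3) * sigma_coord = target / sqrt(2)
  rms <- mean_pairwise_rmsd / sqrt(2)
  models <- lapply(seq_len(n_models), function(m) {
    s <- perturb_structure(gt, rms = rms, seed = seed + m - 1L)
    attr(s, "model_id") <- m
    s
  })
  .new_ensemble(models,
                info = data.frame(model = seq_len(n_models),
                                  energy = NA_real_,
                                  restraint_energy = NA_real_,
                                  violations = NA_integer_,
                                  seed = seed + seq_len(n_models) - 1L))
}
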