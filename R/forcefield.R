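# Simplified CHARMM-like surrogate force field.
#
# Ideal bond lengths, angles and improper/ring torsions are measured from
# the package's own idealized residue templates (self-parameterizing), so
# the unperturbed build is an exact minimum of the covalent terms.  The
# inter-residue O3'-P linkage is a flat-bottomed tether (1.5-4.5 A): the
# rigid-residue builder has no backbone torsional degrees of freedom, and
# the soft tether stands in for the torsional slack with which real DNA
# absorbs intercalation-induced backbone stretch.  Nonbonded terms are a
# soft quartic repulsion plus distance-dependent-dielectric electrostatics
# (eps(r) = r) on the formally charged centres (phosphates, protonated
# linker amines).

.FF_K_BOND <- 300      # kcal/mol/A^2
.FF_K_ANGLE <- 50      # kcal/mol/rad^2
.FF_K_TORSION <- 30    # kcal/mol/rad^2
.FF_K_TETHER <- 50     # kcal/mol/A^2 outside the flat region
.FF_TETHER_LO <- 1.5
.FF_TETHER_HI <- 4.5
.FF_K_REP <- 4         # kcal/mol/A^4 soft quartic
.FF_REP_SCALE <- 0.8
.FF_COULOMB_CUTOFF <- 12
.FF_ELEMENT_RADII <- c(H = 1.0, C = 1.5, N = 1.4, O = 1.3, P = 1.8)
# Hydrogen mass is repartitioned to 3x its physical value so that the
# stated 3 fs cooling timestep integrates stably without bond constraints
# (X-H stretch period scales with sqrt(m)); configurational equilibrium
# properties are independent of the masses.
.FF_ELEMENT_MASS <- c(H = 3.024, C = 12.011, N = 14.007, O = 15.999,
                      P = 30.974)
# Effective phosphate charge under Manning counterion condensation (~76 %
# neutralization), the standard choice for implicit-counterion DNA
# calculations; the protonated linker amines keep their formal +1 scaled
# by the same dielectric pragmatism.
.FF_CHARGE_P <- -0.24
.FF_CHARGE_AMINE <- 0.5

#' Force-field parameter summary
#'
#' Returns the parameters of the simplified force field used by the
#' annealing engine (force constants, tether bounds, repulsion radii,
#' charges). Mostly useful for documentation and reports.
#' @return named list
#' @export
forcefield_params <- function() {
  list(k_bond = .FF_K_BOND, k_angle = .FF_K_ANGLE,
       k_torsion = .FF_K_TORSION, k_tether = .FF_K_TETHER,
       tether = c(.FF_TETHER_LO, .FF_TETHER_HI),
       k_repulsion = .FF_K_REP, repulsion_scale = .FF_REP_SCALE,
       element_radii = .FF_ELEMENT_RADII,
       charge_phosphate = .FF_CHARGE_P, charge_amine = .FF_CHARGE_AMINE,
       dielectric = "distance-dependent, eps(r) = r",
       coulomb_cutoff = .FF_COULOMB_CUTOFF)
}

# per-residue-type covalent parameter tables measured from the template
.ff_type_table <- function(key) {
  .cached(paste0("fftype_", key), function() {
    tpl <- if (key == "XR") .ligand_template() else .residue_template(key)
    at <- tpl$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    rownames(xyz) <- at$atom
    b <- tpl$bonds
    bond_r0 <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                             xyz[b[, 2], , drop = FALSE])^2))
    # adjacency
    nbrs <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
    nbrs <- lapply(nbrs, function(x) sort(unique(x)))
    angles <- list()
    for (c_at in names(nbrs)) {
      nb <- nbrs[[c_at]]
      if (length(nb) < 2) next
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb))) {
        angles[[length(angles) + 1]] <-
          c(cmb[1, k], c_at, cmb[2, k],
            .angle3(xyz[cmb[1, k], ], xyz[c_at, ], xyz[cmb[2, k], ]))
      }
    }
    tors <- list()
    # ring torsions (planarity / pucker memory)
    for (ring in tpl$rings) {
      nr <- length(ring)
      for (k in seq_len(nr)) {
        q <- ring[((k - 1 + 0:3) %% nr) + 1]
        tors[[length(tors) + 1]] <-
          c(q, .dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ]))
      }
    }
    # centre impropers (substituent planarity, sp3 chirality)
    for (c_at in names(nbrs)) {
      nb <- nbrs[[c_at]]
      if (length(nb) < 3) next
      q <- c(nb[1], nb[2], c_at, nb[3])
      tors[[length(tors) + 1]] <-
        c(q, .dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ]))
    }
    list(
      bonds = data.frame(a1 = b[, 1], a2 = b[, 2], r0 = bond_r0,
                         stringsAsFactors = FALSE),
      angles = data.frame(a1 = vapply(angles, `[`, "", 1),
                          a2 = vapply(angles, `[`, "", 2),
                          a3 = vapply(angles, `[`, "", 3),
                          t0 = as.numeric(vapply(angles, `[`, "", 4)),
                          stringsAsFactors = FALSE),
      torsions = data.frame(a1 = vapply(tors, `[`, "", 1),
                            a2 = vapply(tors, `[`, "", 2),
                            a3 = vapply(tors, `[`, "", 3),
                            a4 = vapply(tors, `[`, "", 4),
                            p0 = as.numeric(vapply(tors, `[`, "", 5)),
                            stringsAsFactors = FALSE))
  })
}

# covalent geometry terms of a whole structure (global 1-based indices)
.ff_geometry_terms <- function(structure) {
  ids <- atom_ids(structure)
  resnos <- unique(structure$resno)
  bonds <- list(); angles <- list(); torsions <- list()
  for (rn in resnos) {
    rname <- structure$resname[structure$resno == rn][1]
    key <- if (rname == "XR") "XR" else substr(rname, 2, 2)
    tt <- .ff_type_table(key)
    idx <- function(a) match(paste0(rn, ":", a), ids)
    bonds[[length(bonds) + 1]] <-
      cbind(idx(tt$bonds$a1), idx(tt$bonds$a2), tt$bonds$r0)
    angles[[length(angles) + 1]] <-
      cbind(idx(tt$angles$a1), idx(tt$angles$a2), idx(tt$angles$a3),
            tt$angles$t0)
    torsions[[length(torsions) + 1]] <-
      cbind(idx(tt$torsions$a1), idx(tt$torsions$a2), idx(tt$torsions$a3),
            idx(tt$torsions$a4), tt$torsions$p0)
  }
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles)
  torsions <- do.call(rbind, torsions)
  stopifnot(!anyNA(bonds), !anyNA(angles), !anyNA(torsions))

  # inter-residue O3'(i) - P(i+1) tethers along each strand (5'->3')
  top <- attr(structure, "topology")
  teth <- list()
  if (!is.null(top)) {
    strands <- list(seq_len(top$n), top$n + seq_len(top$n))
    for (st in strands) {
      for (k in seq_len(length(st) - 1)) {
        i <- match(paste0(st[k], ":O3'"), ids)
        j <- match(paste0(st[k + 1], ":P"), ids)
        if (!is.na(i) && !is.na(j)) teth[[length(teth) + 1]] <- c(i, j)
      }
    }
  }
  tethers <- if (length(teth)) do.call(rbind, teth) else
    matrix(integer(), 0, 2)

  list(bonds = bonds[, 1:2, drop = FALSE], bond_r0 = bonds[, 3],
       bond_k = rep(.FF_K_BOND, nrow(bonds)),
       tethers = tethers,
       tether_lo = rep(.FF_TETHER_LO, nrow(tethers)),
       tether_hi = rep(.FF_TETHER_HI, nrow(tethers)),
       tether_k = rep(.FF_K_TETHER, nrow(tethers)),
       angles = angles[, 1:3, drop = FALSE], angle_t0 = angles[, 4],
       angle_k = rep(.FF_K_ANGLE, nrow(angles)),
       torsions = torsions[, 1:4, drop = FALSE], torsion_p0 = torsions[, 5],
       torsion_k = rep(.FF_K_TORSION, nrow(torsions)))
}

# exclusions: all pairs within 3 bonds of each other (1-2, 1-3, 1-4)
.ff_exclusions <- function(n_atoms, bond_idx) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bond_idx))) {
    i <- bond_idx[k, 1]; j <- bond_idx[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  excl <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) {
    lvl1 <- adj[[i]]
    lvl2 <- unique(unlist(adj[lvl1]))
    lvl3 <- unique(unlist(adj[lvl2]))
    near <- setdiff(unique(c(lvl1, lvl2, lvl3)), i)
    near <- near[near > i]
    if (length(near)) excl[[i]] <- cbind(i, near)
  }
  out <- do.call(rbind, excl)
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

#' Build the annealing-engine system description for a structure
#'
#' Assembles every force-field term (bonds, angles, impropers, tethers,
#' nonbonded parameters, charges, masses) plus the distance restraints in
#' the flattened arrays consumed by the compiled engine.
#'
#' @param structure a `dna_structure`
#' @param restraints a `restraint_set` (may be empty)
#' @return a list (class `ff_system`) understood by [run_annealing()]
#' @export
build_ff_system <- function(structure, restraints = NULL) {
  geo <- .ff_geometry_terms(structure)
  n <- nrow(structure)
  all_bonds <- rbind(geo$bonds, geo$tethers)
  excl <- .ff_exclusions(n, all_bonds)

  charges <- numeric(n)
  charges[structure$atom == "P"] <- .FF_CHARGE_P
  charges[structure$resname == "XR" &
          structure$atom %in% c("NG1", "NG2")] <- .FF_CHARGE_AMINE

  radii <- unname(.FF_ELEMENT_RADII[structure$element])
  mass <- unname(.FF_ELEMENT_MASS[structure$element])
  stopifnot(!anyNA(radii), !anyNA(mass))

  ri_idx <- list(); rj_idx <- list()
  r_tgt <- numeric(0); r_hb <- integer(0)
  if (!is.null(restraints) && nrow(restraints) > 0) {
    for (k in seq_len(nrow(restraints))) {
      ri_idx[[k]] <- .restraint_rows(structure, restraints$resno_i[k],
                                     restraints$atom_i[k],
                                     restraints$resname_i[k])
      rj_idx[[k]] <- .restraint_rows(structure, restraints$resno_j[k],
                                     restraints$atom_j[k],
                                     restraints$resname_j[k])
    }
    r_tgt <- restraints$r
    r_hb <- as.integer(restraints$type == "hbond")
  }
  ri_len <- vapply(ri_idx, length, integer(1))
  rj_len <- vapply(rj_idx, length, integer(1))

  structure(list(
    n_atoms = n,
    bonds = geo$bonds, bond_r0 = geo$bond_r0, bond_k = geo$bond_k,
    tethers = geo$tethers, tether_lo = geo$tether_lo,
    tether_hi = geo$tether_hi, tether_k = geo$tether_k,
    angles = geo$angles, angle_t0 = geo$angle_t0, angle_k = geo$angle_k,
    torsions = geo$torsions, torsion_p0 = geo$torsion_p0,
    torsion_k = geo$torsion_k,
    excl = excl, radii = radii, charges = charges, mass = mass,
    k_rep = .FF_K_REP, rep_scale = .FF_REP_SCALE,
    coulomb_cutoff = .FF_COULOMB_CUTOFF,
    rest_i_ptr = c(0L, cumsum(ri_len)), rest_i_idx = unlist(ri_idx),
    rest_j_ptr = c(0L, cumsum(rj_len)), rest_j_idx = unlist(rj_idx),
    rest_r = r_tgt, rest_hbond = r_hb,
    skew_upper = 1, skew_lower = 1),
    class = "ff_system")
}

#' Evaluate force-field energy and forces
#'
#' Thin wrapper around the compiled engine's single-point evaluation;
#' used for tests (translation invariance, finite-difference gradients)
#' and reporting.
#'
#' @param sys an `ff_system` from [build_ff_system()]
#' @param xyz coordinates (n x 3) or a `dna_structure`
#' @param k_noe,k_hbond current restraint force constants (kcal/mol/A^2)
#' @return list with per-term energies (`E_*`), `E_total`, and `forces`
#'   (n x 3, kcal/mol/A)
#' @export
ff_eval <- function(sys, xyz, k_noe = 30, k_hbond = 60) {
  if (inherits(xyz, "dna_structure")) xyz <- coords(xyz)
  engine_eval(sys, xyz, k_noe, k_hbond)
}
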