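# Structure container: a data.frame with one row per atom and columns
#   resno, resname, atom, element, chain, x, y, z
# plus attributes `model_id` and `topology`.  DNA residues are DA/DC/DG/DT
# (sense chain "A", complement chain "B"); ligand molecules are resname
# "XR" with resno 101, 102 on chains "C", "D".

.new_structure <- function(df, topology, model_id = 1L) {
  rownames(df) <- NULL
  structure(df, class = c("dna_structure", "data.frame"),
            topology = topology, model_id = model_id)
}

#' @export
print.dna_structure <- function(x, ...) {
  cat("Structure: ", nrow(x), " atoms, ",
      length(unique(x$resno[x$resname != "XR"])), " nucleotides, ",
      sum(tapply(x$resname, x$resno, function(r) r[1] == "XR")),
      " ligand(s), model ", attr(x, "model_id"), "\n", sep = "")
  invisible(x)
}

coords <- function(structure) as.matrix(structure[, c("x", "y", "z")])

`coords<-` <- function(structure, value) {
  structure$x <- value[, 1]; structure$y <- value[, 2]; structure$z <- value[, 3]
  structure
}

# atom ids "resno:atom", unique within a structure
atom_ids <- function(structure) paste0(structure$resno, ":", structure$atom)

.atom_xyz <- function(structure, resno, atom) {
  i <- which(structure$resno == resno & structure$atom == atom)
  if (length(i) != 1) stop("atom not found: ", resno, ":", atom)
  as.numeric(structure[i, c("x", "y", "z")])
}

.resname_for <- function(base) c(A = "DA", C = "DC", G = "DG", T = "DT")[[base]]

# ---- helix builder ----------------------------------------------------------

# Internal: build a duplex with per-step rise/twist vectors (length n-1).
.build_helix <- function(topology, rises, twists) {
  n <- topology$n
  stopifnot(length(rises) == n - 1, length(twists) == n - 1)
  z <- cumsum(c(0, rises))
  phi <- cumsum(c(0, twists))
  sense_b <- strsplit(topology$sense, "")[[1]]
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    pt <- .pair_template(sense_b[i])
    R <- .rot_z(phi[i])
    t <- c(0, 0, z[i])
    mk <- function(at, resno, chain) {
      xyz <- .xform(as.matrix(at[, c("x", "y", "z")]), R, t)
      data.frame(resno = resno,
                 resname = .resname_for(residue_base(topology, resno)),
                 atom = at$atom, element = at$element, chain = chain,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    }
    out[[i]] <- mk(pt$sense, i, "A")
    out[[n + i]] <- mk(pt$comp, 2L * n + 1L - i, "B")
  }
  df <- do.call(rbind, out)
  df <- df[order(df$resno), ]
  .new_structure(df, topology)
}

#' Build an idealized B-DNA duplex
#'
#' Constructs a right-handed fiber-geometry B-DNA double helix from a
#' duplex topology: uniform rise and twist at every step, standard base
#' geometry from internal templates, all heavy atoms plus non-exchangeable
#' protons (and imino protons for bookkeeping). The helix axis is +z.
#' Round trip with [compute_frames()]/[step_parameters()] returns the
#' requested twist and rise to numerical precision.
#'
#' @param topology a `duplex_topology`
#' @param rise_per_step rise per dinucleotide step in Angstrom (default 3.4)
#' @param twist_per_step helical twist per step in degrees (default 36)
#' @return a `dna_structure`
#' @examples
#' s <- build_bdna(tff1_duplex())
#' mean(step_parameters(compute_frames(s))$twist)  # 36
#' @export
build_bdna <- function(topology, rise_per_step = 3.4, twist_per_step = 36) {
  stopifnot(inherits(topology, "duplex_topology"))
  n <- topology$n
  .build_helix(topology, rep(rise_per_step, n - 1), rep(twist_per_step, n - 1))
}

# ---- ligand placement -------------------------------------------------------

# rigid-place one phenazine unit into an opened gap
.place_unit <- function(lig_atoms, unit_names, frame_lo, frame_hi, lig_tpl) {
  ring_atoms <- unlist(lig_tpl$rings[
    vapply(lig_tpl$rings, function(r) all(r %in% unit_names), logical(1))])
  tpl_xyz <- as.matrix(lig_atoms[match(unit_names, lig_atoms$atom),
                                 c("x", "y", "z")])
  ring_xyz <- as.matrix(lig_atoms[match(ring_atoms, lig_atoms$atom),
                                  c("x", "y", "z")])
  origin_src <- colMeans(ring_xyz)
  # source frame: long axis along ring-centre line, normal +z (planar tpl)
  ring_list <- lig_tpl$rings[
    vapply(lig_tpl$rings, function(r) all(r %in% unit_names), logical(1))]
  cent <- t(vapply(ring_list, function(r)
    colMeans(as.matrix(lig_atoms[match(r, lig_atoms$atom), c("x", "y", "z")])),
    numeric(3)))
  lsrc <- .unit(cent[3, ] - cent[2, ])          # carboxamide ring -> methyl ring
  nsrc <- c(0, 0, 1)
  Bsrc <- cbind(lsrc, .cross(nsrc, lsrc), nsrc)

  origin_tgt <- (frame_lo$origin + frame_hi$origin) / 2
  zm <- .unit(frame_lo$axes[, 3] + frame_hi$axes[, 3])
  ym <- .unit(frame_lo$axes[, 2] + frame_hi$axes[, 2])
  ym <- .unit(ym - sum(ym * zm) * zm)
  xm <- .cross(ym, zm)

  nc_name <- grep("^NC", unit_names, value = TRUE)
  nc_src <- as.numeric(lig_atoms[match(nc_name, lig_atoms$atom), c("x", "y", "z")])
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    el <- s1 * ym; en <- s2 * zm
    Btgt <- cbind(el, .cross(en, el), en)
    R <- Btgt %*% t(Bsrc)
    nc_new <- as.vector(R %*% (nc_src - origin_src)) + origin_tgt
    score <- sum((nc_new - origin_tgt) * xm)     # amide N on major-groove side
    if (is.null(best) || score > best$score) best <- list(R = R, score = score)
  }
  new_xyz <- sweep((tpl_xyz - matrix(origin_src, nrow(tpl_xyz), 3, byrow = TRUE)) %*%
                     t(best$R), 2, -origin_tgt)
  list(names = unit_names, xyz = new_xyz, xm = xm)
}

#' Place bis-intercalating ligands into opened gaps of a duplex
#'
#' Rigidly inserts each phenazine ring system of the ligand into an opened
#' intercalation gap (ring centroid midway between the flanking base-pair
#' origins, ring plane parallel to the bases, long axis along the pair long
#' axis) and threads the carboxamide-aminoalkyl linker through the major
#' groove between the two ring systems.
#'
#' @param structure a `dna_structure` whose gaps have been opened (see
#'   [make_ground_truth()]); a step is "open" if its rise is at least 5 A
#' @param ligand ligand topology from [ligand_topology()]
#' @param site_steps list of integer pairs: for each ligand molecule, the
#'   two dinucleotide step indices (step i = between pairs i and i+1) that
#'   its two ring systems occupy, e.g. `list(XR1 = c(5, 7), XR2 = c(9, 11))`
#' @return a `dna_structure` including the ligand atoms (resno 101, 102,
#'   ..., resname "XR", chains "C", "D", ...)
#' @export
place_ligands <- function(structure, ligand = ligand_topology(), site_steps) {
  if (length(site_steps) == 0) return(structure)
  topology <- attr(structure, "topology")
  frames <- compute_frames(structure, topology)
  steps <- step_parameters(frames)
  parts <- list(structure)
  for (m in seq_along(site_steps)) {
    ss <- site_steps[[m]]
    stopifnot(length(ss) == 2)
    for (s in ss) {
      if (steps$rise[s] < 5) {
        stop("step ", s, " has rise ", round(steps$rise[s], 2),
             " A; intercalation requires an opened gap (>= 5 A)")
      }
    }
    uA <- .place_unit(ligand$atoms, ligand$units$A,
                      frames[[ss[1]]], frames[[ss[1] + 1]], ligand)
    uB <- .place_unit(ligand$atoms, ligand$units$B,
                      frames[[ss[2]]], frames[[ss[2] + 1]], ligand)
    placed <- ligand$atoms
    xyz <- as.matrix(placed[, c("x", "y", "z")])
    xyz[match(uA$names, placed$atom), ] <- uA$xyz
    xyz[match(uB$names, placed$atom), ] <- uB$xyz

    # linker: zig-zag chain along a quadratic Bezier from NCA to NCB that
    # bows into the major groove; the alternating perpendicular offsets
    # reproduce the template's tetrahedral chain angles
    nca <- xyz[match("NCA", placed$atom), ]
    ncb <- xyz[match("NCB", placed$atom), ]
    groove_dir <- .unit(uA$xm + uB$xm)
    ctrl <- (nca + ncb) / 2 + 3.5 * groove_dir
    bez <- function(t) (1 - t)^2 * nca + 2 * (1 - t) * t * ctrl + t^2 * ncb
    chain <- c("CL1", "CL2", "NG1", "CL3", "CL4", "NG2", "CL5", "CL6")
    for (k in seq_along(chain)) {
      t <- k / (length(chain) + 1)
      tang <- .unit(bez(min(t + 0.05, 1)) - bez(max(t - 0.05, 0)))
      perp <- .unit(.cross(tang, groove_dir))
      xyz[match(chain[k], placed$atom), ] <- bez(t) + ((-1)^k) * 0.45 * perp
    }
    for (ng in c("NG1", "NG2")) {
      cgn <- sub("N", "C", ng)
      xyz[match(cgn, placed$atom), ] <-
        xyz[match(ng, placed$atom), ] + 1.49 * groove_dir
    }
    placed$x <- xyz[, 1]; placed$y <- xyz[, 2]; placed$z <- xyz[, 3]
    resno <- 100L + m
    parts[[m + 1]] <- data.frame(resno = resno, resname = "XR",
                                 atom = placed$atom, element = placed$element,
                                 chain = LETTERS[2 + m],
                                 x = placed$x, y = placed$y, z = placed$z,
                                 stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(parts, as.data.frame))
  .new_structure(df, topology, attr(structure, "model_id"))
}

#' Randomly perturb atomic coordinates
#'
#' Adds isotropic Gaussian noise to every atom such that the root-mean-square
#' displacement magnitude equals `rms` Angstrom (per-coordinate sd
#' `rms/sqrt(3)`). Used to create perturbed starting models for refinement
#' tests.
#'
#' @param structure a `dna_structure`
#' @param rms RMS displacement per atom in Angstrom
#' @param seed integer seed
#' @return perturbed `dna_structure`
#' @export
perturb_structure <- function(structure, rms = 1.0, seed = 1) {
  xyz <- coords(structure)
  set.seed(seed)
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = rms / sqrt(3)),
                      nrow(xyz), 3)
  coords(structure) <- xyz
  structure
}
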