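# Idealized residue geometry templates.
#
# Bases are built as planar regular polygons (ring bond 1.38 A) with
# exocyclic substituents on external bisectors; a deoxyribose-phosphate
# unit is attached at the glycosidic nitrogen.  Each template is expressed
# directly in the base-pair reference frame used throughout the package:
# origin at the pair centre, x toward the major groove, y along the long
# pair axis (toward the sense-strand glycosidic bond), z the pair normal
# (5'->3' direction of the sense strand).  The complementary residue of a
# pair is the 180-degree rotation about x of a "plus" template, which
# makes the duplex exactly antiparallel.
#
# The 5' phosphate is positioned by the inverse of the canonical helix
# step (rise 3.4 A, twist 36 deg) applied to the O3' of the previous
# residue, so that in an unperturbed B-DNA build every O3'(i)-P(i+1)
# distance is exactly the 1.6 A linkage length on both strands.
#
# Aromatic C-H is 1.07 A so that the cytosine H5-H6 distance is exactly
# 1.38 + 2*1.07*sin(30 deg) = 2.45 A, the NOESY calibration reference.

.RING_BOND <- 1.38
.AROM_CH <- 1.07
.IMINO_NH <- 1.03
.GLYC_CN <- 1.48
.CANONICAL_RISE <- 3.4
.CANONICAL_TWIST <- 36
.O3P_BOND <- 1.6
.WC_HALF <- 1.45   # half of the N1...N3 hydrogen-bond distance

.dnarmd_cache <- new.env(parent = emptyenv())

.cached <- function(key, fn) {
  if (!exists(key, envir = .dnarmd_cache)) {
    assign(key, fn(), envir = .dnarmd_cache)
  }
  get(key, envir = .dnarmd_cache)
}

# ---- base templates (2d, own frame) ----------------------------------------

# Returns list(atoms = data.frame(atom, element, x, y),
#              bonds = 2-col matrix of atom names,
#              rings = list of cyclic atom-name vectors,
#              glyc, wc, minor_marker, glyc_ring)
.base_template_2d <- function(base) {
  purine <- base %in% c("A", "G")
  hex <- .regular_ring2d(6, .RING_BOND)
  hex_names <- if (purine) c("N1", "C2", "N3", "C4", "C5", "C6")
               else        c("N1", "C2", "N3", "C4", "C5", "C6")
  atoms <- data.frame(atom = hex_names,
                      element = substr(hex_names, 1, 1),
                      x = hex[, 1], y = hex[, 2],
                      stringsAsFactors = FALSE)
  bonds <- cbind(hex_names, hex_names[c(2:6, 1)])
  rings <- list(hex_names)
  hex_centroid <- colMeans(hex)

  add_atom <- function(name, element, pos) {
    atoms[nrow(atoms) + 1L, ] <<- list(name, element, pos[1], pos[2])
  }
  get2 <- function(name) {
    i <- match(name, atoms$atom)
    c(atoms$x[i], atoms$y[i])
  }
  # substituent on ring vertex, along the external bisector
  exo <- function(on, name, element, len, centroid) {
    v <- get2(on)
    pos <- v + len * (v - centroid) / sqrt(sum((v - centroid)^2))
    add_atom(name, element, pos)
    bonds <<- rbind(bonds, c(on, name))
  }

  if (purine) {
    # fuse the five-membered ring on the C4-C5 edge, outside the hexagon
    p <- get2("C4"); q <- get2("C5")
    pent <- .fused_ring2d(p, q, 5, turn_sign = 1)
    if (sqrt(sum(colMeans(pent)^2)) < sqrt(sum(hex_centroid^2)) + 0.5) {
      pent <- .fused_ring2d(p, q, 5, turn_sign = -1)
    }
    pent_names <- c("C4", "C5", "N7", "C8", "N9")
    for (k in 3:5) add_atom(pent_names[k], substr(pent_names[k], 1, 1), pent[k, ])
    bonds <- rbind(bonds, c("C5", "N7"), c("N7", "C8"), c("C8", "N9"),
                   c("N9", "C4"))
    rings <- c(rings, list(pent_names))
    pent_centroid <- colMeans(pent)
    exo("C8", "H8", "H", .AROM_CH, pent_centroid)
    if (base == "A") {
      exo("C6", "N6", "N", 1.34, hex_centroid)
      exo("C2", "H2", "H", .AROM_CH, hex_centroid)
    } else {
      exo("C6", "O6", "O", 1.23, hex_centroid)
      exo("C2", "N2", "N", 1.34, hex_centroid)
      exo("N1", "H1", "H", .IMINO_NH, hex_centroid)   # imino (bookkeeping)
    }
    glyc <- "N9"; wc <- "N1"; minor <- "N3"; glyc_ring <- pent_names
  } else {
    exo("C2", "O2", "O", 1.23, hex_centroid)
    exo("C6", "H6", "H", .AROM_CH, hex_centroid)
    if (base == "C") {
      exo("C4", "N4", "N", 1.34, hex_centroid)
      exo("C5", "H5", "H", .AROM_CH, hex_centroid)
    } else {
      exo("C4", "O4", "O", 1.23, hex_centroid)
      exo("C5", "C7", "C", 1.50, hex_centroid)        # thymine methyl carbon
      exo("N3", "H3", "H", .IMINO_NH, hex_centroid)   # imino (bookkeeping)
    }
    glyc <- "N1"; wc <- "N3"; minor <- "C2"; glyc_ring <- hex_names
  }
  list(atoms = atoms, bonds = bonds, rings = rings,
       glyc = glyc, wc = wc, minor_marker = minor, glyc_ring = glyc_ring)
}

# tetrahedral completion: one H on a centre with three known neighbours
.tetra_one <- function(centre, n1, n2, n3, len = 1.09) {
  d <- -( .unit(n1 - centre) + .unit(n2 - centre) + .unit(n3 - centre) )
  centre + len * .unit(d)
}

# two H on a centre with two known neighbours (CH2 group)
.tetra_two <- function(centre, n1, n2, len = 1.09) {
  bis <- -.unit(.unit(n1 - centre) + .unit(n2 - centre))
  perp <- .unit(.cross(n1 - centre, n2 - centre))
  half <- 54.75 * pi / 180
  list(centre + len * (cos(half) * bis + sin(half) * perp),
       centre + len * (cos(half) * bis - sin(half) * perp))
}

# three methyl H on carbon `cm` bonded to `stem`, splayed tetrahedrally
.methyl_h <- function(cm, stem, ref_normal, len = 1.09) {
  a <- .unit(cm - stem)
  p1 <- .unit(.cross(ref_normal, a))
  n <- .unit(.cross(a, p1))
  ang <- 70.5 * pi / 180
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    cm + len * (cos(ang) * a + sin(ang) * (cos(phi) * p1 + sin(phi) * n))
  })
}

# ---- full residue template in pair-frame "plus" placement ------------------

# Returns list(atoms = data.frame(atom, element, x, y, z), bonds, rings,
#              base_atoms (names used for frame fitting), glyc, wc)
.residue_template <- function(base) {
  .cached(paste0("res_", base), function() .build_residue_template(base))
}

.build_residue_template <- function(base) {
  tpl <- .base_template_2d(base)
  xy <- as.matrix(tpl$atoms[, c("x", "y")])
  rownames(xy) <- tpl$atoms$atom
  g <- xy[tpl$glyc, ]
  w <- xy[tpl$wc, ]
  # rotate so (wc - glyc) points along -y, then put wc at (0, +WC_HALF)
  d <- (w - g) / sqrt(sum((w - g)^2))
  ang <- atan2(d[2], d[1]) - (-pi / 2)
  R2 <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2, 2, byrow = TRUE)
  xy <- xy %*% t(R2)
  xy <- sweep(xy, 2, xy[tpl$wc, ] - c(0, .WC_HALF))
  # minor-groove marker on -x (major groove = +x)
  if (xy[tpl$minor_marker, 1] > 0) xy[, 1] <- -xy[, 1]

  atoms <- data.frame(atom = rownames(xy), element = tpl$atoms$element,
                      x = xy[, 1], y = xy[, 2], z = 0,
                      stringsAsFactors = FALSE)
  bonds <- tpl$bonds
  pos <- function(name) {
    i <- match(name, atoms$atom)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  add <- function(name, element, p) {
    atoms[nrow(atoms) + 1L, ] <<- list(name, element, p[1], p[2], p[3])
  }
  ring_centroid <- function(names) {
    i <- match(names, atoms$atom)
    c(mean(atoms$x[i]), mean(atoms$y[i]), mean(atoms$z[i]))
  }

  # glycosidic C1' along the external bisector at the glycosidic nitrogen
  gc <- ring_centroid(tpl$glyc_ring)
  gpos <- pos(tpl$glyc)
  c1p <- gpos + .GLYC_CN * .unit(gpos - gc)
  add("C1'", "C", c1p)
  bonds <- rbind(bonds, c(tpl$glyc, "C1'"))

  # thymine methyl protons (out of plane)
  if (base == "T") {
    hs <- .methyl_h(pos("C7"), pos("C5"), c(0, 0, 1))
    add("H71", "H", hs[[1]]); add("H72", "H", hs[[2]]); add("H73", "H", hs[[3]])
    bonds <- rbind(bonds, c("C7", "H71"), c("C7", "H72"), c("C7", "H73"))
  }

  # ---- deoxyribose ring ----
  u <- .unit(c1p - gpos)          # in-plane, away from the base
  wax <- c(0, 0, 1)               # strand axis (3' direction)
  v <- .cross(wax, u)             # tangential
  side <- 1.48
  R5 <- side / (2 * sin(pi / 5))
  centroid <- c1p + R5 * .unit(0.90 * u + 0.35 * v - 0.25 * wax)
  a <- .unit(c1p - centroid)
  nr_raw <- 0.90 * v + 0.44 * wax
  nr <- .unit(nr_raw - sum(nr_raw * a) * a)
  b <- .cross(nr, a)
  vert <- function(k) centroid + R5 * (cos(2 * pi * k / 5) * a +
                                       sin(2 * pi * k / 5) * b)
  # choose walking direction so C2' sits on the 5' (-z) side
  if ((vert(1) - vert(4))[3] > 0) b <- -b
  sugar <- c("C2'", "C3'", "C4'", "O4'")
  for (k in 1:4) add(sugar[k], substr(sugar[k], 1, 1), vert(k))
  bonds <- rbind(bonds, c("C1'", "C2'"), c("C2'", "C3'"), c("C3'", "C4'"),
                 c("C4'", "O4'"), c("O4'", "C1'"))

  # ---- backbone ----
  o3 <- pos("C3'") + 1.42 * .unit(.unit(pos("C3'") - centroid) + 0.9 * wax)
  add("O3'", "O", o3)
  bonds <- rbind(bonds, c("C3'", "O3'"))
  c5p <- pos("C4'") + 1.51 * .unit(.unit(pos("C4'") - centroid) - 0.9 * wax)
  add("C5'", "C", c5p)
  bonds <- rbind(bonds, c("C4'", "C5'"))

  # P of the NEXT residue sits at O3' + O3P_BOND * dhat in the helix;
  # place this residue's own P by the inverse canonical step.
  tang <- .unit(c(-o3[2], o3[1], 0))
  dhat <- .unit(0.5 * tang + 0.85 * wax)
  p_next <- o3 + .O3P_BOND * dhat - c(0, 0, .CANONICAL_RISE)
  ppos <- as.vector(.rot_z(-.CANONICAL_TWIST) %*% p_next)
  add("P", "P", ppos)
  e <- .unit(c5p - ppos)
  o5 <- ppos + 1.60 * e + 0.45 * .unit(.cross(e, v))
  add("O5'", "O", o5)
  bonds <- rbind(bonds, c("C5'", "O5'"), c("O5'", "P"))
  # non-bridging phosphate oxygens: splayed away from both bridging bonds
  # (O5' of this residue and O3' of the 5' neighbour)
  e_o5 <- .unit(o5 - ppos)
  dprev <- -as.vector(.rot_z(-.CANONICAL_TWIST) %*% dhat)
  g <- -.unit(e_o5 + dprev)
  h <- .unit(.cross(e_o5, dprev))
  half <- 75 * pi / 180
  add("OP1", "O", ppos + 1.48 * (cos(half) * g + sin(half) * h))
  add("OP2", "O", ppos + 1.48 * (cos(half) * g - sin(half) * h))
  bonds <- rbind(bonds, c("P", "OP1"), c("P", "OP2"))

  # ---- sugar protons ----
  add("H1'", "H", .tetra_one(pos("C1'"), gpos, pos("C2'"), pos("O4'")))
  h2 <- .tetra_two(pos("C2'"), pos("C1'"), pos("C3'"))
  add("H2'", "H", h2[[1]]); add("H2''", "H", h2[[2]])
  add("H3'", "H", .tetra_one(pos("C3'"), pos("C2'"), pos("C4'"), pos("O3'")))
  add("H4'", "H", .tetra_one(pos("C4'"), pos("C3'"), pos("O4'"), pos("C5'")))
  h5 <- .tetra_two(pos("C5'"), pos("C4'"), pos("O5'"))
  add("H5'", "H", h5[[1]]); add("H5''", "H", h5[[2]])
  bonds <- rbind(bonds, c("C1'", "H1'"), c("C2'", "H2'"), c("C2'", "H2''"),
                 c("C3'", "H3'"), c("C4'", "H4'"),
                 c("C5'", "H5'"), c("C5'", "H5''"))

  rings <- c(tpl$rings, list(c("C1'", "C2'", "C3'", "C4'", "O4'")))
  # all base heavy atoms (rings + exocyclic) anchor the frame fit: the
  # exocyclic substituents extend the lever arm and stabilize the fitted
  # orientation on noisy coordinates
  base_atoms <- tpl$atoms$atom[tpl$atoms$element != "H"]
  list(atoms = atoms, bonds = bonds, rings = rings,
       base_atoms = base_atoms, glyc = tpl$glyc, wc = tpl$wc)
}

# Watson-Crick pair template for a given sense base: complement residue is
# the plus template of the complementary base rotated 180 deg about x.
.pair_template <- function(sense_base) {
  .cached(paste0("pair_", sense_base), function() {
    comp_base <- c(A = "T", T = "A", G = "C", C = "G")[[sense_base]]
    s <- .residue_template(sense_base)
    k <- .residue_template(comp_base)
    katoms <- k$atoms
    xyz <- as.matrix(katoms[, c("x", "y", "z")]) %*% t(.rot180_x)
    katoms$x <- xyz[, 1]; katoms$y <- xyz[, 2]; katoms$z <- xyz[, 3]
    list(sense = s$atoms, comp = katoms,
         sense_meta = s, comp_meta = k)
  })
}

# template coordinates (pair frame) of the base ring atoms, used by the
# frame-fitting analyzer; `strand_role` is "sense" or "comp"
.base_fit_template <- function(base, strand_role) {
  comp_base <- c(A = "T", T = "A", G = "C", C = "G")
  if (strand_role == "sense") {
    meta <- .residue_template(base)
    at <- meta$atoms
    sel <- match(meta$base_atoms, at$atom)
    list(names = meta$base_atoms,
         xyz = as.matrix(at[sel, c("x", "y", "z")]))
  } else {
    meta <- .residue_template(base)
    at <- meta$atoms
    sel <- match(meta$base_atoms, at$atom)
    xyz <- as.matrix(at[sel, c("x", "y", "z")]) %*% t(.rot180_x)
    list(names = meta$base_atoms, xyz = xyz)
  }
}

# ---- ligand template (bis-intercalator) -------------------------------------
#
# Two planar phenazine tricyclics (units A and B), each carrying aromatic
# protons H2/H3/H4 (carboxamide ring) and H6/H7/H8 plus a C9 methyl (far
# ring), joined by a carboxamide-aminoalkyl linker with two protonatable
# gamma-amino nitrogens (NG1, NG2; +1 each at pH 7).  Compact unique atom
# names (<= 4 chars, PDB-safe); fusion carbons C4a/C5a/C9a/C10a are CWx/
# CXx/CYx/CZx, N10 is NTx.

.ligand_template <- function() {
  .cached("ligand", .build_ligand_template)
}

.phenazine_unit_2d <- function(suffix) {
  s <- function(n) paste0(n, suffix)
  hexc <- .regular_ring2d(6, 1.39)
  central <- c(s("CW"), s("N5"), s("CX"), s("CY"), s("NT"), s("CZ"))
  atoms <- data.frame(atom = central, element = substr(central, 1, 1),
                      x = hexc[, 1], y = hexc[, 2], stringsAsFactors = FALSE)
  bonds <- cbind(central, central[c(2:6, 1)])
  get2 <- function(n) { i <- match(n, atoms$atom); c(atoms$x[i], atoms$y[i]) }
  add <- function(n, e, p) atoms[nrow(atoms) + 1L, ] <<- list(n, e, p[1], p[2])
  fuse <- function(p_name, q_name, new_names) {
    p <- get2(p_name); q <- get2(q_name)
    ring <- .fused_ring2d(p, q, 6, 1)
    if (sqrt(sum(colMeans(ring)^2)) < 1.5) ring <- .fused_ring2d(p, q, 6, -1)
    for (k in 3:6) add(new_names[k - 2], substr(new_names[k - 2], 1, 1),
                       ring[k, ])
    full <- c(p_name, q_name, new_names)
    bonds <<- rbind(bonds,
                    cbind(full[2:5], full[3:6]), c(full[6], full[1]))
    full
  }
  # ring A (carboxamide side): C10a-C4a edge -> C4, C3, C2, C1
  ringA <- fuse(s("CZ"), s("CW"), c(s("C4"), s("C3"), s("C2"), s("C1")))
  # ring C (methyl side): C9a-C5a edge -> ...
  ringC <- fuse(s("CY"), s("CX"), c(s("C6"), s("C7"), s("C8"), s("C9")))
  exo <- function(on, name, element, len, ring_names) {
    i <- match(ring_names, atoms$atom)
    centroid <- c(mean(atoms$x[i]), mean(atoms$y[i]))
    vtx <- get2(on)
    add(name, element, vtx + len * (vtx - centroid) / sqrt(sum((vtx - centroid)^2)))
    bonds <<- rbind(bonds, c(on, name))
  }
  for (h in c("2", "3", "4")) exo(s(paste0("C", h)), s(paste0("H", h)), "H",
                                  .AROM_CH, ringA)
  for (h in c("6", "7", "8")) exo(s(paste0("C", h)), s(paste0("H", h)), "H",
                                  .AROM_CH, ringC)
  exo(s("C9"), s("CM"), "C", 1.50, ringC)
  exo(s("C1"), s("CC"), "C", 1.50, ringA)
  # carboxamide O and N off the amide carbon; the amide N leans toward the
  # ring N10 at intramolecular-hydrogen-bond distance (~2.7 A), as in
  # phenazine-1-carboxamides, and the carbonyl O clears the peri H2
  cc <- get2(s("CC")); c1 <- get2(s("C1"))
  d <- (cc - c1) / sqrt(sum((cc - c1)^2))
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  add(s("OC"), "O", cc + 1.23 * rot(d, 75 * pi / 180))
  add(s("NC"), "N", cc + 1.34 * rot(d, -50 * pi / 180))
  bonds <- rbind(bonds, c(s("CC"), s("OC")), c(s("CC"), s("NC")))
  list(atoms = atoms, bonds = bonds,
       rings = list(central, c(s("CZ"), s("CW"), s("C4"), s("C3"), s("C2"), s("C1")),
                    c(s("CY"), s("CX"), s("C6"), s("C7"), s("C8"), s("C9"))))
}

.build_ligand_template <- function() {
  A <- .phenazine_unit_2d("A")
  B <- .phenazine_unit_2d("B")

  to3d <- function(u) {
    data.frame(atom = u$atoms$atom, element = u$atoms$element,
               x = u$atoms$x, y = u$atoms$y, z = 0, stringsAsFactors = FALSE)
  }
  aA <- to3d(A)
  pos <- function(df, n) { i <- match(n, df$atom); c(df$x[i], df$y[i], df$z[i]) }

  # linker chain: NCA - CL1 CL2 NG1(CG1) CL3 CL4 NG2(CG2) CL5 CL6 - NCB
  nca <- pos(aA, "NCA")
  step_dir <- .unit(nca - pos(aA, "CCA"))
  chain_names <- c("CL1", "CL2", "NG1", "CL3", "CL4", "NG2", "CL5", "CL6")
  chain <- matrix(0, 8, 3)
  perp <- .unit(.cross(c(0, 0, 1), step_dir))
  for (k in 1:8) {
    chain[k, ] <- nca + k * 1.25 * step_dir + ((-1)^k) * 0.45 * perp
  }
  end <- chain[8, ] + 1.25 * step_dir + 0.45 * perp   # target for NCB

  # unit B: rotate 180 deg in plane, translate so NCB lands at `end`
  aB <- to3d(B)
  xyzB <- as.matrix(aB[, c("x", "y", "z")]) %*% t(.rot_z(180))
  ncb_now <- xyzB[match("NCB", aB$atom), ]
  xyzB <- sweep(xyzB, 2, ncb_now - end)
  aB$x <- xyzB[, 1]; aB$y <- xyzB[, 2]; aB$z <- xyzB[, 3]

  chain_df <- data.frame(atom = chain_names,
                         element = substr(chain_names, 1, 1),
                         x = chain[, 1], y = chain[, 2], z = chain[, 3],
                         stringsAsFactors = FALSE)
  atoms <- rbind(aA, chain_df, aB)
  addrow <- function(n, e, p) {
    atoms[nrow(atoms) + 1L, ] <<- list(n, e, p[1], p[2], p[3])
  }
  gpos <- function(n) { i <- match(n, atoms$atom); c(atoms$x[i], atoms$y[i], atoms$z[i]) }
  # N-methyls on the gamma nitrogens
  for (ng in c("NG1", "NG2")) {
    cgn <- sub("N", "C", ng)
    addrow(cgn, "C", gpos(ng) + 1.49 * .unit(.cross(step_dir, c(0, 0, 1)) * 0 +
                                             c(0, 0, 1) * 0.4 +
                                             ((-1)^(ng == "NG2")) * perp))
  }
  # methyl protons on the two C9 methyls
  for (sfx in c("A", "B")) {
    cm <- gpos(paste0("CM", sfx)); c9 <- gpos(paste0("C9", sfx))
    hs <- .methyl_h(cm, c9, c(0, 0, 1))
    for (k in 1:3) addrow(paste0("HM", k, sfx), "H", hs[[k]])
  }

  bonds <- rbind(A$bonds, B$bonds,
                 cbind(c("NCA", chain_names), c(chain_names, "NCB")),
                 c("NG1", "CG1"), c("NG2", "CG2"),
                 t(vapply(c("A", "B"), function(sfx)
                   c(paste0("CM", sfx), paste0("HM1", sfx)), character(2))),
                 t(vapply(c("A", "B"), function(sfx)
                   c(paste0("CM", sfx), paste0("HM2", sfx)), character(2))),
                 t(vapply(c("A", "B"), function(sfx)
                   c(paste0("CM", sfx), paste0("HM3", sfx)), character(2))))
  dimnames(bonds) <- NULL

  unitA <- c(A$atoms$atom, "HM1A", "HM2A", "HM3A")
  unitB <- c(B$atoms$atom, "HM1B", "HM2B", "HM3B")
  list(atoms = atoms, bonds = bonds,
       rings = c(A$rings, B$rings),
       units = list(A = unitA, B = unitB),
       linker = c(chain_names, "CG1", "CG2"),
       charged = c("NG1", "NG2"))
}

# pseudo-atom group membership (methyls observed as a single centroid)
.pseudo_members <- function(resname, atom) {
  if (resname == "DT" && atom == "M7") return(c("H71", "H72", "H73"))
  if (resname == "XR" && atom == "MA") return(c("HM1A", "HM2A", "HM3A"))
  if (resname == "XR" && atom == "MB") return(c("HM1B", "HM2B", "HM3B"))
  NULL
}

# upper-bound pseudo-atom corrections (A): methyl, methylene, aromatic pair
.pseudo_correction <- function(resname, atom) {
  if (!is.null(.pseudo_members(resname, atom))) return(1.0)
  0
}
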