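# NOE distance restraints: calibration of peak volumes to bounded
# distances (isolated-spin-pair approximation), Watson-Crick hydrogen-bond
# restraints, category bookkeeping, and the skewed bi-harmonic restraint
# potential used during refinement.

.RESTRAINT_CATEGORIES <- c("intraresidue", "sequential", "hydrogen_bond",
                           "drug", "drug_dna")

#' NOE calibration model
#'
#' Volumes are referenced to the cytosine H5-H6 crosspeak, a fixed
#' covalent-geometry distance of 2.45 A; flat bounds are placed at
#' +/- `bound_fraction` (20 %) around the calibrated distance.
#'
#' @param r_ref reference distance in Angstrom (cytosine H5-H6, 2.45)
#' @param V_ref reference peak volume; `NA` means "read it from the peak
#'   list's reference peak at calibration time"
#' @param bound_fraction relative half-width of the flat bounds (0.20)
#' @return object of class `calibration_model`
#' @export
noe_calibration <- function(r_ref = 2.45, V_ref = NA_real_,
                            bound_fraction = 0.20) {
  stopifnot(r_ref > 0, bound_fraction > 0, bound_fraction < 1)
  structure(list(r_ref = r_ref, V_ref = V_ref,
                 bound_fraction = bound_fraction),
            class = "calibration_model")
}

.category_for <- function(resname_i, resno_i, resname_j, resno_j) {
  lig_i <- resname_i == "XR"
  lig_j <- resname_j == "XR"
  ifelse(lig_i & lig_j, "drug",
    ifelse(lig_i | lig_j, "drug_dna",
      ifelse(resno_i == resno_j, "intraresidue", "sequential")))
}

.new_restraint_set <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("restraint_set", "data.frame"))
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("Restraint set:", nrow(x), "distance restraints\n")
  print(table(x$category))
  invisible(x)
}

#' Calibrate NOESY peak volumes into distance restraints
#'
#' Isolated-spin-pair calibration: r = r_ref * (V_ref / V)^(1/6), with flat
#' bounds at (1 - f) r and (1 + f) r (f = 20 %). Pseudo-atom corrections
#' (methyl +1.0 A) are added to the upper bound for unresolved groups.
#' Peaks with non-positive volume are rejected with a warning; the count is
#' stored in the `n_rejected` attribute.
#'
#' @param peaks a `noe_peaks` peak list (see [simulate_noesy()] /
#'   [read_peaks()])
#' @param model a [noe_calibration()] model
#' @return a `restraint_set` data.frame: atom pair, target `r`, `lower`,
#'   `upper`, `category`, `type` ("noe"), `pseudo_correction`
#' @examples
#' # a peak with the reference volume calibrates to exactly 2.45 A
#' @export
calibrate <- function(peaks, model = noe_calibration()) {
  stopifnot(inherits(peaks, "noe_peaks"))
  V_ref <- model$V_ref
  if (is.na(V_ref)) {
    ref <- attr(peaks, "reference_peak")
    if (is.null(ref)) stop("no reference peak in peak list and no V_ref in model")
    hit <- which((peaks$proton_i == ref[1] & peaks$proton_j == ref[2]) |
                 (peaks$proton_i == ref[2] & peaks$proton_j == ref[1]))
    if (length(hit) == 0) stop("reference peak ", ref[1], "-", ref[2],
                               " not present in peak list")
    V_ref <- peaks$volume[hit[1]]
  }
  stopifnot(V_ref > 0)
  bad <- !(peaks$volume > 0)
  if (any(bad)) {
    warning(sum(bad), " peak(s) with non-positive volume rejected")
    peaks <- peaks[!bad, ]
  }
  r <- model$r_ref * (V_ref / peaks$volume)^(1 / 6)
  split_id <- function(id) {
    m <- regmatches(id, regexpr("^[0-9]+", id))
    list(resno = as.integer(m), atom = sub("^[0-9]+:", "", id))
  }
  ii <- split_id(peaks$proton_i)
  jj <- split_id(peaks$proton_j)
  corr <- mapply(.pseudo_correction, peaks$resname_i, ii$atom) +
          mapply(.pseudo_correction, peaks$resname_j, jj$atom)
  f <- model$bound_fraction
  df <- data.frame(resno_i = ii$resno, atom_i = ii$atom,
                   resname_i = peaks$resname_i,
                   resno_j = jj$resno, atom_j = jj$atom,
                   resname_j = peaks$resname_j,
                   r = r, lower = (1 - f) * r, upper = (1 + f) * r + corr,
                   pseudo_correction = as.numeric(corr),
                   category = .category_for(peaks$resname_i, ii$resno,
                                            peaks$resname_j, jj$resno),
                   type = "noe",
                   stringsAsFactors = FALSE)
  out <- .new_restraint_set(df)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "calibration") <- list(r_ref = model$r_ref, V_ref = V_ref,
                                   bound_fraction = f)
  out
}

#' Classify restraints into inventory categories
#'
#' Re-derives the five-category inventory from atom identities:
#' `intraresidue` (both atoms in the same DNA residue), `sequential`
#' (different DNA residues), `hydrogen_bond` (flagged at creation),
#' `drug` (both atoms in a ligand), `drug_dna` (one ligand, one DNA atom).
#' The counts always partition the set.
#'
#' @param set a `restraint_set`
#' @param topology a `duplex_topology` used to validate that every DNA
#'   atom resolves to a residue
#' @return named integer vector over the five categories plus `total`
#' @export
classify <- function(set, topology) {
  stopifnot(inherits(set, "restraint_set"))
  check <- function(resno, resname, atom) {
    dna <- resname != "XR"
    bad <- dna & !(resno %in% topology$residues$resno)
    if (any(bad)) {
      stop("unresolvable atom id: ", resno[bad][1], ":", atom[bad][1])
    }
  }
  if (nrow(set) > 0) {
    check(set$resno_i, set$resname_i, set$atom_i)
    check(set$resno_j, set$resname_j, set$atom_j)
  }
  cat_v <- ifelse(set$type == "hbond", "hydrogen_bond",
                  .category_for(set$resname_i, set$resno_i,
                                set$resname_j, set$resno_j))
  counts <- vapply(.RESTRAINT_CATEGORIES, function(k) sum(cat_v == k),
                   integer(1))
  c(counts, total = nrow(set))
}

#' Watson-Crick hydrogen-bond restraints
#'
#' Two restraints per selected base pair: the central N1...N3 hydrogen
#' bond and one carbonyl...amino bond (G O6-C N4 or A N6-T O4), with
#' target distances taken from the idealized pair geometry and flat bounds
#' of +/- 0.2 A. These hold the duplex paired during high-temperature
#' annealing stages.
#'
#' @param topology a `duplex_topology`
#' @param pairs_subset integer vector of pair indices to restrain;
#'   defaults to all non-terminal pairs
#' @return a `restraint_set` with category `hydrogen_bond`
#' @export
make_hbond_restraints <- function(topology,
                                  pairs_subset = seq(2, topology$n - 1)) {
  stopifnot(inherits(topology, "duplex_topology"))
  if (length(pairs_subset) == 0) {
    return(.new_restraint_set(data.frame(
      resno_i = integer(), atom_i = character(), resname_i = character(),
      resno_j = integer(), atom_j = character(), resname_j = character(),
      r = numeric(), lower = numeric(), upper = numeric(),
      pseudo_correction = numeric(), category = character(),
      type = character(), stringsAsFactors = FALSE)))
  }
  rows <- vector("list", length(pairs_subset))
  for (k in seq_along(pairs_subset)) {
    p <- pairs_subset[k]
    sres <- topology$pairs$sense_res[p]
    cres <- topology$pairs$comp_res[p]
    sb <- residue_base(topology, sres)
    pt <- .pair_template(sb)
    tdist <- function(a_sense, a_comp) {
      ps <- as.numeric(pt$sense[match(a_sense, pt$sense$atom), c("x", "y", "z")])
      pc <- as.numeric(pt$comp[match(a_comp, pt$comp$atom), c("x", "y", "z")])
      sqrt(sum((ps - pc)^2))
    }
    # central N1(purine)...N3(pyrimidine) + carbonyl...amino donor pair
    if (sb %in% c("A", "G")) {
      a1 <- c("N1", "N3")
      a2 <- if (sb == "G") c("O6", "N4") else c("N6", "O4")
    } else {
      a1 <- c("N3", "N1")
      a2 <- if (sb == "C") c("N4", "O6") else c("O4", "N6")
    }
    r1 <- tdist(a1[1], a1[2])
    r2 <- tdist(a2[1], a2[2])
    rows[[k]] <- data.frame(
      resno_i = c(sres, sres), atom_i = c(a1[1], a2[1]),
      resname_i = .resname_for(sb),
      resno_j = c(cres, cres), atom_j = c(a1[2], a2[2]),
      resname_j = .resname_for(residue_base(topology, cres)),
      r = c(r1, r2), lower = c(r1, r2) - 0.2, upper = c(r1, r2) + 0.2,
      pseudo_correction = 0, category = "hydrogen_bond", type = "hbond",
      stringsAsFactors = FALSE)
  }
  .new_restraint_set(do.call(rbind, rows))
}

#' Default hydrogen-bond pair selection for the TFF1-ERE duplex
#'
#' The 12 pairs with clearly observed imino protons: non-terminal pairs
#' 2-14 excluding G11:C20, whose imino proton is barely perturbed at the
#' weak binding site. Yields the canonical 24 hydrogen-bond restraints.
#' @return integer vector of pair indices
#' @export
tff1_hbond_pairs <- function() setdiff(2:14, 11)

#' Restraint force-constant parameters
#'
#' @param k_noe force constant for NOE restraints (kcal/mol/A^2; final
#'   annealing value 30)
#' @param k_hbond force constant for hydrogen-bond restraints (60)
#' @param skew_upper,skew_lower dimensionless stiffness multipliers above /
#'   below the bounds (the "skew" of the bi-harmonic well; default 1:1)
#' @return object of class `restraint_params`
#' @export
restraint_params <- function(k_noe = 30, k_hbond = 60,
                             skew_upper = 1, skew_lower = 1) {
  stopifnot(k_noe >= 0, k_hbond >= 0, skew_upper > 0, skew_lower > 0)
  structure(list(k_noe = k_noe, k_hbond = k_hbond,
                 skew_upper = skew_upper, skew_lower = skew_lower),
            class = "restraint_params")
}

#' Skewed bi-harmonic restraint energy
#'
#' Flat-bottomed quadratic penalty: zero inside `[lower, upper]`,
#' `k * skew_upper * (d - upper)^2` above and
#' `k * skew_lower * (lower - d)^2` below, with `k` selected by restraint
#' type (NOE vs hydrogen bond). Energy and gradient are continuous at the
#' bounds.
#'
#' @param distance distance(s) in Angstrom
#' @param restraint one row of a `restraint_set` (needs `lower`, `upper`,
#'   `type`)
#' @param params a [restraint_params()]
#' @return energy in kcal/mol (vectorized over `distance`)
#' @export
restraint_energy <- function(distance, restraint, params = restraint_params()) {
  stopifnot(all(distance > 0))
  k <- if (identical(restraint$type, "hbond")) params$k_hbond else params$k_noe
  up <- pmax(distance - restraint$upper, 0)
  lo <- pmax(restraint$lower - distance, 0)
  k * (params$skew_upper * up^2 + params$skew_lower * lo^2)
}

#' @rdname restraint_energy
#' @return `restraint_gradient`: dE/dd in kcal/mol/A
#' @export
restraint_gradient <- function(distance, restraint, params = restraint_params()) {
  k <- if (identical(restraint$type, "hbond")) params$k_hbond else params$k_noe
  up <- pmax(distance - restraint$upper, 0)
  lo <- pmax(restraint$lower - distance, 0)
  2 * k * (params$skew_upper * up - params$skew_lower * lo)
}

# ---- evaluation against a structure ----------------------------------------

# resolve one restraint side to the row indices of its (pseudo-)atoms
.restraint_rows <- function(structure, resno, atom, resname) {
  members <- .pseudo_members(resname, atom)
  ids <- atom_ids(structure)
  if (is.null(members)) {
    i <- match(paste0(resno, ":", atom), ids)
    if (is.na(i)) stop("restraint atom not found in structure: ",
                       resno, ":", atom)
    i
  } else {
    i <- match(paste0(resno, ":", members), ids)
    if (anyNA(i)) stop("pseudo-atom members missing for ", resno, ":", atom)
    i
  }
}

#' Evaluate restraint distances on a structure
#'
#' Pseudo-atom groups are evaluated at their centroid.
#' @param structure a `dna_structure`
#' @param set a `restraint_set`
#' @return numeric vector of distances (A), one per restraint
#' @export
restraint_distances <- function(structure, set) {
  xyz <- coords(structure)
  vapply(seq_len(nrow(set)), function(k) {
    ri <- .restraint_rows(structure, set$resno_i[k], set$atom_i[k],
                          set$resname_i[k])
    rj <- .restraint_rows(structure, set$resno_j[k], set$atom_j[k],
                          set$resname_j[k])
    pi_ <- colMeans(xyz[ri, , drop = FALSE])
    pj <- colMeans(xyz[rj, , drop = FALSE])
    sqrt(sum((pi_ - pj)^2))
  }, numeric(1))
}

#' Restraint violations of a structure
#'
#' @inheritParams restraint_distances
#' @param threshold violation threshold in Angstrom (0.2 by convention)
#' @return list: `n_violations` (excess beyond a bound larger than
#'   `threshold`), `rmsd` (root-mean-square excess over all violated
#'   restraints, i.e. those with any positive excess), `excess` vector
#' @export
restraint_violations <- function(structure, set, threshold = 0.2) {
  d <- restraint_distances(structure, set)
  excess <- pmax(d - set$upper, set$lower - d, 0)
  viol <- excess[excess > 0]
  list(n_violations = sum(excess > threshold),
       rmsd = if (length(viol)) sqrt(mean(viol^2)) else 0,
       excess = excess)
}

#' Total restraint energy of a structure
#' @inheritParams restraint_distances
#' @param params a [restraint_params()]
#' @return energy in kcal/mol
#' @export
total_restraint_energy <- function(structure, set,
                                   params = restraint_params()) {
  d <- restraint_distances(structure, set)
  k <- ifelse(set$type == "hbond", params$k_hbond, params$k_noe)
  up <- pmax(d - set$upper, 0)
  lo <- pmax(set$lower - d, 0)
  sum(k * (params$skew_upper * up^2 + params$skew_lower * lo^2))
}
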