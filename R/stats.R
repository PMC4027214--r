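# Ensemble container and structural statistics: optimal superposition
# RMSD, restraint-violation statistics, geometry deviations and the
# Table-1-style ensemble report.

.new_ensemble <- function(models, info) {
  stopifnot(length(models) == nrow(info))
  structure(list(models = models, info = info), class = "dna_ensemble")
}

#' @export
print.dna_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$models), "models,",
      nrow(x$models[[1]]), "atoms each\n")
  print(utils::head(x$info, 12))
  invisible(x)
}

#' @export
length.dna_ensemble <- function(x) length(x$models)

#' Optimal-superposition RMSD between two structures
#'
#' Least-squares rigid superposition (rotation + translation, no
#' reflection; Kabsch algorithm) of the selected atoms of `a` onto `b`,
#' returning the residual RMSD.
#'
#' @param a,b `dna_structure` objects sharing the selected atoms
#' @param selection which atoms to superpose: "heavy" (default, all
#'   non-hydrogen atoms), "all", or a character vector of atom ids
#'   ("resno:atom")
#' @return RMSD in Angstrom
#' @export
superpose_rmsd <- function(a, b, selection = "heavy") {
  ids_a <- atom_ids(a)
  ids_b <- atom_ids(b)
  sel <- if (identical(selection, "heavy")) {
    ids_a[a$element != "H"]
  } else if (identical(selection, "all")) {
    ids_a
  } else selection
  ia <- match(sel, ids_a)
  ib <- match(sel, ids_b)
  if (anyNA(ia) || anyNA(ib)) stop("selection not resolvable in both structures")
  if (length(sel) < 3) stop("need at least 3 atoms to superpose")
  .kabsch(coords(a)[ia, , drop = FALSE], coords(b)[ib, , drop = FALSE])$rmsd
}

#' Ensemble structural statistics
#'
#' The standard refinement report: per-model restraint violations beyond a
#' threshold, RMS of the out-of-bound excess, RMS deviations from ideal
#' covalent geometry (bonds, angles, impropers of the internal force
#' field), and the mean pairwise heavy-atom RMSD after optimal
#' superposition.
#'
#' @param ensemble a `dna_ensemble`
#' @param restraints a `restraint_set` evaluable on every model
#' @param threshold violation threshold in Angstrom (0.2)
#' @param selection atom selection for the pairwise RMSD (see
#'   [superpose_rmsd()]); "heavy" by default
#' @return object of class `stats_report`: list with `per_model`
#'   (data.frame of violation counts and geometry deviations), and summary
#'   fields `violations_mean`, `violations_sd`, `violation_rmsd_mean`,
#'   `violation_rmsd_sd`, `bond_dev_mean`, `angle_dev_mean`,
#'   `improper_dev_mean`, `pairwise_rmsd_mean`, `pairwise_rmsd_sd`
#' @export
ensemble_stats <- function(ensemble, restraints, threshold = 0.2,
                           selection = "heavy") {
  stopifnot(inherits(ensemble, "dna_ensemble"), length(ensemble) >= 1)
  ids0 <- atom_ids(ensemble$models[[1]])
  for (m in ensemble$models) {
    if (!identical(atom_ids(m), ids0)) stop("atom mismatch across models")
  }
  ff <- .ff_geometry_terms(ensemble$models[[1]])
  per <- lapply(ensemble$models, function(m) {
    v <- restraint_violations(m, restraints, threshold)
    g <- .geometry_deviations(m, ff)
    data.frame(n_violations = v$n_violations, violation_rmsd = v$rmsd,
               bond_dev = g$bond, angle_dev = g$angle, improper_dev = g$improper)
  })
  per <- do.call(rbind, per)
  per$model <- seq_len(nrow(per))

  nm <- length(ensemble$models)
  prmsd <- c()
  if (nm >= 2) {
    for (i in seq_len(nm - 1)) for (j in seq(i + 1, nm)) {
      prmsd <- c(prmsd, superpose_rmsd(ensemble$models[[i]],
                                       ensemble$models[[j]], selection))
    }
  }
  structure(list(
    per_model = per,
    violations_mean = mean(per$n_violations),
    violations_sd = stats::sd(per$n_violations),
    violation_rmsd_mean = mean(per$violation_rmsd),
    violation_rmsd_sd = stats::sd(per$violation_rmsd),
    bond_dev_mean = mean(per$bond_dev),
    angle_dev_mean = mean(per$angle_dev),
    improper_dev_mean = mean(per$improper_dev),
    pairwise_rmsd_mean = if (length(prmsd)) mean(prmsd) else 0,
    pairwise_rmsd_sd = if (length(prmsd) > 1) stats::sd(prmsd) else 0,
    threshold = threshold, n_restraints = nrow(restraints)),
    class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Ensemble statistics (", nrow(x$per_model), " models, ",
      x$n_restraints, " restraints)\n", sep = "")
  cat(sprintf("  NOE violations > %.1f A : %.2f +/- %.2f\n",
              x$threshold, x$violations_mean, x$violations_sd))
  cat(sprintf("  RMSD of violations (A) : %.3f +/- %.3f\n",
              x$violation_rmsd_mean, x$violation_rmsd_sd))
  cat(sprintf("  Bond deviation (A)     : %.4f\n", x$bond_dev_mean))
  cat(sprintf("  Angle deviation (deg)  : %.2f\n", x$angle_dev_mean))
  cat(sprintf("  Improper dev. (deg)    : %.2f\n", x$improper_dev_mean))
  cat(sprintf("  Pairwise RMSD (A)      : %.2f +/- %.2f\n",
              x$pairwise_rmsd_mean, x$pairwise_rmsd_sd))
  invisible(x)
}

# RMS deviations of a model from the force-field ideal geometry
.geometry_deviations <- function(model, ff) {
  xyz <- coords(model)
  b <- ff$bonds
  db <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                      xyz[b[, 2], , drop = FALSE])^2)) - ff$bond_r0
  a <- ff$angles
  dth <- vapply(seq_len(nrow(a)), function(k) {
    .angle3(xyz[a[k, 1], ], xyz[a[k, 2], ], xyz[a[k, 3], ]) - ff$angle_t0[k]
  }, numeric(1))
  t <- ff$torsions
  dph <- vapply(seq_len(nrow(t)), function(k) {
    dd <- .dihedral(xyz[t[k, 1], ], xyz[t[k, 2], ], xyz[t[k, 3], ],
                    xyz[t[k, 4], ]) - ff$torsion_p0[k]
    ((dd + 180) %% 360) - 180
  }, numeric(1))
  list(bond = sqrt(mean(db^2)), angle = sqrt(mean(dth^2)),
       improper = sqrt(mean(dph^2)))
}
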