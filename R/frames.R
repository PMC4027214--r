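# Base-pair reference frames and helical step parameters.
#
# A pair frame is fitted by one joint least-squares superposition
# (Kabsch) of the idealized two-base pair template (all base heavy atoms,
# complement pre-flipped into the pair frame) onto the observed atoms.
# The joint fit keeps the frame origin inside the fitted atom cloud; a
# per-base fit with averaged frames extrapolates the origin several
# Angstrom outside each base and amplifies coordinate noise into origin
# and twist error, which matters when analysing noisy ensembles.  Step
# parameters follow a mid-step frame convention: rise is the projection
# of the inter-origin vector on the mean z axis, twist the rotation of
# the x axis about the mean z axis.

#' Compute base-pair reference frames
#'
#' @param model a `dna_structure`
#' @param topology the duplex topology; defaults to the one attached to
#'   the structure
#' @return list of `n` frames, each `list(origin, axes)` with `axes` an
#'   orthonormal 3x3 matrix (columns x = major-groove direction,
#'   y = long pair axis, z = pair normal), plus a `fit_rmsd` attribute
#' @export
compute_frames <- function(model, topology = attr(model, "topology")) {
  stopifnot(inherits(model, "dna_structure"), inherits(topology, "duplex_topology"))
  n <- topology$n
  frames <- vector("list", n)
  ids <- atom_ids(model)
  xyz <- coords(model)
  for (i in seq_len(n)) {
    sres <- topology$pairs$sense_res[i]
    cres <- topology$pairs$comp_res[i]
    ts <- .base_fit_template(residue_base(topology, sres), "sense")
    tc <- .base_fit_template(residue_base(topology, cres), "comp")
    want <- c(paste0(sres, ":", ts$names), paste0(cres, ":", tc$names))
    rows <- match(want, ids)
    if (anyNA(rows)) {
      stop("missing base atoms for pair ", i, ": ",
           paste(want[is.na(rows)], collapse = ", "))
    }
    k <- .kabsch(rbind(ts$xyz, tc$xyz), xyz[rows, , drop = FALSE])
    frames[[i]] <- list(origin = k$t, axes = k$R, fit_rmsd = k$rmsd, pair = i)
  }
  frames
}

#' Helical step parameters (rise and twist)
#'
#' For each consecutive pair of base-pair frames: rise is the projection of
#' the origin displacement onto the mean normal, twist the signed rotation
#' of the x axis about the mean normal, and unwinding the deficit from the
#' 36 degrees/step of regular B-DNA. Intercalation gaps show up as steps
#' with rise around 6 A instead of 3.4 A.
#'
#' @param frames list of frames from [compute_frames()]
#' @return data.frame with columns `step`, `rise` (A), `twist` (deg),
#'   `unwinding` (deg, = 36 - twist)
#' @export
step_parameters <- function(frames) {
  stopifnot(length(frames) >= 2)
  out <- data.frame(step = seq_len(length(frames) - 1L),
                    rise = NA_real_, twist = NA_real_)
  for (i in seq_len(length(frames) - 1L)) {
    f1 <- frames[[i]]; f2 <- frames[[i + 1]]
    zm <- .unit(f1$axes[, 3] + f2$axes[, 3])
    out$rise[i] <- sum((f2$origin - f1$origin) * zm)
    x1 <- f1$axes[, 1]; x2 <- f2$axes[, 1]
    x1p <- .unit(x1 - sum(x1 * zm) * zm)
    x2p <- .unit(x2 - sum(x2 * zm) * zm)
    ang <- atan2(sum(.cross(x1p, x2p) * zm), sum(x1p * x2p)) * 180 / pi
    out$twist[i] <- ang
  }
  out$unwinding <- 36 - out$twist
  out
}

#' Total unwinding over a binding site
#'
#' Sums the per-step twist deficit (36 deg minus observed twist) over the
#' steps spanned by a site. For the 3-step site C5-G8 of the first ligand
#' the deposited ensemble gives about 32 degrees.
#'
#' @param steps data.frame from [step_parameters()]
#' @param site integer vector of step indices (e.g. `5:7` for pairs 5-8)
#' @return unwinding in degrees
#' @export
site_unwinding <- function(steps, site) {
  if (length(site) == 0) stop("empty site range")
  if (!all(site %in% steps$step)) stop("site steps outside the duplex")
  sum(36 - steps$twist[match(site, steps$step)])
}
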