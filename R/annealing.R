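# NOE-restrained molecular dynamics / simulated annealing protocol.
#
# The staged protocol: equilibration at 300 K for 20 ps with all restraint
# force constants at 1 kcal/mol/A^2; equilibration at 1000 K for 3 ps; a
# 24 ps ramp of the force constants to their final values (30 for NOE, 60
# for hydrogen bonds); cooling from 1000 K to 300 K in 25 K decrements of
# 1000 x 3 fs steps (28 cycles); 3 ps of final equilibration; coordinate
# averaging over a last 3 ps window; and 250 steps of energy minimization.
# Heating/equilibration stages use a 1 fs timestep, cooling cycles 3 fs.

#' The default annealing schedule
#'
#' Encodes the staged refinement protocol exactly (see the package
#' vignette for the provenance of each number): 300 K/20 ps at restraint
#' k = 1, 1000 K/3 ps, a 24 ps ramp to (30, 60) kcal/mol/A^2, cooling
#' 1000 -> 300 K in 28 cycles of 25 K (1000 steps of 3 fs each), 3 ps
#' equilibration, 3 ps coordinate averaging, 250 minimization steps.
#'
#' @return object of class `annealing_schedule`: list with `stages`
#'   (data.frame), `n_min`, and helper fields
#' @examples
#' sch <- default_schedule()
#' sum(sch$stages$temperature < 1000 & sch$stages$dt_fs == 3)  # 28 cycles
#' @export
default_schedule <- function() {
  stage <- function(T, ps, dt, kn0, kn1, kh0, kh1, avg = 0L) {
    data.frame(temperature = T, duration_ps = ps, dt_fs = dt,
               nsteps = as.integer(round(ps * 1000 / dt)),
               k_noe_start = kn0, k_noe_end = kn1,
               k_hbond_start = kh0, k_hbond_end = kh1,
               average = as.integer(avg))
  }
  cooling_T <- seq(1000 - 25, 300, by = -25)
  cool <- do.call(rbind, lapply(cooling_T, function(T)
    stage(T, 3, 3, 30, 30, 60, 60)))
  stages <- rbind(
    stage(300, 20, 1, 1, 1, 1, 1),       # low-T equilibration, k = 1
    stage(1000, 3, 1, 1, 1, 1, 1),       # heat
    stage(1000, 24, 1, 1, 30, 1, 60),    # force-constant ramp
    cool,                                # 28 cooling cycles, 25 K each
    stage(300, 3, 1, 30, 30, 60, 60),    # final equilibration
    stage(300, 3, 1, 30, 30, 60, 60, avg = 1L)  # averaging window
  )
  structure(list(stages = stages, n_min = 250L, scale = 1),
            class = "annealing_schedule")
}

#' Scale an annealing schedule's durations
#'
#' Multiplies every stage's step count by `factor` (minimum one step per
#' stage), leaving temperatures, timesteps and force-constant targets
#' unchanged. `factor = 0.1` is the desk-scale mode used as the test
#' default; the full-length protocol is the deployment setting.
#'
#' @param schedule an `annealing_schedule`
#' @param factor duration multiplier in (0, 1]
#' @return scaled `annealing_schedule`
#' @export
scale_schedule <- function(schedule, factor = 0.1) {
  stopifnot(inherits(schedule, "annealing_schedule"), factor > 0, factor <= 1)
  schedule$stages$nsteps <- pmax(1L, as.integer(round(schedule$stages$nsteps * factor)))
  schedule$stages$duration_ps <-
    schedule$stages$nsteps * schedule$stages$dt_fs / 1000
  # minimization steps are kept at full length: they cost little and the
  # protocol's endpoint should stay converged even in desk-scale mode
  schedule$scale <- schedule$scale * factor
  schedule
}

#' @export
print.annealing_schedule <- function(x, ...) {
  st <- x$stages
  cat("Annealing schedule:", nrow(st), "stages,",
      sum(st$nsteps), "MD steps,", x$n_min, "minimization steps",
      if (x$scale != 1) sprintf("(scaled x%g)", x$scale) else "", "\n")
  cat(sprintf("  %4.0f K for %6.2f ps (dt %g fs), restraint k %g->%g / %g->%g\n",
              st$temperature[1], st$duration_ps[1], st$dt_fs[1],
              st$k_noe_start[1], st$k_noe_end[1],
              st$k_hbond_start[1], st$k_hbond_end[1]))
  cool <- st$dt_fs == 3 & st$temperature < 1000
  if (any(cool)) {
    cat(sprintf("  ... cooling: %d cycles of %d steps, %.0f -> %.0f K\n",
                sum(cool), st$nsteps[which(cool)[1]],
                max(st$temperature[cool]) + 25, min(st$temperature[cool])))
  }
  invisible(x)
}

#' Run restrained simulated annealing
#'
#' Refines `n_models` copies of the starting structure, each with an
#' independent Maxwell-Boltzmann velocity seed (`seed + model - 1`),
#' through the staged protocol: velocity-Verlet integration with a
#' per-step velocity-rescaling thermostat at the stage temperature,
#' restraint force constants per schedule, coordinate averaging over the
#' final window, then energy minimization. Deterministic given
#' (structure, restraints, schedule, seed).
#'
#' @param start a chemically complete `dna_structure`
#' @param restraints a `restraint_set`
#' @param schedule an `annealing_schedule` (default: desk-scale 10 % of
#'   the full protocol)
#' @param n_models number of models to generate
#' @param seed base integer seed
#' @param params a [restraint_params()] carrying the bi-harmonic skew
#' @return a `dna_ensemble` with per-model energies, restraint energies,
#'   violation counts and seeds; aborted models are flagged in `info`
#' @export
run_annealing <- function(start, restraints,
                          schedule = scale_schedule(default_schedule(), 0.1),
                          n_models = 10, seed = 1L,
                          params = restraint_params()) {
  stopifnot(inherits(start, "dna_structure"), n_models >= 1)
  sys <- build_ff_system(start, restraints)
  sys$skew_upper <- params$skew_upper
  sys$skew_lower <- params$skew_lower
  n <- nrow(start)
  mass <- sys$mass
  T1 <- schedule$stages$temperature[1]
  kB <- 0.0019872041
  models <- vector("list", n_models)
  info <- vector("list", n_models)
  logs <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    sd_m <- sqrt(kB * T1 / mass)
    set.seed(seed + m - 1L)
    vel <- matrix(stats::rnorm(3 * n), n, 3) * sd_m
    res <- engine_anneal(sys, coords(start), vel, schedule$stages,
                         schedule$n_min)
    s <- start
    coords(s) <- res$xyz
    attr(s, "model_id") <- m
    models[[m]] <- s
    viol <- if (res$aborted) NA_integer_ else
      restraint_violations(s, restraints)$n_violations
    info[[m]] <- data.frame(model = m, energy = res$E_total,
                            restraint_energy = res$E_restraint,
                            violations = viol, seed = seed + m - 1L,
                            aborted = res$aborted)
    logs[[m]] <- data.frame(stage = seq_along(res$stage_T),
                            T_target = schedule$stages$temperature,
                            T_mean = res$stage_T,
                            E_total = res$stage_E,
                            E_restraint = res$stage_E_restraint)
  }
  info <- do.call(rbind, info)
  if (any(info$aborted)) {
    warning(sum(info$aborted), " model(s) aborted on energy divergence")
  }
  out <- .new_ensemble(models, info)
  out$logs <- logs
  out
}

#' Select the best models of a candidate ensemble
#'
#' Lexicographic ranking by (number of restraint violations > 0.2 A,
#' total energy), with the original index as a stable tie-break; the
#' first `n` models are returned. This is the "minimal energy terms and
#' minimal number of violations" selection rule.
#'
#' @param candidates a `dna_ensemble`
#' @param n number of models to keep (default 10)
#' @return a `dna_ensemble` of the selected models
#' @export
select_models <- function(candidates, n = 10) {
  stopifnot(inherits(candidates, "dna_ensemble"))
  if (length(candidates) < n) {
    stop("need at least ", n, " candidates, have ", length(candidates))
  }
  info <- candidates$info
  ok <- !isTRUE(info$aborted) & !is.na(info$violations)
  ord <- order(!ok, info$violations, info$energy, info$model)
  keep <- ord[seq_len(n)]
  .new_ensemble(candidates$models[keep], info[keep, , drop = FALSE])
}
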