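#' Simulation parameters
#'
#' Reduced DPD units throughout: r_c = 1, kT = 1, reference particle mass
#' = 1. The friction coefficient is tied to the random force magnitude by
#' the fluctuation-dissipation relation gamma = sigma^2 / (2 kT), so the
#' dissipative and random forces act together as a momentum-conserving
#' thermostat.
#'
#' @param steps number of dynamics steps.
#' @param dt time step (DPD time), default 0.04.
#' @param kT target temperature (DPD energy), default 1.
#' @param sigma random force magnitude, default 3.
#' @param output_frequency record a frame and scalar series entry every
#'   this many steps.
#' @param integrator \code{"GWMVV"} (velocity Verlet with lambda velocity
#'   prediction for the dissipative force) or \code{"SCMVV"}
#'   (self-consistent velocity iteration).
#' @param lambda velocity-prediction parameter, default 0.5.
#' @param minimization_steps initial steepest-descent steps on the
#'   conservative + bond potential (capped displacement 0.05 r_c).
#' @param minimization_output record a minimization frame every this many
#'   steps (0 = none).
#' @param velocity_scaling_steps initial steps during which velocities are
#'   rescaled so the instantaneous kT equals the target exactly.
#' @param unit_mass give every particle mass 1; otherwise masses are the
#'   particle molar masses normalized by the reference (smallest-volume)
#'   particle.
#' @param periodic per-axis periodic boundary flags.
#' @param temperature physical temperature (K) used for repulsion lookup
#'   in the particle set.
#' @param rng_kind pair-noise generator; \code{"counter"} is the splittable
#'   counter generator keyed on (seed, step, pair).
#' @param seed integer seed for all stochastic elements.
#' @return object of class \code{simulation_parameters}; \code{gamma} is
#'   derived, not settable.
#' @export
simulation_parameters <- function(steps = 1000, dt = 0.04, kT = 1, sigma = 3,
                                  output_frequency = 100,
                                  integrator = c("GWMVV", "SCMVV"),
                                  lambda = 0.5,
                                  minimization_steps = 0,
                                  minimization_output = 0,
                                  velocity_scaling_steps = 0,
                                  unit_mass = TRUE,
                                  periodic = c(TRUE, TRUE, TRUE),
                                  temperature = 298,
                                  rng_kind = "counter", seed = 1L) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, sigma >= 0, output_frequency >= 1, steps >= 0, kT > 0)
  structure(list(steps = as.integer(steps), dt = dt, kT = kT, sigma = sigma,
                 gamma = sigma^2 / (2 * kT),
                 output_frequency = as.integer(output_frequency),
                 integrator = integrator, lambda = lambda,
                 minimization_steps = as.integer(minimization_steps),
                 minimization_output = as.integer(minimization_output),
                 velocity_scaling_steps = as.integer(velocity_scaling_steps),
                 unit_mass = isTRUE(unit_mass),
                 periodic = as.logical(periodic),
                 temperature = temperature,
                 rng_kind = rng_kind, seed = as.integer(seed)),
            class = "simulation_parameters")
}

#' Movement constraints per molecule type
#'
#' @param fixation character vector of molecule type names held spatially
#'   fixed (positions restored, velocities zeroed every step).
#' @param cages named list: molecule type -> c(xlo, xhi, ylo, yhi, zlo,
#'   zhi); particles are reflected at the cage walls.
#' @param fixed_velocity named list: molecule type -> 3-vector, velocity
#'   overwritten every step.
#' @param kicks named list: molecule type -> list(velocity = 3-vector,
#'   frequency = n); the increment is added every n-th step.
#' @return object of class \code{movement_constraints}.
#' @export
movement_constraints <- function(fixation = character(0), cages = list(),
                                 fixed_velocity = list(), kicks = list()) {
  for (cg in cages) stopifnot(length(cg) == 6L)
  for (kk in kicks) stopifnot(kk$frequency >= 1)
  structure(list(fixation = fixation, cages = cages,
                 fixed_velocity = fixed_velocity, kicks = kicks),
            class = "movement_constraints")
}

#' Harmonic bond table for a start configuration
#'
#' One harmonic spring per SPICES bond of the configuration. Protein shape
#' springs (backbone and segment distance forces) can be added with
#' \code{r0 = "start"}, which takes each bond's rest length from the start
#' geometry so the PDB-derived shape is preserved instead of collapsing.
#'
#' @param config a \code{start_configuration}.
#' @param k spring constant (reduced units), default 4.
#' @param r0 rest length in r_c (default 1), or \code{"start"} for
#'   per-bond start-geometry distances.
#' @return data.frame with columns i, j, k, r0 (1-based particle indices).
#' @export
harmonic_bonds <- function(config, k = 4, r0 = 1) {
  stopifnot(inherits(config, "start_configuration"))
  b <- config$bonds
  if (!nrow(b)) {
    return(data.frame(i = integer(0), j = integer(0), k = numeric(0),
                      r0 = numeric(0)))
  }
  if (identical(r0, "start")) {
    p <- as.matrix(config$particles[, c("x", "y", "z")])
    L <- config$box$edges
    d <- p[b[, 1], , drop = FALSE] - p[b[, 2], , drop = FALSE]
    for (ax in 1:3) {
      if (config$box$periodic[ax]) {
        d[, ax] <- d[, ax] - L[ax] * round(d[, ax] / L[ax])
      }
    }
    r0 <- sqrt(rowSums(d^2))
  }
  data.frame(i = b[, 1], j = b[, 2], k = k, r0 = r0)
}

#' Additional springs between indexed particles of a molecule type
#'
#' Implements molecule backbone forces: extra harmonic springs between the
#' particles carrying SPICES backbone indices within each molecule of the
#' given type.
#'
#' @param config a \code{start_configuration}.
#' @param molecule_type molecule type name.
#' @param pairs 2-column matrix of backbone index pairs.
#' @param k spring constant.
#' @param r0 rest length, or \code{"start"}.
#' @param graph the molecule's \code{spices_graph} (to resolve backbone
#'   indices to within-molecule particle offsets).
#' @return bond data.frame as in \code{\link{harmonic_bonds}}.
#' @export
indexed_molecule_bonds <- function(config, molecule_type, pairs, graph,
                                   k = 4, r0 = "start") {
  stopifnot(inherits(config, "start_configuration"))
  pairs <- rbind(pairs)
  bi <- graph$backbone_index
  out <- list()
  p <- as.matrix(config$particles[, c("x", "y", "z")])
  for (mid in unique(config$particles$molecule_id[
      config$particles$molecule_type == molecule_type])) {
    members <- which(config$particles$molecule_id == mid)
    for (r in seq_len(nrow(pairs))) {
      ii <- members[which(bi == pairs[r, 1])]
      jj <- members[which(bi == pairs[r, 2])]
      if (!length(ii) || !length(jj)) stop("backbone index not found in molecule")
      rr <- if (identical(r0, "start")) {
        sqrt(sum((p[ii, ] - p[jj, ])^2))
      } else r0
      out[[length(out) + 1L]] <- data.frame(i = ii, j = jj, k = k, r0 = rr)
    }
  }
  do.call(rbind, out)
}

# resolve particle-set data to per-particle arrays
prepare_system <- function(config, set, params) {
  types <- unique(config$particles$type)
  if (!is.null(set)) {
    # probe particles keep the interactions of the particle they replace;
    # unknown tokens fall back to the first declared type
    amat <- matrix(NA_real_, length(types), length(types),
                   dimnames = list(types, types))
    probe_map <- config$probe_map
    resolve <- function(tok) {
      if (tok %in% set$types$name) return(tok)
      if (!is.null(probe_map) && tok %in% names(probe_map)) {
        return(probe_map[[tok]])
      }
      set$types$name[1]
    }
    for (i in seq_along(types)) {
      for (j in i:length(types)) {
        amat[i, j] <- amat[j, i] <-
          repulsion(set, resolve(types[i]), resolve(types[j]), params$temperature)
      }
    }
    ref_mass <- set$types$mass[which.min(set$types$volume)]
    mass_of <- set$types$mass[match(vapply(types, resolve, ""), set$types$name)] / ref_mass
    charge_of <- set$types$charge[match(vapply(types, resolve, ""), set$types$name)]
  } else {
    amat <- matrix(25, length(types), length(types),
                   dimnames = list(types, types))
    mass_of <- rep(1, length(types))
    charge_of <- rep(0L, length(types))
  }
  ti <- match(config$particles$type, types) - 1L
  masses <- if (params$unit_mass) rep(1, nrow(config$particles)) else mass_of[ti + 1L]
  charges <- as.numeric(charge_of[ti + 1L])
  list(types = types, type_index = ti, a_matrix = amat, masses = masses,
       charges = charges)
}

#' Maxwell-Boltzmann initial velocities
#'
#' Draws velocities at the target temperature and removes the net momentum.
#'
#' @param n particle count.
#' @param masses per-particle masses.
#' @param kT target temperature.
#' @return n x 3 velocity matrix. Uses the R RNG; seed upstream.
#' @export
maxwell_velocities <- function(n, masses = rep(1, n), kT = 1) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT / rep(masses, 3))), n, 3)
  mom <- colSums(v * masses)
  sweep(v, 2, mom / sum(masses))
}

constraint_arrays <- function(config, constraints) {
  empty <- list(fixed_idx = integer(0), fixed_pos = matrix(0, 0, 3),
                cage_idx = integer(0), cage = matrix(0, 0, 6),
                fv_idx = integer(0), fv = matrix(0, 0, 3),
                kick_idx = integer(0), kick = matrix(0, 0, 3),
                kick_freq = integer(0))
  if (is.null(constraints)) return(empty)
  mt <- config$particles$molecule_type
  p <- as.matrix(config$particles[, c("x", "y", "z")])
  out <- empty
  fi <- which(mt %in% constraints$fixation)
  out$fixed_idx <- fi - 1L
  out$fixed_pos <- p[fi, , drop = FALSE]
  for (nm in names(constraints$cages)) {
    idx <- which(mt == nm)
    out$cage_idx <- c(out$cage_idx, idx - 1L)
    out$cage <- rbind(out$cage, matrix(rep(constraints$cages[[nm]],
                                           length(idx)),
                                       ncol = 6, byrow = TRUE))
  }
  for (nm in names(constraints$fixed_velocity)) {
    idx <- which(mt == nm)
    out$fv_idx <- c(out$fv_idx, idx - 1L)
    out$fv <- rbind(out$fv, matrix(rep(constraints$fixed_velocity[[nm]],
                                       length(idx)), ncol = 3, byrow = TRUE))
  }
  for (nm in names(constraints$kicks)) {
    idx <- which(mt == nm)
    out$kick_idx <- c(out$kick_idx, idx - 1L)
    out$kick <- rbind(out$kick, matrix(rep(constraints$kicks[[nm]]$velocity,
                                           length(idx)), ncol = 3, byrow = TRUE))
    out$kick_freq <- c(out$kick_freq, rep(as.integer(constraints$kicks[[nm]]$frequency),
                                          length(idx)))
  }
  out
}

#' Compute DPD forces for a configuration snapshot
#'
#' Evaluates the soft conservative repulsion F_C = a_ij (1 - r/r_c) e, the
#' dissipative force F_D = -gamma (1 - r/r_c)^2 (e . v_ij) e, the random
#' force F_R = sigma (1 - r/r_c) theta_ij dt^{-1/2} e, harmonic bond
#' forces, and optional fields. The pair noise theta_ij (zero mean, unit
#' variance, symmetric per pair) is a pure function of (seed, step, pair).
#'
#' @param positions,velocities n x 3 matrices (r_c, reduced units).
#' @param box a \code{box_spec}.
#' @param type_index 0-based particle type indices.
#' @param a_matrix symmetric repulsion matrix over types.
#' @param params a \code{simulation_parameters}.
#' @param bonds bond data.frame (i, j, k, r0) or NULL.
#' @param masses,charges per-particle vectors.
#' @param thermostat include dissipative and random forces.
#' @param step global step index keying the pair noise.
#' @param electrostatics list(coupling, cutoff, smear) or NULL.
#' @param gravity 3-vector acceleration.
#' @return list with \code{forces} (n x 3), \code{epot_pair},
#'   \code{epot_bond}, \code{virial} (diagonal, conservative part).
#' @export
dpd_forces <- function(positions, velocities, box, type_index, a_matrix,
                       params, bonds = NULL, masses = rep(1, nrow(positions)),
                       charges = rep(0, nrow(positions)), thermostat = TRUE,
                       step = 0, electrostatics = NULL, gravity = c(0, 0, 0)) {
  if (is.null(bonds) || !nrow(bonds)) {
    bm <- matrix(integer(0), 0, 2); bk <- numeric(0); br0 <- numeric(0)
  } else {
    bm <- cbind(as.integer(bonds$i) - 1L, as.integer(bonds$j) - 1L)
    n <- nrow(positions)
    if (any(bm < 0L) || any(bm >= n)) stop("bond index out of range")
    bk <- bonds$k; br0 <- bonds$r0
  }
  cpp_compute_forces(positions, velocities, box$edges, box$periodic,
                     as.integer(type_index), a_matrix, masses, charges,
                     params$gamma, params$sigma, params$dt, params$seed,
                     step, bm, bk, br0, thermostat,
                     !is.null(electrostatics),
                     if (is.null(electrostatics)) 0 else electrostatics$coupling,
                     if (is.null(electrostatics)) 3 else electrostatics$cutoff,
                     if (is.null(electrostatics)) 1 else electrostatics$smear,
                     gravity)
}

#' Run a DPD simulation
#'
#' Three phases: (1) \code{minimization_steps} of steepest descent on the
#' conservative + bond potential with per-step displacement capped at
#' 0.05 r_c and backtracking, so the energy never increases; (2)
#' \code{velocity_scaling_steps} of dynamics with exact instantaneous
#' temperature rescaling; (3) free DPD dynamics. Scalar series (kT with
#' 3N-3 degrees of freedom, kinetic and potential energy, surface tension
#' from the diagonal virial pressure anisotropy) are recorded at every
#' output step.
#'
#' @param config a \code{start_configuration}.
#' @param params a \code{simulation_parameters}.
#' @param set the \code{particle_set} providing repulsions, masses and
#'   charges (NULL: a_ij = 25, unit masses, no charges).
#' @param bonds bond data.frame (default: \code{harmonic_bonds(config)}).
#' @param constraints a \code{movement_constraints} or NULL.
#' @param velocities optional n x 3 start velocities (default:
#'   Maxwell-Boltzmann at the target kT, seeded from \code{params$seed}).
#' @param electrostatics optional list(coupling, cutoff, smear).
#' @param gravity acceleration vector, applied as m g per particle.
#' @return object of class \code{dpd_result}: \code{trajectory}
#'   (\code{dpd_trajectory}: frames, frame velocities, steps, box),
#'   \code{series} (data.frame step, kT, kineticEnergy, potentialEnergy,
#'   surfaceTension), \code{minimization} (energy series and frames),
#'   \code{final} (positions, velocities, step) and the run inputs for
#'   restarting.
#' @export
run_dynamics <- function(config, params, set = NULL, bonds = NULL,
                         constraints = NULL, velocities = NULL,
                         electrostatics = NULL, gravity = c(0, 0, 0)) {
  stopifnot(inherits(config, "start_configuration"),
            inherits(params, "simulation_parameters"))
  sys <- prepare_system(config, set, params)
  pos <- as.matrix(config$particles[, c("x", "y", "z")])
  n <- nrow(pos)
  if (is.null(velocities)) {
    set.seed(params$seed)
    velocities <- maxwell_velocities(n, sys$masses, params$kT)
  }
  if (is.null(bonds)) bonds <- harmonic_bonds(config)
  run_engine(config, params, sys, pos, velocities, bonds, constraints,
             electrostatics, gravity, step_offset = 0,
             scale_steps = params$velocity_scaling_steps,
             min_steps = params$minimization_steps,
             eval_velocities = velocities)
}

run_engine <- function(config, params, sys, pos, vel, bonds, constraints,
                       electrostatics, gravity, step_offset, scale_steps,
                       min_steps, eval_velocities = vel) {
  ca <- constraint_arrays(config, constraints)
  if (is.null(bonds) || !nrow(bonds)) {
    bm <- matrix(integer(0), 0, 2); bk <- numeric(0); br0 <- numeric(0)
  } else {
    bm <- cbind(as.integer(bonds$i) - 1L, as.integer(bonds$j) - 1L)
    bk <- bonds$k; br0 <- bonds$r0
  }
  res <- cpp_run_dynamics(pos, vel, config$box$edges, config$box$periodic,
                          sys$type_index, sys$a_matrix, sys$masses,
                          sys$charges, params$gamma, params$sigma, params$dt,
                          params$kT, params$steps, params$output_frequency,
                          min_steps, params$minimization_output,
                          scale_steps, bm, bk, br0,
                          ca$fixed_idx, ca$fixed_pos, ca$cage_idx, ca$cage,
                          ca$fv_idx, ca$fv, ca$kick_idx, ca$kick,
                          ca$kick_freq,
                          !is.null(electrostatics),
                          if (is.null(electrostatics)) 0 else electrostatics$coupling,
                          if (is.null(electrostatics)) 3 else electrostatics$cutoff,
                          if (is.null(electrostatics)) 1 else electrostatics$smear,
                          gravity,
                          if (params$integrator == "SCMVV") 1L else 0L,
                          params$lambda, params$seed, step_offset,
                          TRUE, eval_velocities)
  trajectory <- structure(list(frames = res$frames,
                               velocities = res$frames_vel,
                               steps = res$frame_steps,
                               box = config$box,
                               types = config$particles$type,
                               molecule_id = config$particles$molecule_id,
                               molecule_type = config$particles$molecule_type),
                          class = "dpd_trajectory")
  structure(list(trajectory = trajectory,
                 series = res$series,
                 minimization = list(energy = res$minimization_energy,
                                     frames = res$minimization_frames),
                 final = list(positions = res$final_pos,
                              velocities = res$final_vel,
                              eval_velocities = res$final_eval_vel,
                              step = res$final_step),
                 config = config, params = params, sys = sys, bonds = bonds,
                 constraints = constraints, electrostatics = electrostatics,
                 gravity = gravity),
            class = "dpd_result")
}

#' @export
print.dpd_result <- function(x, ...) {
  cat(sprintf("dpd_result: %d frame(s), final step %d, N = %d\n",
              length(x$trajectory$frames), as.integer(x$final$step),
              nrow(x$final$positions)))
  invisible(x)
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf("dpd_trajectory: %d frame(s), steps %s..%s, N = %d\n",
              length(x$frames), min(x$steps), max(x$steps),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0L))
  invisible(x)
}

#' Restart a completed simulation
#'
#' Continues from the final frame (positions, velocities, step counter and
#' the step-keyed pair noise are all carried forward, so a run of n steps
#' is bitwise identical to a run of k steps plus a restart of n - k).
#' Constraint and simulation-parameter edits are allowed; edits touching
#' the molecular composition or the spatial configuration are rejected,
#' since they would change the physical state mid-trajectory.
#'
#' @param result a \code{dpd_result}.
#' @param additional_steps number of steps to append.
#' @param edits named list; allowed names: \code{constraints},
#'   \code{output_frequency}, \code{kT}, \code{sigma}.
#' @return a new \code{dpd_result} whose series and trajectory continue
#'   the parent's step numbering.
#' @export
restart_dynamics <- function(result, additional_steps, edits = list()) {
  stopifnot(inherits(result, "dpd_result"), additional_steps >= 0)
  forbidden <- c("config", "composition", "positions", "counts", "box",
                 "molecules", "specs")
  bad <- intersect(names(edits), forbidden)
  if (length(bad)) {
    stop("restart cannot edit the molecular composition or spatial ",
         "configuration (rejected edit: ", paste(bad, collapse = ", "), ")")
  }
  allowed <- c("constraints", "output_frequency", "kT", "sigma")
  unknown <- setdiff(names(edits), allowed)
  if (length(unknown)) stop("unknown restart edit: ", paste(unknown, collapse = ", "))
  params <- result$params
  constraints <- result$constraints
  if ("constraints" %in% names(edits)) constraints <- edits$constraints
  if ("output_frequency" %in% names(edits)) {
    params$output_frequency <- as.integer(edits$output_frequency)
  }
  if ("kT" %in% names(edits)) params$kT <- edits$kT
  if ("sigma" %in% names(edits)) {
    params$sigma <- edits$sigma
    params$gamma <- edits$sigma^2 / (2 * params$kT)
  }
  params$steps <- as.integer(additional_steps)
  done <- result$final$step
  remaining_scaling <- max(0L, result$params$velocity_scaling_steps - as.integer(done))
  out <- run_engine(result$config, params, result$sys,
                    result$final$positions, result$final$velocities,
                    result$bonds, constraints, result$electrostatics,
                    result$gravity, step_offset = done,
                    scale_steps = remaining_scaling, min_steps = 0L,
                    eval_velocities = result$final$eval_velocities)
  out
}
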