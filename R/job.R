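#' A complete, valid default simulation job
#'
#' A fresh job is already a complete and valid simulation definition with
#' one species: the set's reference (smallest-volume, water-like)
#' particle. Quantity, density and box size are consistent; simulation
#' parameters are modest defaults suitable for a quick equilibration.
#'
#' @param set a non-empty \code{particle_set}.
#' @param quantity total particle count (default 3000).
#' @param density DPD density (default 3).
#' @param seed RNG seed.
#' @return object of class \code{job_input} with the four sections
#'   \code{general}, \code{chemical}, \code{interaction} and
#'   \code{simulation}, plus the derived \code{counts} and \code{box}.
#' @export
default_job <- function(set, quantity = 3000, density = 3, seed = 1L) {
  stopifnot(inherits(set, "particle_set"))
  if (!nrow(set$types)) stop("empty particle set")
  water <- set$types$name[which.min(set$types$volume)]
  job <- structure(list(
    general = list(description = "default job",
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    chemical = list(
      set = set,
      molecules = list(molecule_spec(water, water, amount = 100,
                                     unit = "molpercent", color = "blue")),
      quantity = as.integer(quantity),
      density = density,
      box_aspect = c(1, 1, 1),
      compartments = list(),
      movement = NULL,
      property_calculations = character(0)),
    interaction = list(temperature = 298, sigma = 3,
                       electrostatics = NULL, gravity = c(0, 0, 0),
                       bond_k = 4, bond_r0 = 1),
    simulation = list(steps = 100L, dt = 0.04, integrator = "GWMVV",
                      output_frequency = 10L, minimization_steps = 0L,
                      minimization_output = 0L,
                      periodic = c(TRUE, TRUE, TRUE), unit_mass = TRUE,
                      velocity_scaling_steps = 0L, rng_kind = "counter",
                      seed = as.integer(seed))),
    class = "job_input")
  update_cascade(job)
}

# directed top-down update: composition/quantity -> counts,
# quantity/density/aspect -> box size; one pass reaches the fixed point
update_cascade <- function(job) {
  job$counts <- composition_to_counts(job$chemical$molecules,
                                      job$chemical$quantity,
                                      job$chemical$set)
  job$box <- derive_box_size(job$chemical$quantity, job$chemical$density,
                             job$chemical$box_aspect,
                             job$simulation$periodic)
  job
}

#' @export
print.job_input <- function(x, ...) {
  cat(sprintf("job_input: %d species, %d particles at density %.3g, box %s\n",
              length(x$chemical$molecules), x$chemical$quantity,
              x$chemical$density,
              paste(signif(x$box$edges, 4), collapse = " x ")))
  rep <- validate_job(x)
  cat(sprintf("  %d error(s), %d hint(s)\n", length(rep$errors),
              length(rep$hints)))
  invisible(x)
}

#' Edit a job field with cascade updates
#'
#' Sets a field addressed by a dotted key and recomputes all subordinate
#' features top-down (quantity and density changes resize the box;
#' composition changes recompute molecule counts), then re-validates.
#'
#' @param job a \code{job_input}.
#' @param field dotted key, e.g. \code{"chemical.quantity"},
#'   \code{"chemical.density"}, \code{"simulation.steps"},
#'   \code{"interaction.sigma"}, \code{"chemical.molecules"}.
#' @param value the new value.
#' @return the updated \code{job_input}.
#' @export
apply_update <- function(job, field, value) {
  stopifnot(inherits(job, "job_input"))
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% names(job) ||
      !parts[2] %in% names(job[[parts[1]]])) {
    stop("unknown job field: ", field)
  }
  old <- job[[parts[1]]][[parts[2]]]
  if (!is.null(old) && is.numeric(old) && !is.numeric(value)) {
    stop("type mismatch for field ", field)
  }
  job[[parts[1]]][[parts[2]]] <- value
  job <- update_cascade(job)
  rep <- validate_job(job)
  if (length(rep$errors)) {
    warning("job now has validation error(s): ",
            paste(rep$errors, collapse = "; "))
  }
  job
}

#' Validate a job definition
#'
#' Errors block execution; hints flag possible shortcomings (for example
#' identical display colors for different molecules) but do not.
#'
#' @param job a \code{job_input}.
#' @return list with character vectors \code{errors} and \code{hints}.
#' @export
validate_job <- function(job) {
  stopifnot(inherits(job, "job_input"))
  errors <- character(0)
  hints <- character(0)
  set <- job$chemical$set
  if (job$chemical$quantity <= 0) errors <- c(errors, "quantity must be positive")
  if (job$chemical$density <= 0) errors <- c(errors, "density must be positive")
  if (job$simulation$dt <= 0) errors <- c(errors, "time step must be positive")
  if (job$simulation$output_frequency < 1) {
    errors <- c(errors, "output frequency must be at least 1")
  }
  for (ms in job$chemical$molecules) {
    unknown <- setdiff(ms$graph$particles, set$types$name)
    if (length(unknown)) {
      errors <- c(errors, paste0("molecule ", ms$name,
                                 " uses undeclared particle(s): ",
                                 paste(unknown, collapse = ", ")))
    }
  }
  # interaction coverage at the job temperature
  toks <- unique(unlist(lapply(job$chemical$molecules,
                               function(m) m$graph$particles)))
  toks <- intersect(toks, set$types$name)
  for (i in seq_along(toks)) {
    for (j in i:length(toks)) {
      ok <- tryCatch({
        repulsion(set, toks[i], toks[j], job$interaction$temperature)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        errors <- c(errors, paste0("missing interaction entry for pair ",
                                   toks[i], "-", toks[j]))
      }
    }
  }
  for (ci in seq_along(job$chemical$compartments)) {
    cp <- job$chemical$compartments[[ci]]
    if (!compartment_in_box(cp, job$box)) {
      errors <- c(errors, paste0("compartment ", ci, " lies outside the box"))
    } else {
      requested <- sum(vapply(cp$contents, function(ct)
        ct$count * length(ct$spec$graph$particles), 1))
      capacity <- round(job$chemical$density * compartment_volume(cp, job$box))
      if (requested > capacity) {
        errors <- c(errors, sprintf(
          "compartment %d overfilled: %d particles requested, capacity %d",
          ci, as.integer(requested), as.integer(capacity)))
      }
    }
  }
  cols <- vapply(job$chemical$molecules, function(m) m$color, "")
  cols <- cols[!is.na(cols)]
  if (anyDuplicated(cols)) {
    hints <- c(hints, "different molecules share a display color")
  }
  list(errors = errors, hints = hints)
}

job_parameters <- function(job) {
  simulation_parameters(
    steps = job$simulation$steps, dt = job$simulation$dt,
    kT = 1, sigma = job$interaction$sigma,
    output_frequency = job$simulation$output_frequency,
    integrator = job$simulation$integrator,
    minimization_steps = job$simulation$minimization_steps,
    minimization_output = job$simulation$minimization_output,
    velocity_scaling_steps = job$simulation$velocity_scaling_steps,
    unit_mass = job$simulation$unit_mass,
    periodic = job$simulation$periodic,
    temperature = job$interaction$temperature,
    rng_kind = job$simulation$rng_kind,
    seed = job$simulation$seed)
}

# flat text serialization of a job (dotted keys) for workspace storage
serialize_job <- function(job) {
  lines <- c("[General]",
             paste0("description = ", job$general$description),
             paste0("timestamp = ", job$general$timestamp),
             "", "[ChemicalSystem]",
             paste0("particleSet = ", job$chemical$set$name),
             paste0("quantity = ", job$chemical$quantity),
             paste0("density = ", format(job$chemical$density)),
             paste0("boxAspect = ", paste(job$chemical$box_aspect, collapse = " ")),
             paste0("boxSize = ", paste(format(job$box$edges), collapse = " ")))
  for (m in job$chemical$molecules) {
    lines <- c(lines, sprintf("molecule.%s = %s | %s %s", m$name,
                              write_spices(m$graph), format(m$amount), m$unit))
  }
  lines <- c(lines, "", "[Interaction]",
             paste0("temperature = ", job$interaction$temperature),
             paste0("randomForceMagnitude = ", job$interaction$sigma),
             paste0("electrostatics = ",
                    if (is.null(job$interaction$electrostatics)) "off" else "on"),
             paste0("gravity = ", paste(job$interaction$gravity, collapse = " ")),
             "", "[Simulation]")
  for (key in names(job$simulation)) {
    lines <- c(lines, sprintf("%s = %s", key,
                              paste(format(job$simulation[[key]]), collapse = " ")))
  }
  lines
}

#' Execute a job in a workspace
#'
#' Refuses invalid jobs, builds the start configuration, runs the
#' dynamics, runs the configured property calculations, and stores the
#' outcome under \code{workspace/JobResults/<id>} with a copy of the
#' serialized input under \code{workspace/JobInputs/<id>}.
#'
#' @param job a \code{job_input} validating with zero errors.
#' @param workspace workspace directory (created if missing).
#' @param id result identifier (default: derived from the timestamp).
#' @param progress optional function(fraction) called after the run.
#' @return object of class \code{job_result}: list with \code{id},
#'   \code{input_digest}, \code{result} (a \code{dpd_result}),
#'   \code{analyses}, \code{status}, \code{lineage}, \code{path}.
#' @export
execute_job <- function(job, workspace, id = NULL, progress = NULL) {
  rep <- validate_job(job)
  if (length(rep$errors)) {
    stop("invalid job is not allowed to be executed: ",
         paste(rep$errors, collapse = "; "))
  }
  if (is.null(id)) id <- format(Sys.time(), "job_%Y%m%d_%H%M%OS3")
  dir.create(file.path(workspace, "JobInputs", id), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(workspace, "JobResults", id), recursive = TRUE,
             showWarnings = FALSE)
  in_path <- file.path(workspace, "JobInputs", id, "job.txt")
  writeLines(serialize_job(job), in_path)
  digest <- unname(tools::md5sum(in_path))

  set.seed(job$simulation$seed)
  config <- build_start_configuration(
    specs = job$chemical$molecules, counts = job$counts, box = job$box,
    compartments = job$chemical$compartments, set = job$chemical$set,
    seed = job$simulation$seed)
  params <- job_parameters(job)
  bonds <- harmonic_bonds(config, k = job$interaction$bond_k,
                          r0 = job$interaction$bond_r0)
  status <- "completed"
  run <- tryCatch(
    run_dynamics(config, params, set = job$chemical$set, bonds = bonds,
                 constraints = job$chemical$movement,
                 electrostatics = job$interaction$electrostatics,
                 gravity = job$interaction$gravity),
    error = function(e) {
      status <<- paste0("failed: ", conditionMessage(e))
      NULL
    })
  analyses <- list()
  if (!is.null(run)) {
    for (pc in job$chemical$property_calculations) {
      analyses[[pc]] <- switch(pc,
        rdf = {
          tok <- run$trajectory$types[1]
          rdf(run$trajectory, c(tok, tok))
        },
        rg = radius_of_gyration(run$trajectory),
        neighbors = nearest_neighbors(run$trajectory),
        NULL)
    }
  }
  res <- structure(list(id = id, input_digest = digest, result = run,
                        analyses = analyses, status = status,
                        lineage = character(0),
                        path = file.path(workspace, "JobResults", id)),
                   class = "job_result")
  if (!is.null(run)) write_job_result(res, workspace)
  if (!is.null(progress)) progress(1)
  res
}

write_job_result <- function(res, workspace) {
  dir <- file.path(workspace, "JobResults", res$id)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  run <- res$result
  tr <- run$trajectory
  for (f in seq_along(tr$frames)) {
    write_xyz(tr$frames[[f]], file.path(dir, "frames",
                                        sprintf("frame_%08d.xyz", as.integer(tr$steps[f]))),
              types = tr$types, molecule_id = tr$molecule_id, box = tr$box,
              step = tr$steps[f])
  }
  utils::write.table(run$series, file.path(dir, "series.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(id = res$id, input_digest = res$input_digest,
               status = res$status, lineage = res$lineage,
               box = run$config$box$edges,
               density = run$config$box$density,
               periodic = run$config$box$periodic,
               final_step = run$final$step,
               n_particles = nrow(run$final$positions))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-read a stored job result
#'
#' @param workspace workspace directory.
#' @param id job result id.
#' @return list with \code{metadata}, \code{series} and \code{trajectory}
#'   (frames re-read from the stored extended-XYZ files).
#' @export
read_job_result <- function(workspace, id) {
  dir <- file.path(workspace, "JobResults", id)
  if (!dir.exists(dir)) stop("no such job result: ", id)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  series <- utils::read.table(file.path(dir, "series.tsv"), sep = "\t",
                              header = TRUE)
  files <- sort(list.files(file.path(dir, "frames"), full.names = TRUE))
  frames <- lapply(files, read_xyz)
  tr <- structure(list(frames = lapply(frames, `[[`, "positions"),
                       velocities = list(),
                       steps = vapply(frames, `[[`, 1, "step"),
                       box = frames[[1]]$box,
                       types = frames[[1]]$types,
                       molecule_id = frames[[1]]$molecule_id,
                       molecule_type = frames[[1]]$types),
                  class = "dpd_trajectory")
  list(metadata = meta, series = series, trajectory = tr)
}

#' Restart a stored job result
#'
#' Continues the parent's dynamics for additional steps; edits of the
#' molecular composition or spatial configuration are rejected, while
#' movement-constraint edits (the relaxation-pipeline case: remove a
#' fixation before restarting) are allowed.
#'
#' @param res a \code{job_result} with a completed run.
#' @param additional_steps steps to append.
#' @param edits passed to \code{\link{restart_dynamics}}.
#' @param workspace workspace directory for the new result.
#' @return a new \code{job_result} whose lineage links to the parent.
#' @export
restart_job <- function(res, additional_steps, edits = list(),
                        workspace = dirname(dirname(res$path))) {
  stopifnot(inherits(res, "job_result"))
  if (res$status != "completed") stop("only completed results can be restarted")
  run2 <- restart_dynamics(res$result, additional_steps, edits)
  id <- paste0(res$id, "_r", as.integer(run2$final$step))
  out <- structure(list(id = id, input_digest = res$input_digest,
                        result = run2, analyses = list(),
                        status = "completed",
                        lineage = c(res$lineage, res$id),
                        path = file.path(workspace, "JobResults", id)),
                   class = "job_result")
  dir.create(out$path, recursive = TRUE, showWarnings = FALSE)
  write_job_result(out, workspace)
  out
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("job_result %s: %s, final step %s\n", x$id, x$status,
              if (is.null(x$result)) "-" else as.integer(x$result$final$step)))
  invisible(x)
}
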