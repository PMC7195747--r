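test_that("a fresh default job is complete and valid with one species", {
  minimal <- parse_particle_set(c("[Particle description]", "H2O 18 0 30",
                                  "[Particle interactions]", "pair 298",
                                  "H2O_H2O 25"), name = "H2O")
  job <- default_job(minimal)
  rep <- validate_job(job)
  expect_equal(length(rep$errors), 0L)
  expect_equal(length(job$chemical$molecules), 1L)
  expect_equal(job$chemical$molecules[[1]]$graph$particles, "H2O")
  # quantity/density/box consistency
  expect_equal(prod(job$box$edges), job$chemical$quantity / job$chemical$density)
  expect_error(default_job(structure(list(
    name = "empty", types = data.frame(name = character(0)),
    interactions = NULL, amino_acids = NULL), class = "particle_set")),
    "empty")
})

test_that("update cascades recompute subordinate features top-down", {
  job <- default_job(toy_set, quantity = 375)
  job2 <- apply_update(job, "chemical.quantity", 3000)
  expect_equal(job2$box$edges, c(10, 10, 10))
  expect_equal(sum(job2$counts), 3000)
  job3 <- apply_update(job2, "chemical.density", 3 / 8)
  expect_equal(job3$box$edges, c(20, 20, 20))
  # a field without dependents changes nothing else
  job4 <- apply_update(job2, "simulation.steps", 42L)
  expect_equal(job4$simulation$steps, 42L)
  expect_equal(job4$box$edges, job2$box$edges)
  expect_error(apply_update(job, "nope.field", 1), "unknown job field")
  expect_error(apply_update(job, "chemical.quantity", "many"), "type mismatch")
  # cascades are confluent: edit order does not matter
  a <- apply_update(apply_update(job, "chemical.quantity", 3000),
                    "chemical.density", 6)
  b <- apply_update(apply_update(job, "chemical.density", 6),
                    "chemical.quantity", 3000)
  expect_equal(a$box$edges, b$box$edges)
  expect_equal(a$counts, b$counts)
})

test_that("validation distinguishes blocking errors from hints", {
  job <- default_job(toy_set, quantity = 375)
  # overfilled compartment is an error naming the compartment
  cp <- compartment("sphere", center = c(2.5, 2.5, 2.5), radius = 1,
                    contents = list(list(
                      spec = molecule_spec("w", "H2O", 1, "count"),
                      count = 1000, orientation = "random")))
  job$chemical$compartments <- list(cp)
  rep <- validate_job(job)
  expect_true(any(grepl("compartment 1 overfilled", rep$errors)))
  # shared colors are a hint, not an error
  job2 <- default_job(toy_set, quantity = 375)
  job2$chemical$molecules <- list(
    molecule_spec("a", "H2O", 50, "molpercent", color = "red"),
    molecule_spec("b", "BB", 50, "molpercent", color = "red"))
  job2 <- dpdfrag:::update_cascade(job2)
  rep2 <- validate_job(job2)
  expect_equal(length(rep2$errors), 0L)
  expect_true(any(grepl("color", rep2$hints)))
})

test_that("execution writes a workspace layout that round-trips", {
  ws <- file.path(tempdir(), paste0("ws", as.integer(runif(1, 1, 1e8))))
  job <- default_job(toy_set, quantity = 192, seed = 5)
  job$simulation$steps <- 10L
  job$simulation$output_frequency <- 5L
  res <- execute_job(job, ws, id = "t1")
  expect_equal(res$status, "completed")
  expect_true(file.exists(file.path(ws, "JobInputs", "t1", "job.txt")))
  expect_true(file.exists(file.path(ws, "JobResults", "t1", "metadata.json")))
  expect_gte(length(res$result$trajectory$frames), 1L)
  expect_equal(nrow(res$result$series), length(res$result$trajectory$frames))
  back <- read_job_result(ws, "t1")
  expect_equal(back$metadata$input_digest, res$input_digest)
  expect_equal(back$series, res$result$series, tolerance = 1e-9)
  expect_equal(length(back$trajectory$frames),
               length(res$result$trajectory$frames))
  expect_equal(back$trajectory$frames[[1]], res$result$trajectory$frames[[1]],
               tolerance = 1e-9, ignore_attr = TRUE)
  # identical seeds give identical trajectories
  res2 <- execute_job(job, ws, id = "t2")
  expect_identical(res$result$final$positions, res2$result$final$positions)
  unlink(ws, recursive = TRUE)
})

test_that("invalid jobs are refused before any output", {
  ws <- file.path(tempdir(), paste0("ws", as.integer(runif(1, 1, 1e8))))
  job <- default_job(toy_set, quantity = 375)
  job$chemical$quantity <- -5
  job <- dpdfrag:::update_cascade(default_job(toy_set, quantity = 375))
  job$simulation$dt <- -1
  expect_error(execute_job(job, ws, id = "bad"), "not allowed")
  expect_false(dir.exists(file.path(ws, "JobResults", "bad", "frames")))
  unlink(ws, recursive = TRUE)
})

test_that("job restarts continue the lineage and reject composition edits", {
  ws <- file.path(tempdir(), paste0("ws", as.integer(runif(1, 1, 1e8))))
  job <- default_job(toy_set, quantity = 192, seed = 6)
  job$simulation$steps <- 10L
  job$simulation$output_frequency <- 5L
  res <- execute_job(job, ws, id = "p")
  r2 <- restart_job(res, 10)
  expect_equal(r2$lineage, "p")
  expect_equal(r2$result$final$step, 20)
  expect_error(restart_job(res, 5, edits = list(composition = 1)),
               "composition")
  # constraint removal is an allowed restart edit
  r3 <- restart_job(res, 5, edits = list(constraints = movement_constraints()))
  expect_equal(r3$result$final$step, 15)
  # zero additional steps reproduce the parent state
  r0 <- restart_job(res, 0)
  expect_identical(r0$result$final$positions, res$result$final$positions)
  unlink(ws, recursive = TRUE)
})

test_that("fixtures are deterministic and usable", {
  d <- tempdir()
  f1 <- make_fixtures("particle-set", d, seed = 1)
  set <- parse_particle_set(f1, is_path = TRUE)
  expect_equal(nrow(set$types), 4L)
  expect_equal(nrow(set$amino_acids), 5L)

  f2 <- make_fixtures("pdb", d, seed = 1)
  m <- parse_pdb(f2, is_path = TRUE)
  expect_equal(nrow(m$residues), 3L)

  f3 <- make_fixtures("job", d, seed = 1)
  expect_true(any(grepl("\\[Simulation\\]", readLines(f3))))

  f4 <- make_fixtures("two-slab-config", d, seed = 1)
  frame <- read_xyz(f4)
  expect_equal(nrow(frame$positions), round(3 * prod(frame$box$edges)))

  # byte-identical for equal seeds
  d2 <- file.path(tempdir(), "fx2"); dir.create(d2, showWarnings = FALSE)
  f4b <- make_fixtures("two-slab-config", d2, seed = 1)
  expect_identical(readLines(f4), readLines(f4b))
  expect_error(make_fixtures("nope", d), "arg")
})

test_that("XYZ round trips preserve geometry and box metadata", {
  cfg <- random_fluid_config(50, density = 3, seed = 7)
  path <- tempfile(fileext = ".xyz")
  write_xyz(cfg, path)
  back <- read_xyz(path)
  expect_equal(back$positions,
               unname(as.matrix(cfg$particles[, c("x", "y", "z")])),
               tolerance = 1e-9)
  expect_equal(back$box$edges, cfg$box$edges)
  expect_equal(back$types, cfg$particles$type)
  cfg2 <- xyz_to_configuration(back)
  expect_s3_class(cfg2, "start_configuration")
  expect_equal(nrow(cfg2$particles), 50L)
})
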