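test_that("pair forces match the formula and the brute-force oracle", {
  # two particles at half cutoff, a = 25: |F_C| = 12.5, opposite
  cfg <- dimer_config(sep = 0.5)
  cfg$bonds <- matrix(integer(0), 0, 2)
  p <- simulation_parameters(sigma = 0)
  a <- matrix(25, 1, 1, dimnames = list("H2O", "H2O"))
  pos <- as.matrix(cfg$particles[, c("x", "y", "z")])
  f <- dpd_forces(pos, pos * 0, cfg$box, c(0L, 0L), a, p, thermostat = FALSE)
  expect_equal(f$forces[1, 1], -12.5)
  expect_equal(f$forces[2, 1], 12.5)
  expect_equal(f$forces[, 2:3], matrix(0, 2, 2))
  expect_equal(f$epot_pair, 25 / 2 * 0.25)  # (a/2)(1-r)^2

  # at the cutoff all components vanish
  cfg2 <- dimer_config(sep = 1)
  pos2 <- as.matrix(cfg2$particles[, c("x", "y", "z")])
  f2 <- dpd_forces(pos2, pos2 * 0, cfg2$box, c(0L, 0L), a, p, thermostat = FALSE)
  expect_equal(f2$forces, matrix(0, 2, 3))

  # cell-list forces equal the all-pairs R oracle to machine precision
  cfgN <- random_fluid_config(200, density = 3, seed = 21)
  posN <- as.matrix(cfgN$particles[, c("x", "y", "z")])
  ti <- rep(0L, 200)
  aN <- matrix(25, 1, 1, dimnames = list("H2O", "H2O"))
  fN <- dpd_forces(posN, posN * 0, cfgN$box, ti, aN, p, thermostat = FALSE)
  bf <- bf_pair_forces(posN, cfgN$box, ti, aN)
  expect_equal(fN$forces, bf$forces, tolerance = 1e-12)
  expect_equal(fN$epot_pair, bf$epot, tolerance = 1e-12)
})

test_that("forces obey Newton's third law including the stochastic parts", {
  cfg <- random_fluid_config(300, density = 3, seed = 31)
  pos <- as.matrix(cfg$particles[, c("x", "y", "z")])
  set.seed(31)
  vel <- matrix(rnorm(900), 300, 3)
  p <- simulation_parameters(sigma = 3, seed = 31)
  a <- matrix(25, 1, 1, dimnames = list("H2O", "H2O"))
  f <- dpd_forces(pos, vel, cfg$box, rep(0L, 300), a, p, thermostat = TRUE,
                  step = 17)
  expect_lt(max(abs(colSums(f$forces))), 1e-10)
})

test_that("the conservative force is the gradient of the pair potential", {
  p <- simulation_parameters(sigma = 0)
  a <- matrix(25, 1, 1, dimnames = list("H2O", "H2O"))
  box <- box_spec(c(20, 20, 20))
  set.seed(5)
  for (k in 1:20) {
    r <- runif(1, 0.05, 0.95)
    pos <- rbind(c(10, 10, 10), c(10 + r, 10, 10))
    h <- 1e-6
    e_plus <- dpd_forces(rbind(c(10, 10, 10), c(10 + r + h, 10, 10)),
                         pos * 0, box, c(0L, 0L), a, p,
                         thermostat = FALSE)$epot_pair
    e_minus <- dpd_forces(rbind(c(10, 10, 10), c(10 + r - h, 10, 10)),
                          pos * 0, box, c(0L, 0L), a, p,
                          thermostat = FALSE)$epot_pair
    fx <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p,
                     thermostat = FALSE)$forces[2, 1]
    expect_equal(fx, -(e_plus - e_minus) / (2 * h), tolerance = 1e-6)
  }
})

test_that("bond forces follow Hooke's law across periodic boundaries", {
  p <- simulation_parameters(sigma = 0)
  a <- matrix(0, 1, 1, dimnames = list("H2O", "H2O"))
  box <- box_spec(c(5, 5, 5))
  bonds <- data.frame(i = 1L, j = 2L, k = 4, r0 = 0)
  pos <- rbind(c(1, 1, 1), c(1.5, 1, 1))
  f <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p, bonds = bonds,
                  thermostat = FALSE)
  expect_equal(abs(f$forces[1, 1]), 2)  # k r = 4 * 0.5
  expect_equal(f$epot_bond, 0.5 * 4 * 0.25)
  # at rest length the force vanishes
  b1 <- data.frame(i = 1L, j = 2L, k = 4, r0 = 0.5)
  f1 <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p, bonds = b1,
                   thermostat = FALSE)
  expect_equal(f1$forces, matrix(0, 2, 3))
  # bond across the boundary uses the wrapped distance (0.4, not 4.6)
  posw <- rbind(c(0.2, 1, 1), c(4.8, 1, 1))
  fw <- dpd_forces(posw, posw * 0, box, c(0L, 0L), a, p, bonds = bonds,
                   thermostat = FALSE)
  expect_equal(abs(fw$forces[1, 1]), 4 * 0.4, tolerance = 1e-12)
  expect_error(dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p,
                          bonds = data.frame(i = 1L, j = 9L, k = 4, r0 = 0)),
               "out of range")
})

test_that("optional field forces behave physically", {
  p <- simulation_parameters(sigma = 0)
  a <- matrix(0, 1, 1, dimnames = list("H2O", "H2O"))
  box <- box_spec(c(20, 20, 20))
  pos <- rbind(c(9, 10, 10), c(11, 10, 10))
  # neutral pair: no electrostatic force
  f0 <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p, charges = c(0, 0),
                   thermostat = FALSE,
                   electrostatics = list(coupling = 10, cutoff = 3, smear = 1))
  expect_equal(f0$forces, matrix(0, 2, 3))
  # opposite charges attract: force on + points toward -
  f1 <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p, charges = c(1, -1),
                   thermostat = FALSE,
                   electrostatics = list(coupling = 10, cutoff = 3, smear = 1))
  expect_gt(f1$forces[1, 1], 0)
  expect_lt(f1$forces[2, 1], 0)
  # gravity sums to g * total mass
  fg <- dpd_forces(pos, pos * 0, box, c(0L, 0L), a, p,
                   masses = c(2, 3), thermostat = FALSE,
                   gravity = c(0, 0, -5))
  expect_equal(colSums(fg$forces), c(0, 0, -25))
})

test_that("free flight and the harmonic dimer integrate correctly", {
  # free particle: displacement v dt per step
  cfg <- dimer_config(sep = 5)   # beyond cutoff, no bond
  cfg$bonds <- matrix(integer(0), 0, 2)
  p <- simulation_parameters(steps = 10, dt = 0.1, sigma = 0,
                             output_frequency = 10, seed = 1)
  vel <- rbind(c(0.3, 0, 0), c(0, 0.2, 0))
  r <- run_dynamics(cfg, p, set = NULL, velocities = vel,
                    bonds = data.frame(i = integer(0), j = integer(0),
                                       k = numeric(0), r0 = numeric(0)))
  # a = 25 still acts? pair separated by 5 r_c: no interaction
  expect_equal(r$final$positions[1, 1] - cfg$particles$x[1], 0.3 * 1,
               tolerance = 1e-12)

  # all-zero velocities and forces: state unchanged except the step counter
  cfg0 <- dimer_config(sep = 5)
  cfg0$bonds <- matrix(integer(0), 0, 2)
  r0 <- run_dynamics(cfg0, p, set = NULL, velocities = vel * 0,
                     bonds = data.frame(i = integer(0), j = integer(0),
                                        k = numeric(0), r0 = numeric(0)))
  expect_equal(r0$final$positions,
               as.matrix(cfg0$particles[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_equal(r0$final$step, 10)

  # harmonic dimer (thermostat off): period within 1% of 2 pi sqrt(mu/k)
  k_spring <- 4
  cfgd <- dimer_config(sep = 1.3)
  dt <- 0.002
  pd <- simulation_parameters(steps = 2500, dt = dt, sigma = 0,
                              output_frequency = 1, seed = 1)
  bonds <- data.frame(i = 1L, j = 2L, k = k_spring, r0 = 1)
  # an interaction-free set so only the spring acts
  zero_set <- parse_particle_set(c("[Particle description]", "H2O 18 0 30",
                                   "[Particle interactions]", "pair 298",
                                   "H2O_H2O 0"))
  rd <- run_dynamics(cfgd, pd, set = zero_set, bonds = bonds,
                     velocities = matrix(0, 2, 3))
  dist <- vapply(rd$trajectory$frames, function(f)
    abs(f[2, 1] - f[1, 1]), 1)
  # period from successive maxima of the separation
  mx <- which(diff(sign(diff(dist))) < 0) + 1L
  periods <- diff(rd$trajectory$steps[mx]) * dt
  expected <- 2 * pi * sqrt(0.5 / k_spring)
  expect_lt(abs(mean(periods) - expected) / expected, 0.01)
})

test_that("movement constraints hold fixed, caged and driven molecules", {
  set.seed(7)
  box <- derive_box_size(375, 3)
  wall <- molecule_spec("wall", "BB", 20, "count")
  wat <- molecule_spec("water", "H2O", 1, "count")
  cfg <- build_start_configuration(list(wall, wat), c(wall = 20, water = 1),
                                   box, set = toy_set, seed = 7)
  p <- simulation_parameters(steps = 100, output_frequency = 20, seed = 7)
  cons <- movement_constraints(fixation = "wall")
  r <- run_dynamics(cfg, p, set = toy_set, constraints = cons)
  idx <- cfg$particles$molecule_type == "wall"
  expect_identical(unname(r$final$positions[idx, ]),
                   unname(as.matrix(cfg$particles[idx, c("x", "y", "z")])))

  cage <- movement_constraints(cages = list(wall = c(1, 4, 1, 4, 1, 4)))
  # place the caged molecules inside the cage first
  cfg2 <- cfg
  cfg2$particles[idx, c("x", "y", "z")] <- 2.5
  r2 <- run_dynamics(cfg2, p, set = toy_set, constraints = cage)
  for (f in r2$trajectory$frames) {
    expect_true(all(f[idx, ] >= 1 - 1e-9 & f[idx, ] <= 4 + 1e-9))
  }

  # fixed velocity: displacement v t dt in an empty direction
  cfg3 <- dimer_config(sep = 5)
  cfg3$bonds <- matrix(integer(0), 0, 2)
  p3 <- simulation_parameters(steps = 50, dt = 0.01, sigma = 0,
                              output_frequency = 50, seed = 1)
  cons3 <- movement_constraints(fixed_velocity = list(dimer = c(0, 0, 0.1)))
  r3 <- run_dynamics(cfg3, p3, set = NULL, velocities = matrix(0, 2, 3),
                     constraints = cons3,
                     bonds = data.frame(i = integer(0), j = integer(0),
                                        k = numeric(0), r0 = numeric(0)))
  expect_equal(r3$final$positions[1, 3] - cfg3$particles$z[1],
               0.1 * 50 * 0.01, tolerance = 1e-9)
})

test_that("velocity scaling pins the instantaneous temperature exactly", {
  cfg <- random_fluid_config(375, density = 3, seed = 13)
  p <- simulation_parameters(steps = 20, output_frequency = 1,
                             velocity_scaling_steps = 20, seed = 13)
  r <- run_dynamics(cfg, p, set = NULL)
  n <- 375
  for (f in seq_along(r$trajectory$velocities)) {
    if (r$trajectory$steps[f] == 0) next
    v <- r$trajectory$velocities[[f]]
    kT <- sum(v^2) / (3 * n - 3)
    expect_equal(kT, 1, tolerance = 1e-12)
  }
})

test_that("minimization monotonically lowers the potential energy", {
  cfg <- random_fluid_config(375, density = 3, seed = 17)
  p <- simulation_parameters(steps = 0, minimization_steps = 50,
                             minimization_output = 10, seed = 17)
  r <- run_dynamics(cfg, p, set = NULL)
  e <- r$minimization$energy
  expect_gt(length(e), 2)
  expect_true(all(diff(e) <= 1e-9))
  expect_lt(e[length(e)], e[1])
})

test_that("zero steps yield a single-frame trajectory", {
  cfg <- random_fluid_config(100, density = 3, seed = 1)
  p <- simulation_parameters(steps = 0, seed = 1)
  r <- run_dynamics(cfg, p, set = NULL)
  expect_equal(length(r$trajectory$frames), 1L)
  expect_equal(r$trajectory$steps, 0)
})

test_that("restart continues bitwise and rejects composition edits", {
  cfg <- random_fluid_config(375, density = 3, seed = 23)
  pfull <- simulation_parameters(steps = 120, output_frequency = 40, seed = 23)
  rfull <- run_dynamics(cfg, pfull, set = NULL)
  ppart <- simulation_parameters(steps = 70, output_frequency = 40, seed = 23)
  rpart <- run_dynamics(cfg, ppart, set = NULL)
  rcont <- restart_dynamics(rpart, 50)
  expect_identical(rfull$final$positions, rcont$final$positions)
  expect_identical(rfull$final$velocities, rcont$final$velocities)
  expect_equal(rcont$final$step, 120)
  # zero additional steps leave the state untouched
  r0 <- restart_dynamics(rpart, 0)
  expect_identical(r0$final$positions, rpart$final$positions)
  expect_error(restart_dynamics(rpart, 10, edits = list(composition = 1)),
               "composition")
  # constraint edits are allowed (relaxation-pipeline case)
  rc <- restart_dynamics(rpart, 10,
                         edits = list(constraints = movement_constraints()))
  expect_equal(rc$final$step, 80)
})

test_that("divergence is reported with the step number", {
  # a stiff spring with a grossly oversized time step in an open box is
  # numerically unstable: the oscillation amplifies geometrically
  cfg <- dimer_config(sep = 0.5)
  cfg$box <- box_spec(c(20, 20, 20), periodic = c(FALSE, FALSE, FALSE))
  p <- simulation_parameters(steps = 500, dt = 1, sigma = 0,
                             output_frequency = 100, seed = 1)
  expect_error(run_dynamics(cfg, p, set = NULL, velocities = matrix(0, 2, 3),
                            bonds = data.frame(i = 1L, j = 2L, k = 100, r0 = 0)),
               "diverged at step")
})
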