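water_spec <- molecule_spec("water", "H2O", amount = 100, unit = "molpercent")

test_that("composition conversion handles count and relative units", {
  a <- molecule_spec("a", "H2O-H2O", amount = 50, unit = "molpercent")
  b <- molecule_spec("b", "BB-BB", amount = 50, unit = "molpercent")
  counts <- composition_to_counts(list(a, b), 1000, toy_set)
  expect_equal(unname(counts), c(250L, 250L))  # 2 particles per molecule

  cnt <- molecule_spec("w", "H2O", amount = 42, unit = "count")
  expect_equal(unname(composition_to_counts(list(cnt))), 42L)

  # weight-percent with equal molar masses reduces to mol-percent
  c1 <- molecule_spec("c1", "SC-SC", amount = 30, unit = "weightpercent")
  c2 <- molecule_spec("c2", "SCQ-SCQ", amount = 70, unit = "weightpercent")
  m1 <- molecule_spec("m1", "SC-SC", amount = 30, unit = "molpercent")
  m2 <- molecule_spec("m2", "SCQ-SCQ", amount = 70, unit = "molpercent")
  expect_equal(unname(composition_to_counts(list(c1, c2), 600, toy_set)),
               unname(composition_to_counts(list(m1, m2), 600, toy_set)))

  expect_error(composition_to_counts(list(cnt, a), 100, toy_set), "mixed")
  expect_error(composition_to_counts(list(a, b), NULL, toy_set), "total")
})

test_that("box sizing conserves volume for any aspect", {
  b <- derive_box_size(3000, 3)
  expect_equal(b$edges, c(10, 10, 10))
  b2 <- derive_box_size(3000, 3, aspect = c(1, 1, 4))
  expect_equal(prod(b2$edges), 1000)
  expect_equal(b2$edges[3] / b2$edges[1], 4)
  expect_equal(round(b2$density * prod(b2$edges)), 3000)
  expect_error(derive_box_size(3000, 3, aspect = c(1, 0, 1)), "positive")
})

test_that("bulk-only configurations hit the exact density count", {
  box <- derive_box_size(3000, 3)
  cfg <- build_start_configuration(list(water_spec), c(water = 1), box,
                                   set = toy_set, seed = 11)
  expect_equal(nrow(cfg$particles), 3000L)
  p <- as.matrix(cfg$particles[, c("x", "y", "z")])
  expect_true(all(p >= 0 & p <= 10))
})

test_that("sphere compartments are filled at density, contents stay inside", {
  box <- derive_box_size(3000, 3)
  r <- (100 * 3 / (4 * pi))^(1 / 3)  # volume 100 r_c^3
  n_in <- round(3 * 4 / 3 * pi * r^3)
  cp <- compartment("sphere", center = c(5, 5, 5), radius = r,
                    contents = list(list(
                      spec = molecule_spec("inwater", "H2O", 1, "count"),
                      count = n_in, orientation = "random")))
  cfg <- build_start_configuration(list(water_spec), c(water = 1), box,
                                   compartments = list(cp), set = toy_set,
                                   seed = 5)
  expect_equal(nrow(cfg$particles), 3000L)
  p <- as.matrix(cfg$particles[, c("x", "y", "z")])
  inside <- sqrt(rowSums(sweep(p, 2, c(5, 5, 5))^2)) <= r
  is_comp <- cfg$particles$molecule_type == "inwater"
  # brute-force point-in-sphere census: every compartment particle inside,
  # and the interior holds exactly the requested count (bulk excluded)
  expect_true(all(inside[is_comp]))
  expect_equal(sum(is_comp), n_in)
  expect_equal(sum(inside), n_in)
})

test_that("outward orientation puts START farther from the center than END", {
  # open (non-periodic) box so long amphiphile tails are not wrapped and
  # the radial-distance predicate can be read off directly
  box <- derive_box_size(6000, 3, periodic = c(FALSE, FALSE, FALSE))
  dmpc <- molecule_spec("dmpc", "TriMeNP[START]-DMPN(MeAc-6Et)(MeAc-6Et[END])",
                        1, "count")
  cp <- compartment("sphere", center = box$edges / 2, radius = 3.5,
                    contents = list(list(spec = dmpc, count = 20,
                                         orientation = "outward")))
  cfg <- build_start_configuration(list(water_spec), c(water = 1), box,
                                   compartments = list(cp), set = toy_set,
                                   seed = 9)
  g <- dmpc$graph
  si <- which(g$tag == "START"); ei <- which(g$tag == "END")
  for (mid in unique(cfg$particles$molecule_id[cfg$particles$molecule_type == "dmpc"])) {
    idx <- which(cfg$particles$molecule_id == mid)
    p <- as.matrix(cfg$particles[idx, c("x", "y", "z")])
    ds <- sqrt(sum((p[si, ] - box$edges / 2)^2))
    de <- sqrt(sum((p[ei, ] - box$edges / 2)^2))
    expect_gt(ds, de)
  }
})

test_that("configurations are reproducible by seed and differ across seeds", {
  box <- derive_box_size(600, 3)
  c1 <- build_start_configuration(list(water_spec), c(water = 1), box,
                                  set = toy_set, seed = 3)
  c2 <- build_start_configuration(list(water_spec), c(water = 1), box,
                                  set = toy_set, seed = 3)
  c3 <- build_start_configuration(list(water_spec), c(water = 1), box,
                                  set = toy_set, seed = 4)
  expect_identical(c1$particles, c2$particles)
  expect_false(isTRUE(all.equal(c1$particles$x, c3$particles$x)))
})

test_that("fresh tube configurations keep bonded distances short", {
  box <- derive_box_size(3000, 3)
  eth <- molecule_spec("ethanol", "Me-MeOH", 50, "count")
  wat <- molecule_spec("water", "H2O", 1, "count")
  cfg <- build_start_configuration(list(eth, wat), c(ethanol = 50, water = 1),
                                   box, set = NULL, seed = 2)
  expect_equal(nrow(cfg$particles), 3000L)
  p <- as.matrix(cfg$particles[, c("x", "y", "z")])
  d <- p[cfg$bonds[, 1], , drop = FALSE] - p[cfg$bonds[, 2], , drop = FALSE]
  for (ax in 1:3) d[, ax] <- d[, ax] - 10 * round(d[, ax] / 10)
  expect_true(all(sqrt(rowSums(d^2)) <= 2))
  # bonds only join particles of the same molecule
  expect_true(all(cfg$particles$molecule_id[cfg$bonds[, 1]] ==
                    cfg$particles$molecule_id[cfg$bonds[, 2]]))
})

test_that("overfilled compartments and out-of-box geometry are errors", {
  box <- derive_box_size(375, 3)
  cp_big <- compartment("sphere", center = c(2.5, 2.5, 2.5), radius = 1,
                        contents = list(list(
                          spec = molecule_spec("w", "H2O", 1, "count"),
                          count = 500, orientation = "random")))
  expect_error(build_start_configuration(list(water_spec), c(water = 1), box,
                                         compartments = list(cp_big),
                                         seed = 1),
               "overfilled")
  cp_out <- compartment("sphere", center = c(0, 0, 0), radius = 2)
  expect_error(build_start_configuration(list(water_spec), c(water = 1), box,
                                         compartments = list(cp_out),
                                         seed = 1),
               "outside")
})

test_that("lattice layers form a uniform simple cubic grid", {
  box <- box_spec(c(3, 3, 9), density = 3)
  cp <- compartment("layer", zmin = 3, zmax = 6)
  pos <- place_lattice_layer(cp, box, 27)
  expect_equal(nrow(pos), 27L)
  expect_true(all(pos[, 3] >= 3 & pos[, 3] <= 6))
  # nearest-neighbor distance census: all equal
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(max(nn) - min(nn), 0, tolerance = 1e-12)
  expect_equal(nn[[1]], 1)
  one <- place_lattice_layer(cp, box, 1)
  expect_equal(one[1, ], c(1.5, 1.5, 4.5), ignore_attr = TRUE)
  expect_error(compartment("layer", zmin = 3, zmax = 6, lattice = TRUE,
                           contents = list(list(
                             spec = molecule_spec("e", "Me-MeOH", 1, "count"),
                             count = 2))),
               "single-particle")
})

test_that("protein placement excludes other particles from its sphere", {
  m <- parse_pdb(c("HEADER    X",
                   sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                           1:3, 1:3, c(0, 3.8, 7.6), c(0, 0, 0), c(0, 0, 0),
                           1.0, 0.0),
                   "END"))
  pp <- protein_to_particles(m, toy_set)
  box <- derive_box_size(600, 3)
  set.seed(1)
  cfg <- build_start_configuration(list(water_spec), c(water = 1), box,
                                   proteins = list(list(pp = pp, count = 1,
                                                        name = "pep")),
                                   set = toy_set, seed = 8)
  expect_equal(nrow(cfg$particles), 600L)
  prot <- cfg$particles$molecule_type == "pep"
  expect_equal(sum(prot), length(pp$graph$particles))
})
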