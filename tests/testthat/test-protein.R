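make_pdb_lines <- function(res = c("GLY", "ALA", "LYS"),
                           chains = rep("A", length(res)),
                           xyz = NULL, extra = character(0)) {
  if (is.null(xyz)) {
    xyz <- cbind(3.8 * seq_along(res), 0, 0)
  }
  atoms <- vapply(seq_along(res), function(i) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, res[i], chains[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0)
  }, "")
  c("HEADER    SYNTHETIC FIXTURE", extra, atoms, "TER", "END")
}

test_that("PDB parsing extracts one CA residue per (chain, number)", {
  m <- parse_pdb(make_pdb_lines())
  expect_s3_class(m, "protein_model")
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$three, c("Gly", "Ala", "Lys"))
  expect_equal(m$residues$x, c(3.8, 7.6, 11.4))
  expect_error(parse_pdb(make_pdb_lines(), exclude_chains = "A"), "excluded")
  two <- parse_pdb(make_pdb_lines(res = c("GLY", "ALA", "GLY", "GLU"),
                                  chains = c("A", "A", "B", "B")),
                   exclude_chains = "B")
  expect_equal(unique(two$residues$chain), "A")
  expect_equal(nrow(two$residues), 2L)
  expect_error(parse_pdb(c("HEADER    X", "END")), "CA|error")
})

test_that("SSBOND records are captured", {
  ss <- "SSBOND   1 CYS A    1    CYS A    4"
  m <- parse_pdb(make_pdb_lines(res = c("CYS", "GLY", "GLY", "CYS"),
                                extra = ss))
  expect_equal(nrow(m$ssbonds), 1L)
  expect_equal(m$ssbonds$resno1, 1L)
  expect_equal(m$ssbonds$resno2, 4L)
})

test_that("mutation changes identity but never geometry", {
  m <- parse_pdb(make_pdb_lines())
  mut <- mutate_protein(m, data.frame(chain = "A", resno = 2, three = "Ala",
                                      stringsAsFactors = FALSE))
  expect_equal(mut$residues[, c("x", "y", "z")], m$residues[, c("x", "y", "z")])
  expect_equal(nrow(mut$residues), nrow(m$residues))
  expect_equal(mutate_protein(m, NULL), m)  # empty set is identity
  expect_error(mutate_protein(m, data.frame(chain = "A", resno = 99,
                                            three = "Ala")), "not found")
})

test_that("protonation follows the step rule and is monotone in pH", {
  aa <- toy_set$amino_acids
  expect_equal(protonation_state("Lys", 7, aa), "charged")    # base, pH < 10.5
  expect_equal(protonation_state("Lys", 12, aa), "neutral")
  expect_equal(protonation_state("Glu", 2, aa), "neutral")    # acid, pH < 4.1
  expect_equal(protonation_state("Glu", 7, aa), "charged")
  expect_equal(protonation_state("Gly", 1, aa), "neutral")
  expect_equal(protonation_state("Gly", 13, aa), "neutral")
  expect_error(protonation_state("Xyz", 7, aa), "unknown")
  # monotonicity: raising pH never adds positive charge, never removes
  # negative charge
  charge_at <- function(pH) {
    g <- peptide_to_spices("KE", toy_set, pH = pH)
    c(pos = sum(g$charge[g$charge > 0]), neg = sum(g$charge[g$charge < 0]))
  }
  phs <- seq(1, 13, by = 0.5)
  q <- t(vapply(phs, charge_at, c(pos = 0, neg = 0)))
  expect_true(all(diff(q[, "pos"]) <= 0))
  expect_true(all(diff(q[, "neg"]) <= 0))  # negative charge only grows
})

test_that("particle conversion anchors backbones at scaled CA positions", {
  m <- parse_pdb(make_pdb_lines())
  pp <- protein_to_particles(m, toy_set, density = 3)
  expect_equal(length(pp$backbone_nodes), 3L)
  scale <- dpd_length_scale(toy_set, 3)
  expect_equal(pp$backbone_coords,
               as.matrix(m$residues[, c("x", "y", "z")]) / scale,
               ignore_attr = TRUE)
  # per-residue fragment assembly: Gly 1 + Ala 2 + Lys 2 (charged at pH 7)
  expect_equal(length(pp$graph$particles), 5L)
  expect_error(protein_to_particles(
    mutate_protein(m, data.frame(chain = "A", resno = 1, three = "Trp")),
    toy_set), "missing from")
})

test_that("probe replacement relabels only, with identical interactions", {
  m <- parse_pdb(make_pdb_lines())
  base <- protein_to_particles(m, toy_set)
  probed <- protein_to_particles(m, toy_set,
                                 probes = data.frame(chain = "A", resno = 1,
                                                     probe = "PROBE",
                                                     stringsAsFactors = FALSE))
  expect_equal(probed$graph$edges, base$graph$edges)
  expect_equal(probed$backbone_coords, base$backbone_coords)
  bb1 <- probed$backbone_nodes[1]
  expect_equal(probed$graph$particles[bb1], "PROBE")
  expect_equal(probed$graph$particles[-bb1], base$graph$particles[-bb1])
  # the engine resolves unknown probe tokens to the replaced particle's
  # interactions: repulsion(probe, X) == repulsion(original, X)
  cfg <- structure(list(
    particles = data.frame(type = probed$graph$particles,
                           molecule_id = 1L, molecule_type = "pep",
                           x = 0, y = 0, z = 0),
    bonds = probed$graph$edges, box = box_spec(c(5, 5, 5)),
    probe_map = probed$probe_map),
    class = "start_configuration")
  sys <- dpdfrag:::prepare_system(cfg, toy_set,
                                  simulation_parameters(temperature = 298))
  a_probe <- sys$a_matrix["PROBE", ]
  a_orig <- vapply(names(a_probe), function(tok)
    repulsion(toy_set, "BB", if (tok == "PROBE") "BB" else tok, 298), 1)
  expect_equal(unname(a_probe), unname(a_orig))
})

test_that("segment labels land on the addressed backbone nodes only", {
  m <- parse_pdb(make_pdb_lines())
  pp <- protein_to_particles(m, toy_set,
                             segments = data.frame(chain = "A", from = 1,
                                                   to = 2, segment = "S1",
                                                   stringsAsFactors = FALSE))
  expect_equal(sum(pp$segments == "S1", na.rm = TRUE), 2L)
  expect_true(is.na(pp$segments[3]))
  expect_error(protein_to_particles(m, toy_set,
                                    segments = data.frame(chain = "A",
                                                          from = 1, to = 9,
                                                          segment = "S1")),
               "outside")
})

test_that("side-chain collapse puts every side chain on its backbone", {
  m <- parse_pdb(make_pdb_lines())
  pp <- protein_to_particles(m, toy_set)
  set.seed(1)
  pos <- collapse_sidechains(pp, jitter = 0.01)
  g <- pp$graph
  is_bb <- seq_along(g$particles) %in% pp$backbone_nodes
  # each side-chain particle within jitter of its bonded backbone particle
  for (v in which(!is_bb)) {
    nb <- unique(c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1]))
    bb <- nb[nb %in% pp$backbone_nodes]
    d <- min(sqrt(rowSums((pos[bb, , drop = FALSE] -
                             matrix(pos[v, ], length(bb), 3, byrow = TRUE))^2)))
    expect_lte(d, 0.01 + 1e-12)
  }
  # all-glycine model collapses to the backbone exactly
  mg <- parse_pdb(make_pdb_lines(res = rep("GLY", 3)))
  ppg <- protein_to_particles(mg, toy_set)
  expect_equal(collapse_sidechains(ppg, jitter = 0), ppg$backbone_coords,
               ignore_attr = TRUE)
})

test_that("sphere shrinking uses the summed-volume radius and contains all", {
  r <- shrink_to_sphere(matrix(rnorm(90), 30, 3), rep(30, 30))
  expect_equal(r$radius, (3 * 900 / (4 * pi))^(1 / 3))
  expect_true(all(sqrt(rowSums(r$positions^2)) <= r$radius + 1e-9))
  one <- shrink_to_sphere(matrix(c(5, 5, 5), 1, 3), 30, center = c(1, 2, 3))
  expect_equal(one$positions[1, ], c(1, 2, 3))
  set.seed(2)
  for (k in 1:5) {
    n <- sample(2:40, 1)
    pos <- matrix(rnorm(3 * n, sd = 10), n, 3)
    rr <- shrink_to_sphere(pos, runif(n, 10, 60), center = c(1, 1, 1))
    expect_true(all(sqrt(rowSums(sweep(rr$positions, 2, c(1, 1, 1))^2)) <=
                      rr$radius + 1e-9))
  }
})
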