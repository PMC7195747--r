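#' Deterministic synthetic fixtures
#'
#' Writes small, fully synthetic test inputs:
#' \describe{
#'   \item{\code{"particle-set"}}{a 4-type biomolecular toy set (water,
#'     backbone, side chain, chargeable side chain) with an amino-acid
#'     table for Gly, Ala, Lys, Glu and Cys.}
#'   \item{\code{"pdb"}}{a 3-residue single-chain synthetic peptide PDB
#'     (CA trace).}
#'   \item{\code{"job"}}{a small valid job definition serialized to text.}
#'   \item{\code{"two-slab-config"}}{a start configuration with a solute
#'     confined to two z-slabs in water, as extended XYZ.}
#' }
#'
#' @param kind fixture kind.
#' @param dir output directory.
#' @param seed RNG seed (fixtures are byte-identical for equal seeds).
#' @return path of the written file.
#' @export
make_fixtures <- function(kind, dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind, c("particle-set", "pdb", "job", "two-slab-config"))
  set.seed(seed)
  switch(kind,
    "particle-set" = {
      path <- file.path(dir, "ParticleSet_Toy.txt")
      writeLines(fixture_particle_set_text(), path)
      path
    },
    "pdb" = {
      path <- file.path(dir, "synthetic_tripeptide.pdb")
      writeLines(fixture_pdb_text(), path)
      path
    },
    "job" = {
      set <- parse_particle_set(fixture_particle_set_text(), name = "Toy")
      job <- default_job(set, quantity = 375, density = 3, seed = seed)
      job$simulation$steps <- 10L
      job$simulation$output_frequency <- 5L
      path <- file.path(dir, "job.txt")
      writeLines(serialize_job(job), path)
      path
    },
    "two-slab-config" = {
      cfg <- fixture_two_slab_configuration(seed)
      path <- file.path(dir, "two_slab.xyz")
      write_xyz(cfg, path)
      path
    })
}

fixture_particle_set_text <- function() {
  c("# synthetic biomolecular toy particle set",
    "[Particle description]",
    "# name mass charge volume color",
    "H2O 18 0 30 blue",
    "BB 56 0 60 grey",
    "SC 45 0 55 green",
    "SCQ 45 0 55 red",
    "",
    "[Particle interactions]",
    "pair 298 310",
    "H2O_H2O 25 25.5",
    "BB_BB 25 25.4",
    "SC_SC 25 25.3",
    "SCQ_SCQ 25 25.3",
    "H2O_BB 28 28.4",
    "H2O_SC 30 30.2",
    "H2O_SCQ 22 22.2",
    "BB_SC 26 26.1",
    "BB_SCQ 27 27.1",
    "SC_SCQ 27 27.2",
    "",
    "[Amino acids]",
    "# one three spices backboneIndex pKa chargedVariant",
    "G Gly BB 1 - -",
    "A Ala BB-SC 1 - -",
    "K Lys BB-SC 1 10.5 charged=BB-SCQ[+]",
    "E Glu BB-SC 1 4.1 charged=BB-SCQ[-]",
    "C Cys BB-SC 1 8.3 charged=BB-SCQ[-]")
}

#' The toy particle set as an object
#'
#' @param name set name.
#' @return a \code{particle_set}.
#' @export
toy_particle_set <- function(name = "Toy") {
  parse_particle_set(fixture_particle_set_text(), name = name)
}

fixture_pdb_text <- function() {
  # synthetic 3-residue CA trace, chain A: Gly-Ala-Lys
  res <- c("GLY", "ALA", "LYS")
  xyz <- matrix(c(0.0, 0.0, 0.0,
                  3.8, 0.0, 0.0,
                  5.9, 3.1, 0.5), 3, 3, byrow = TRUE)
  atoms <- vapply(1:3, function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, res[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0)
  }, "")
  c("HEADER    SYNTHETIC TEST PEPTIDE", atoms, "TER", "END")
}

fixture_two_slab_configuration <- function(seed = 1L) {
  set.seed(seed)
  box <- box_spec(c(6, 6, 12), density = 3)
  n_total <- round(3 * prod(box$edges))
  n_solute <- 200L
  # solute confined to z in [1,3] and [9,11]; water everywhere else
  half <- n_solute %/% 2L
  zs <- c(stats::runif(half, 1, 3), stats::runif(n_solute - half, 9, 11))
  solute <- cbind(stats::runif(n_solute, 0, 6), stats::runif(n_solute, 0, 6), zs)
  water <- cbind(stats::runif(n_total - n_solute, 0, 6),
                 stats::runif(n_total - n_solute, 0, 6),
                 stats::runif(n_total - n_solute, 0, 12))
  particles <- data.frame(
    type = c(rep("Et", n_solute), rep("H2O", n_total - n_solute)),
    molecule_id = seq_len(n_total),
    molecule_type = c(rep("ethanol", n_solute), rep("water", n_total - n_solute)),
    x = c(solute[, 1], water[, 1]),
    y = c(solute[, 2], water[, 2]),
    z = c(solute[, 3], water[, 3]),
    stringsAsFactors = FALSE)
  structure(list(particles = particles, bonds = matrix(integer(0), 0, 2),
                 box = box),
            class = "start_configuration")
}
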