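# Independent brute-force oracles (plain R, all-pairs, no shared code with
# the compiled kernels) and small fixture builders.

min_image <- function(d, L, periodic) {
  for (ax in 1:3) {
    if (periodic[ax]) d[ax] <- d[ax] - L[ax] * round(d[ax] / L[ax])
  }
  d
}

# conservative DPD pair forces + potential, O(N^2)
bf_pair_forces <- function(pos, box, type_index, a_matrix) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  epot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min_image(pos[i, ] - pos[j, ], box$edges, box$periodic)
      r <- sqrt(sum(d^2))
      if (r >= 1 || r < 1e-12) {
        if (r < 1e-12) epot <- epot + 0.5 * a_matrix[type_index[i] + 1, type_index[j] + 1]
        next
      }
      a <- a_matrix[type_index[i] + 1, type_index[j] + 1]
      w <- 1 - r
      fv <- a * w * d / r
      f[i, ] <- f[i, ] + fv
      f[j, ] <- f[j, ] - fv
      epot <- epot + 0.5 * a * w^2
    }
  }
  list(forces = f, epot = epot)
}

# minimum-image same-type pair distance histogram, O(N^2)
bf_histogram <- function(pos, box, r_max, n_bins) {
  h <- numeric(n_bins)
  w <- r_max / n_bins
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum(min_image(pos[i, ] - pos[j, ], box$edges, box$periodic)^2))
      if (r < r_max) {
        b <- min(n_bins, floor(r / w) + 1)
        h[b] <- h[b] + 1
      }
    }
  }
  h
}

# neighbor shell census, O(N^2)
bf_neighbor_counts <- function(pos, box, shell) {
  n <- nrow(pos)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum(min_image(pos[i, ] - pos[j, ], box$edges, box$periodic)^2))
      if (r <= shell) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

random_fluid_config <- function(n, density = 3, seed = 1, type = "H2O") {
  set.seed(seed)
  box <- derive_box_size(n, density)
  particles <- data.frame(type = type, molecule_id = seq_len(n),
                          molecule_type = "water",
                          x = runif(n, 0, box$edges[1]),
                          y = runif(n, 0, box$edges[2]),
                          z = runif(n, 0, box$edges[3]),
                          stringsAsFactors = FALSE)
  structure(list(particles = particles, bonds = matrix(integer(0), 0, 2),
                 box = box),
            class = "start_configuration")
}

# two bonded particles in a large open box
dimer_config <- function(sep = 1.3, box_edge = 20) {
  particles <- data.frame(type = "H2O", molecule_id = c(1L, 1L),
                          molecule_type = "dimer",
                          x = c(10 - sep / 2, 10 + sep / 2),
                          y = c(10, 10), z = c(10, 10),
                          stringsAsFactors = FALSE)
  structure(list(particles = particles, bonds = matrix(c(1L, 2L), 1, 2),
                 box = box_spec(c(box_edge, box_edge, box_edge), density = 3)),
            class = "start_configuration")
}

toy_set <- toy_particle_set()
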