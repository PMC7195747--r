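#' Thermodynamic scalar series from a trajectory
#'
#' Recomputes per frame: kT = 2 E_kin / (3N - 3) (momentum-conserving
#' thermostat removes three degrees of freedom), potential energy
#' (conservative pair + bond), and surface tension from the diagonal
#' virial pressure tensor with a z-normal planar-interface convention,
#' gamma = (Lz / 2) (P_zz - (P_xx + P_yy) / 2) — the factor Lz/2 accounts
#' for the two interfaces of a periodic slab.
#'
#' @param trajectory a \code{dpd_trajectory} with frame velocities.
#' @param params the run's \code{simulation_parameters}.
#' @param a_matrix symmetric repulsion matrix over the trajectory's types
#'   (default a_ij = 25).
#' @param bonds bond data.frame or NULL.
#' @param masses per-particle masses.
#' @return data.frame with columns step, kT, kineticEnergy,
#'   potentialEnergy, surfaceTension.
#' @export
thermo_series <- function(trajectory, params, a_matrix = NULL, bonds = NULL,
                          masses = NULL) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  if (!length(trajectory$velocities)) {
    stop("trajectory has no velocities; kinetic quantities unavailable")
  }
  types <- unique(trajectory$types)
  if (is.null(a_matrix)) {
    a_matrix <- matrix(25, length(types), length(types),
                       dimnames = list(types, types))
  }
  ti <- match(trajectory$types, colnames(a_matrix)) - 1L
  n <- length(ti)
  if (is.null(masses)) masses <- rep(1, n)
  dof <- max(1L, 3L * n - 3L)
  box <- trajectory$box
  V <- prod(box$edges)
  out <- lapply(seq_along(trajectory$frames), function(f) {
    pos <- trajectory$frames[[f]]
    vel <- trajectory$velocities[[f]]
    fr <- dpd_forces(pos, vel, box, ti, a_matrix, params, bonds = bonds,
                     masses = masses, thermostat = FALSE)
    ekin <- sum(0.5 * masses * rowSums(vel^2))
    kin_diag <- colSums(masses * vel^2)
    P <- (kin_diag + fr$virial) / V
    data.frame(step = trajectory$steps[f],
               kT = 2 * ekin / dof,
               kineticEnergy = ekin,
               potentialEnergy = fr$epot_pair + fr$epot_bond,
               surfaceTension = (box$edges[3] / 2) * (P[3] - (P[1] + P[2]) / 2))
  })
  do.call(rbind, out)
}

#' Radial distribution function for a particle-type pair
#'
#' Minimum-image pair histogram normalized by the ideal-gas shell count
#' and the frame count, so g(r) tends to 1 at large r in a homogeneous
#' fluid.
#'
#' @param trajectory a \code{dpd_trajectory}.
#' @param pair length-2 character vector of particle type tokens (equal
#'   tokens give the self-RDF).
#' @param bin_width histogram bin width (r_c).
#' @param r_max maximal distance; must not exceed half the smallest
#'   periodic box edge (minimum-image validity).
#' @return object of class \code{rdf_result}: data.frame with columns
#'   r (bin centers) and g, plus attributes pair and bin_width.
#' @export
rdf <- function(trajectory, pair, bin_width = 0.05, r_max = NULL) {
  stopifnot(inherits(trajectory, "dpd_trajectory"), length(pair) == 2L)
  box <- trajectory$box
  half <- min(box$edges[box$periodic]) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    stop("r_max exceeds half the smallest periodic edge; ",
         "minimum-image distances are not valid beyond ", signif(half, 4))
  }
  n_bins <- max(1L, round(r_max / bin_width))
  r_max <- n_bins * bin_width
  sel_a <- which(trajectory$types == pair[1]) - 1L
  sel_b <- which(trajectory$types == pair[2]) - 1L
  if (!length(sel_a) || !length(sel_b)) stop("no particles of requested type")
  same <- pair[1] == pair[2]
  h <- numeric(n_bins)
  for (f in seq_along(trajectory$frames)) {
    h <- h + cpp_pair_histogram(trajectory$frames[[f]], box$edges,
                                box$periodic, sel_a, sel_b, r_max, n_bins,
                                same)
  }
  V <- prod(box$edges)
  n_pairs <- if (same) length(sel_a) * (length(sel_a) - 1) / 2 else
    length(sel_a) * length(sel_b)
  edges <- seq(0, r_max, by = bin_width)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  ideal <- n_pairs * shell / V * length(trajectory$frames)
  out <- data.frame(r = edges[-length(edges)] + bin_width / 2, g = h / ideal)
  attr(out, "pair") <- pair
  attr(out, "bin_width") <- bin_width
  class(out) <- c("rdf_result", "data.frame")
  out
}

#' Minimum-image distance series between two particles
#'
#' @param trajectory a \code{dpd_trajectory}.
#' @param i,j particle indices (1-based).
#' @return data.frame step, distance.
#' @export
pair_distance_series <- function(trajectory, i, j) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  n <- nrow(trajectory$frames[[1]])
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("particle index out of range")
  box <- trajectory$box
  d <- vapply(trajectory$frames, function(p) {
    dd <- p[i, ] - p[j, ]
    for (ax in 1:3) {
      if (box$periodic[ax]) {
        dd[ax] <- dd[ax] - box$edges[ax] * round(dd[ax] / box$edges[ax])
      }
    }
    sqrt(sum(dd^2))
  }, 1)
  data.frame(step = trajectory$steps, distance = d)
}

# unwrap molecule coordinates against the first member (minimum image)
unwrap_molecule <- function(pos, box) {
  ref <- pos[1, ]
  for (ax in 1:3) {
    if (box$periodic[ax]) {
      d <- pos[, ax] - ref[ax]
      pos[, ax] <- ref[ax] + d - box$edges[ax] * round(d / box$edges[ax])
    }
  }
  pos
}

#' Radius of gyration series per molecule
#'
#' Rg = sqrt(sum m_i |r_i - r_cm|^2 / sum m_i), with molecule coordinates
#' unwrapped by minimum image before the center of mass is taken.
#'
#' @param trajectory a \code{dpd_trajectory}.
#' @param molecules molecule ids to evaluate (default: all molecules with
#'   more than one particle).
#' @param masses per-particle masses (default 1).
#' @return data.frame step, molecule_id, rg.
#' @export
radius_of_gyration <- function(trajectory, molecules = NULL, masses = NULL) {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  mid <- trajectory$molecule_id
  if (is.null(molecules)) {
    tab <- table(mid)
    molecules <- as.integer(names(tab)[tab > 1L])
    if (!length(molecules)) molecules <- as.integer(names(tab))
  }
  if (!length(molecules)) stop("empty molecule selection")
  if (is.null(masses)) masses <- rep(1, length(mid))
  box <- trajectory$box
  out <- list()
  for (f in seq_along(trajectory$frames)) {
    p <- trajectory$frames[[f]]
    for (m in molecules) {
      idx <- which(mid == m)
      if (!length(idx)) stop("unknown molecule id: ", m)
      pm <- unwrap_molecule(p[idx, , drop = FALSE], box)
      w <- masses[idx]
      cm <- colSums(pm * w) / sum(w)
      rg <- sqrt(sum(w * rowSums(sweep(pm, 2, cm)^2)) / sum(w))
      out[[length(out) + 1L]] <- data.frame(step = trajectory$steps[f],
                                            molecule_id = m, rg = rg)
    }
  }
  do.call(rbind, out)
}

#' Nearest-neighbor census
#'
#' Two readings of "neighborhood", both reported: (a) the single nearest
#' neighbor of every particle, and (b) a shell census — the mean number of
#' particles of each type within \code{shell_radius} of a particle of each
#' subject type, averaged over frames.
#'
#' @param trajectory a \code{dpd_trajectory}.
#' @param shell_radius census shell (r_c), at most half the smallest
#'   periodic edge.
#' @param by \code{"type"} (particle types) or \code{"molecule"}
#'   (molecule type names).
#' @return object of class \code{neighbor_table}: list with
#'   \code{shell_radius}, \code{mean_counts} (matrix subject x neighbor),
#'   \code{nearest} (data.frame step, particle, nearest, distance).
#' @export
nearest_neighbors <- function(trajectory, shell_radius = 1, by = "type") {
  stopifnot(inherits(trajectory, "dpd_trajectory"))
  box <- trajectory$box
  half <- min(box$edges[box$periodic]) / 2
  if (shell_radius > half + 1e-9) {
    stop("shell radius exceeds half the smallest periodic edge")
  }
  labels <- if (by == "molecule") trajectory$molecule_type else trajectory$types
  lv <- sort(unique(labels))
  li <- match(labels, lv) - 1L
  acc <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  nearest <- list()
  for (f in seq_along(trajectory$frames)) {
    cen <- cpp_neighbor_census(trajectory$frames[[f]], box$edges,
                               box$periodic, li, length(lv), shell_radius)
    for (s in seq_along(lv)) {
      rows <- li == s - 1L
      if (any(rows)) acc[s, ] <- acc[s, ] + colMeans(cen$counts[rows, , drop = FALSE])
    }
    nearest[[f]] <- data.frame(step = trajectory$steps[f],
                               particle = seq_along(li),
                               nearest = cen$nearest + 1L,
                               distance = cen$nearest_dist)
  }
  structure(list(shell_radius = shell_radius,
                 mean_counts = acc / length(trajectory$frames),
                 nearest = do.call(rbind, nearest)),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat(sprintf("neighbor_table (shell %.3g r_c): mean counts\n", x$shell_radius))
  print(round(x$mean_counts, 3))
  invisible(x)
}

#' Particle frequency along a box axis
#'
#' Histogram of selected particles along one axis, optionally restricted
#' to a zoom region (a \code{compartment}); the counts sum to the number
#' of selected particles inside the region.
#'
#' @param positions n x 3 frame matrix (or a \code{start_configuration}).
#' @param box a \code{box_spec} (ignored when a configuration is given).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param bins number of bins along the axis.
#' @param select logical or integer particle selection (default: all).
#' @param region optional \code{compartment} restricting the census.
#' @return object of class \code{axis_histogram}: data.frame with bin
#'   midpoints (\code{pos}) and \code{count}.
#' @export
axis_frequency <- function(positions, box = NULL, axis = "z", bins = 20,
                           select = NULL, region = NULL) {
  if (inherits(positions, "start_configuration")) {
    box <- positions$box
    positions <- as.matrix(positions$particles[, c("x", "y", "z")])
  }
  stopifnot(bins >= 1, inherits(box, "box_spec"))
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be x, y or z")
  if (!is.null(select)) positions <- positions[select, , drop = FALSE]
  if (!is.null(region)) {
    keep <- apply(positions, 1, point_in_compartment, cp = region)
    positions <- positions[keep, , drop = FALSE]
  }
  edges <- seq(0, box$edges[ax], length.out = bins + 1L)
  cnt <- if (nrow(positions)) {
    tabulate(pmin(bins, pmax(1L, findInterval(positions[, ax], edges,
                                              rightmost.closed = TRUE))),
             nbins = bins)
  } else integer(bins)
  out <- data.frame(pos = (edges[-1] + edges[-length(edges)]) / 2,
                    count = cnt)
  attr(out, "axis") <- axis
  class(out) <- c("axis_histogram", "data.frame")
  out
}
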