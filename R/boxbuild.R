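#' Box specification
#'
#' @param edges box edge lengths (Lx, Ly, Lz) in r_c.
#' @param density DPD number density (particles per r_c^3).
#' @param periodic logical length-3, per-axis periodicity.
#' @return object of class \code{box_spec}.
#' @export
box_spec <- function(edges, density = 3, periodic = c(TRUE, TRUE, TRUE)) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) == 3L, all(edges > 0), density > 0,
            length(periodic) == 3L)
  structure(list(edges = edges, density = density,
                 periodic = as.logical(periodic)),
            class = "box_spec")
}

#' Molecule specification
#'
#' @param name molecule name.
#' @param graph SPICES string or \code{spices_graph}.
#' @param amount positive amount.
#' @param unit one of \code{"count"}, \code{"gram"}, \code{"mol"},
#'   \code{"molpercent"}, \code{"weightpercent"}.
#' @param color optional display color token.
#' @return object of class \code{molecule_spec}.
#' @export
molecule_spec <- function(name, graph, amount = 1, unit = "count",
                          color = NA_character_) {
  if (!inherits(graph, "spices_graph")) graph <- parse_spices(graph)
  unit <- match.arg(unit, c("count", "gram", "mol", "molpercent", "weightpercent"))
  stopifnot(amount > 0)
  if (unit == "count" && amount != round(amount)) {
    stop("count amounts must be integral")
  }
  structure(list(name = name, graph = graph, amount = amount, unit = unit,
                 color = color),
            class = "molecule_spec")
}

molecule_molar_mass <- function(spec, set) {
  m <- set$types$mass[match(spec$graph$particles, set$types$name)]
  if (anyNA(m)) {
    stop("molecule ", spec$name, " uses particle(s) not in the set: ",
         paste(unique(spec$graph$particles[is.na(m)]), collapse = ", "))
  }
  sum(m)
}

#' Convert a composition to molecule counts
#'
#' Count amounts pass through unchanged. Gram and mol amounts are converted
#' to mole fractions via the molecular molar masses (sum of particle masses);
#' mol-percent and weight-percent are normalized. Relative amounts are then
#' scaled so that the total particle count equals \code{total_particles},
#' rounded half-up with at least 1 molecule per positive amount.
#'
#' @param specs list of \code{molecule_spec} (all in one unit family:
#'   either all \code{"count"} or all relative units).
#' @param total_particles target total particle count (required for
#'   relative units).
#' @param set a \code{particle_set} (needed for gram/weight conversion).
#' @return named integer vector of molecule counts.
#' @export
composition_to_counts <- function(specs, total_particles = NULL, set = NULL) {
  units <- vapply(specs, function(s) s$unit, "")
  nm <- vapply(specs, function(s) s$name, "")
  sizes <- vapply(specs, function(s) length(s$graph$particles), 1L)
  if (all(units == "count")) {
    counts <- as.integer(vapply(specs, function(s) s$amount, 1))
    names(counts) <- nm
    return(counts)
  }
  if (any(units == "count")) {
    stop("mixed incompatible units: counts cannot be combined with relative amounts")
  }
  if (is.null(total_particles) || total_particles <= 0) {
    stop("relative units require a positive total particle count")
  }
  amounts <- vapply(specs, function(s) s$amount, 1)
  frac <- numeric(length(specs))
  for (k in seq_along(specs)) {
    frac[k] <- switch(units[k],
      mol = , molpercent = amounts[k],
      gram = , weightpercent = amounts[k] / molecule_molar_mass(specs[[k]], set))
  }
  if (sum(frac) == 0) stop("zero total amount")
  frac <- frac / sum(frac)
  scale <- total_particles / sum(frac * sizes)
  counts <- floor(frac * scale + 0.5)
  counts[amounts > 0 & counts < 1] <- 1
  counts <- as.integer(counts)
  names(counts) <- nm
  counts
}

#' Derive box dimensions from particle count and density
#'
#' Volume V = N / rho; edges are proportional to \code{aspect} with
#' Lx Ly Lz = V (a cube for aspect (1,1,1)).
#'
#' @param total_particles particle count N.
#' @param density DPD density rho.
#' @param aspect length-3 positive aspect ratios.
#' @param periodic per-axis periodicity flags.
#' @return a \code{box_spec}.
#' @export
derive_box_size <- function(total_particles, density = 3, aspect = c(1, 1, 1),
                            periodic = c(TRUE, TRUE, TRUE)) {
  stopifnot(total_particles > 0, density > 0)
  if (any(aspect <= 0)) stop("aspect ratios must be positive")
  V <- total_particles / density
  s <- (V / prod(aspect))^(1 / 3)
  box_spec(aspect * s, density, periodic)
}

#' Compartment of a start configuration
#'
#' @param kind \code{"sphere"}, \code{"layer"} or \code{"cuboid"}.
#' @param center sphere center (r_c).
#' @param radius sphere radius.
#' @param zmin,zmax layer z-interval (layers span the full box cross
#'   section).
#' @param corner,extents cuboid lower corner and edge lengths.
#' @param contents list of \code{list(spec = molecule_spec, count = n,
#'   orientation = "random"|"inward"|"outward"|axis vector)}.
#' @param lattice place contents on a simple cubic lattice (single-particle
#'   molecules only).
#' @return object of class \code{compartment}.
#' @export
compartment <- function(kind, center = NULL, radius = NULL, zmin = NULL,
                        zmax = NULL, corner = NULL, extents = NULL,
                        contents = list(), lattice = FALSE) {
  kind <- match.arg(kind, c("sphere", "layer", "cuboid"))
  if (kind == "sphere") stopifnot(!is.null(center), !is.null(radius), radius > 0)
  if (kind == "layer") stopifnot(!is.null(zmin), !is.null(zmax), zmax > zmin)
  if (kind == "cuboid") stopifnot(!is.null(corner), !is.null(extents), all(extents > 0))
  if (lattice) {
    for (ct in contents) {
      if (length(ct$spec$graph$particles) != 1L) {
        stop("lattice positioning requires single-particle molecules")
      }
    }
  }
  structure(list(kind = kind, center = center, radius = radius,
                 zmin = zmin, zmax = zmax, corner = corner, extents = extents,
                 contents = contents, lattice = lattice),
            class = "compartment")
}

compartment_volume <- function(cp, box) {
  switch(cp$kind,
    sphere = 4 / 3 * pi * cp$radius^3,
    layer = box$edges[1] * box$edges[2] * (cp$zmax - cp$zmin),
    cuboid = prod(cp$extents))
}

point_in_compartment <- function(p, cp) {
  switch(cp$kind,
    sphere = sum((p - cp$center)^2) <= cp$radius^2,
    layer = p[3] >= cp$zmin && p[3] <= cp$zmax,
    cuboid = all(p >= cp$corner) && all(p <= cp$corner + cp$extents))
}

compartment_in_box <- function(cp, box) {
  L <- box$edges
  switch(cp$kind,
    sphere = all(cp$center - cp$radius >= 0) && all(cp$center + cp$radius <= L),
    layer = cp$zmin >= 0 && cp$zmax <= L[3],
    cuboid = all(cp$corner >= 0) && all(cp$corner + cp$extents <= L))
}

random_point_in_compartment <- function(cp, box) {
  switch(cp$kind,
    sphere = {
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) return(cp$center + cp$radius * p)
      }
    },
    layer = c(stats::runif(1, 0, box$edges[1]),
              stats::runif(1, 0, box$edges[2]),
              stats::runif(1, cp$zmin, cp$zmax)),
    cuboid = cp$corner + stats::runif(3) * cp$extents)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simple cubic lattice positions inside a layer
#'
#' Fills the layer with a simple cubic lattice of uniform nearest-neighbor
#' spacing, e.g. to seed a solid surface that is then held in place with a
#' molecule fixation constraint.
#'
#' @param cp a layer \code{compartment}.
#' @param box a \code{box_spec}.
#' @param count number of particles (single-particle molecules).
#' @return count x 3 position matrix.
#' @export
place_lattice_layer <- function(cp, box, count) {
  stopifnot(inherits(cp, "compartment"))
  if (cp$kind != "layer") stop("lattice placement is defined for layer compartments")
  ext <- c(box$edges[1], box$edges[2], cp$zmax - cp$zmin)
  s <- (prod(ext) / count)^(1 / 3)
  n <- pmax(1L, as.integer(round(ext / s)))
  while (prod(n) < count) {
    grow <- which.max(ext / n)
    n[grow] <- n[grow] + 1L
  }
  spacing <- min(ext / n)
  # center the lattice block in the layer
  block <- (n - 1L) * spacing
  o <- c(0, 0, cp$zmin) + (ext - block) / 2
  pos <- as.matrix(expand.grid(x = seq_len(n[1]) - 1L,
                               y = seq_len(n[2]) - 1L,
                               z = seq_len(n[3]) - 1L))
  pos <- sweep(pos * spacing, 2, o, `+`)
  pos[seq_len(count), , drop = FALSE]
}

#' Build a simulation-box start configuration
#'
#' Places molecules as randomly oriented tubes at the target DPD density.
#' Compartment contents are placed inside their geometry; sphere contents
#' with inward/outward orientation point the molecule's [START]-tagged end
#' toward/away from the sphere center. Protein particle models are placed
#' with side chains collapsed onto their backbone particles and the whole
#' molecule shrunk into a virtual sphere of its summed particle volume,
#' from which all other placements are excluded. Bulk molecules fill the
#' remaining space (outside all compartments) so that the configuration
#' holds exactly \code{round(rho V)} particles.
#'
#' @param specs list of \code{molecule_spec} for bulk molecules.
#' @param counts named integer vector of bulk molecule counts (names match
#'   specs). The filler species' count is adjusted so the total particle
#'   count is exact.
#' @param box a \code{box_spec}.
#' @param compartments list of \code{compartment}.
#' @param proteins list of \code{list(pp = protein_particles, count = n)}.
#' @param set the \code{particle_set} (for particle volumes of proteins).
#' @param filler name of the bulk species absorbing the rounding remainder
#'   (default: first single-particle bulk spec).
#' @param seed RNG seed (integer) for reproducible configurations.
#' @param max_attempts placement attempts per molecule before an overfill
#'   error.
#' @return object of class \code{start_configuration}: list with
#'   \code{particles} (data.frame type, molecule_id, molecule_type, x, y,
#'   z), \code{bonds} (2-column matrix), \code{box}.
#' @export
build_start_configuration <- function(specs, counts, box,
                                      compartments = list(),
                                      proteins = list(), set = NULL,
                                      filler = NULL, seed = NULL,
                                      max_attempts = 10000L) {
  stopifnot(inherits(box, "box_spec"))
  if (!is.null(seed)) set.seed(seed)
  for (cp in compartments) {
    if (!compartment_in_box(cp, box)) stop("compartment outside box")
  }
  V <- prod(box$edges)
  total <- round(box$density * V)

  # innermost-first membership: spheres sorted by radius ascending decide
  # which compartment owns a point
  sphere_order <- order(vapply(compartments, function(c0)
    if (c0$kind == "sphere") c0$radius else Inf, 1))

  owner <- function(p) {
    for (ci in sphere_order) {
      if (point_in_compartment(p, compartments[[ci]])) return(ci)
    }
    0L
  }

  exclusions <- list()  # protein spheres: list(center, radius)
  excluded <- function(p) {
    for (e in exclusions) {
      if (sum((p - e$center)^2) < e$radius^2) return(TRUE)
    }
    FALSE
  }

  type <- character(0)
  mol_id <- integer(0)
  mol_type <- character(0)
  pos <- list()
  bonds <- list()
  next_mol <- 1L
  n_placed <- 0L

  add_molecule <- function(spec_name, graph, coords) {
    k <- nrow(coords)
    type <<- c(type, graph$particles)
    mol_id <<- c(mol_id, rep(next_mol, k))
    mol_type <<- c(mol_type, rep(spec_name, k))
    offset <- n_placed
    pos[[length(pos) + 1L]] <<- coords
    if (nrow(graph$edges)) {
      bonds[[length(bonds) + 1L]] <<- graph$edges + offset
    }
    next_mol <<- next_mol + 1L
    n_placed <<- n_placed + k
  }

  wrap <- function(coords) {
    for (d in 1:3) {
      if (box$periodic[d]) coords[, d] <- coords[, d] %% box$edges[d]
    }
    coords
  }

  place_tube <- function(spec, anchor, orient) {
    coords <- tube_coordinates(spec$graph, bond_length = 0.86)
    # rotate the canonical +z layout onto `orient`, center on the anchor
    coords <- rotate_onto(coords, orient)
    sweep(coords, 2, anchor - colMeans(coords), `+`)
  }

  ## compartment contents
  for (ci in seq_along(compartments)) {
    cp <- compartments[[ci]]
    requested <- sum(vapply(cp$contents, function(ct)
      ct$count * length(ct$spec$graph$particles), 1))
    capacity <- round(box$density * compartment_volume(cp, box))
    if (requested > capacity) {
      stop(sprintf("overfilled compartment %d: %d particles requested, capacity %d",
                   ci, as.integer(requested), as.integer(capacity)))
    }
    for (ct in cp$contents) {
      orientation <- if (is.null(ct$orientation)) "random" else ct$orientation
      if (cp$lattice) {
        latt <- place_lattice_layer(cp, box, ct$count)
        for (m in seq_len(ct$count)) {
          add_molecule(ct$spec$name, ct$spec$graph, latt[m, , drop = FALSE])
        }
        next
      }
      for (m in seq_len(ct$count)) {
        placed_ok <- FALSE
        for (att in seq_len(max_attempts)) {
          anchor <- random_point_in_compartment(cp, box)
          if (owner(anchor) != ci || excluded(anchor)) next
          if (is.character(orientation) && orientation %in% c("inward", "outward") &&
              cp$kind == "sphere") {
            radial <- anchor - cp$center
            rl <- sqrt(sum(radial^2))
            u <- if (rl > 1e-9) radial / rl else random_unit_vector()
            coords <- orient_start_end(ct$spec$graph, anchor, u,
                                       outward = orientation == "outward")
          } else if (is.numeric(orientation)) {
            coords <- place_tube(ct$spec, anchor, orientation)
          } else {
            coords <- place_tube(ct$spec, anchor, random_unit_vector())
          }
          add_molecule(ct$spec$name, ct$spec$graph, wrap(coords))
          placed_ok <- TRUE
          break
        }
        if (!placed_ok) {
          stop(sprintf("could not place %s in compartment %d after %d attempts",
                       ct$spec$name, ci, max_attempts))
        }
      }
    }
  }

  ## proteins: collapsed + shrunk, with exclusion spheres
  probe_map <- character(0)
  for (pr in proteins) {
    pp <- pr$pp
    if (length(pp$probe_map)) probe_map <- c(probe_map, pp$probe_map)
    volumes <- if (!is.null(set)) {
      set$types$volume[match(pp$graph$particles, set$types$name)] /
        pp$length_scale^3
    } else rep(1 / box$density, length(pp$graph$particles))
    for (m in seq_len(pr$count)) {
      collapsed <- collapse_sidechains(pp)
      placed_ok <- FALSE
      for (att in seq_len(max_attempts)) {
        anchor <- stats::runif(3) * box$edges
        sh <- shrink_to_sphere(collapsed, volumes, center = anchor)
        if (owner(anchor) != 0L || excluded(anchor)) next
        add_molecule(if (!is.null(pr$name)) pr$name else "protein",
                     pp$graph, wrap(sh$positions))
        exclusions[[length(exclusions) + 1L]] <- list(center = anchor,
                                                      radius = sh$radius)
        placed_ok <- TRUE
        break
      }
      if (!placed_ok) stop("could not place protein after ", max_attempts, " attempts")
    }
  }

  ## bulk molecules fill the remainder, outside all compartments
  nm_specs <- vapply(specs, function(s) s$name, "")
  if (is.null(names(counts))) names(counts) <- nm_specs
  counts <- counts[nm_specs]
  sizes <- vapply(specs, function(s) length(s$graph$particles), 1L)
  if (is.null(filler)) {
    cand <- which(sizes == 1L)
    filler <- if (length(cand)) names(counts)[cand[1]] else names(counts)[which.max(counts)]
  }
  remainder <- total - n_placed - sum(counts * sizes) +
    counts[filler] * sizes[names(counts) == filler][1]
  fsize <- sizes[names(counts) == filler][1]
  if (remainder < 0 || remainder %% fsize != 0) {
    stop("composition does not fit the box: ", remainder,
         " particles left for filler of size ", fsize)
  }
  counts[filler] <- remainder / fsize
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (m in seq_len(counts[spec$name])) {
      placed_ok <- FALSE
      for (att in seq_len(max_attempts)) {
        anchor <- stats::runif(3) * box$edges
        if (owner(anchor) != 0L || excluded(anchor)) next
        coords <- if (length(spec$graph$particles) == 1L) {
          matrix(anchor, 1, 3)
        } else {
          wrap(place_tube(spec, anchor, random_unit_vector()))
        }
        add_molecule(spec$name, spec$graph, coords)
        placed_ok <- TRUE
        break
      }
      if (!placed_ok) {
        stop("could not place bulk molecule ", spec$name, " after ",
             max_attempts, " attempts")
      }
    }
  }

  particles <- data.frame(type = type, molecule_id = mol_id,
                          molecule_type = mol_type,
                          stringsAsFactors = FALSE)
  coords <- do.call(rbind, pos)
  particles$x <- coords[, 1]; particles$y <- coords[, 2]; particles$z <- coords[, 3]
  bm <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  structure(list(particles = particles, bonds = bm, box = box,
                 probe_map = probe_map),
            class = "start_configuration")
}

# rotate coords so that unit vector `z` maps onto `u`
rotate_vec_onto <- function(coords, z, u) {
  u <- u / sqrt(sum(u^2))
  z <- z / sqrt(sum(z^2))
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2))
  c0 <- sum(z * u)
  if (s < 1e-12) {
    if (c0 > 0) return(coords)
    # 180 degrees about any axis perpendicular to z
    p <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- p - sum(p * z) * z
    a <- a / sqrt(sum(a^2))
    R <- 2 * outer(a, a) - diag(3)
    return(coords %*% t(R))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
  coords %*% t(R)
}

rotate_onto <- function(coords, u) rotate_vec_onto(coords, c(0, 0, 1), u)

# directed placement: rotate the molecule so its END -> START vector lies
# along the radial axis (outward: START points away from the sphere
# center), then put the START/END midpoint on the anchor — both tagged
# ends sit exactly on the radial axis, so the orientation predicate holds
# by construction
orient_start_end <- function(graph, anchor, u, outward) {
  coords <- tube_coordinates(graph, bond_length = 0.86)
  si <- which(graph$tag == "START")
  ei <- which(graph$tag == "END")
  if (!length(si) || !length(ei)) {
    coords <- rotate_onto(coords, u)
    return(sweep(coords, 2, anchor - colMeans(coords), `+`))
  }
  w <- coords[si, ] - coords[ei, ]
  target <- if (outward) u else -u
  coords <- rotate_vec_onto(coords, w, target)
  mid <- (coords[si, ] + coords[ei, ]) / 2
  sweep(coords, 2, anchor - mid, `+`)
}

#' @export
print.start_configuration <- function(x, ...) {
  cat(sprintf("start_configuration: %d particle(s), %d molecule(s), %d bond(s), box %s\n",
              nrow(x$particles), length(unique(x$particles$molecule_id)),
              nrow(x$bonds),
              paste(signif(x$box$edges, 4), collapse = " x ")))
  invisible(x)
}
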