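#' Parse a PDB file into a CA-trace protein model
#'
#' Reads ATOM records (via bio3d), keeps one residue per (chain, residue
#' number) anchored at its alpha-carbon coordinate. Alternate locations are
#' resolved to the highest-occupancy copy. SSBOND records and REMARK 350
#' biological-assembly transforms are parsed from the raw text; transforms
#' of the selected assembly can be applied to replicate chains.
#'
#' @param text PDB file content (single string or lines) or a path when
#'   \code{is_path = TRUE}.
#' @param exclude_chains chain identifiers to drop.
#' @param assembly biological assembly id to apply from REMARK 350
#'   (\code{NULL} = asymmetric unit as given).
#' @param is_path treat \code{text} as a file path.
#' @return object of class \code{protein_model}: list with \code{residues}
#'   (data.frame chain, resno, three, x, y, z in Angstrom), \code{ssbonds}
#'   (data.frame chain1, resno1, chain2, resno2) and \code{assemblies}
#'   (list of transform lists).
#' @export
parse_pdb <- function(text, exclude_chains = character(0), assembly = NULL,
                      is_path = FALSE) {
  if (is_path) {
    lines <- readLines(text, warn = FALSE)
    path <- text
  } else {
    lines <- if (length(text) == 1L && grepl("\n", text))
      strsplit(text, "\r?\n")[[1]] else text
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB format error: ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("PDB parse error: no CA atoms found")
  # alternate locations: keep highest occupancy per (chain, resno)
  at$o[is.na(at$o)] <- 1
  at <- at[order(at$chain, at$resno, -at$o), , drop = FALSE]
  at <- at[!duplicated(at[, c("chain", "resno")]), , drop = FALSE]
  at <- at[!(at$chain %in% exclude_chains), , drop = FALSE]
  if (!nrow(at)) stop("empty protein model: all chains excluded")
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  residues <- data.frame(chain = at$chain, resno = at$resno,
                         three = to_title_case3(at$resid),
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE)
  ## SSBOND records
  ss <- grep("^SSBOND", lines, value = TRUE)
  ssbonds <- if (length(ss)) {
    do.call(rbind, lapply(ss, function(l) {
      data.frame(chain1 = trimws(substr(l, 16, 16)),
                 resno1 = as.integer(substr(l, 18, 21)),
                 chain2 = trimws(substr(l, 30, 30)),
                 resno2 = as.integer(substr(l, 32, 35)),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(chain1 = character(0), resno1 = integer(0),
                    chain2 = character(0), resno2 = integer(0))
  assemblies <- parse_remark350(lines)
  model <- structure(list(residues = residues, ssbonds = ssbonds,
                          assemblies = assemblies),
                     class = "protein_model")
  if (!is.null(assembly)) model <- apply_assembly(model, assembly)
  model
}

to_title_case3 <- function(x) {
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}

# REMARK 350 BIOMT transform blocks, one list element per assembly
parse_remark350 <- function(lines) {
  rem <- grep("^REMARK 350", lines, value = TRUE)
  if (!length(rem)) return(list())
  assemblies <- list()
  current <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(current) && length(rows)) {
      mats <- list()
      ids <- unique(vapply(rows, function(r) r$id, 1))
      for (id in ids) {
        m <- do.call(rbind, lapply(rows[vapply(rows, function(r) r$id, 1) == id],
                                   function(r) r$row))
        if (nrow(m) == 3L) mats[[length(mats) + 1L]] <- m
      }
      assemblies[[as.character(current)]] <<- mats
    }
    rows <<- list()
  }
  for (l in rem) {
    if (grepl("BIOMOLECULE:", l)) {
      flush()
      current <- as.integer(sub(".*BIOMOLECULE:\\s*", "", l))
    } else if (grepl("BIOMT[123]", l)) {
      f <- strsplit(trimws(sub("^REMARK 350\\s+BIOMT[123]", "", l)), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- list(id = as.integer(f[1]),
                                        row = as.numeric(f[2:5]))
    }
  }
  flush()
  assemblies
}

apply_assembly <- function(model, assembly) {
  key <- as.character(assembly)
  if (!key %in% names(model$assemblies)) {
    if (identical(assembly, 1L) || identical(assembly, 1)) return(model)
    stop("biological assembly not present in PDB: ", assembly)
  }
  mats <- model$assemblies[[key]]
  res <- model$residues
  out <- list()
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    r <- res
    xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(m[, 1:3])
    r$x <- xyz[, 1] + m[1, 4]
    r$y <- xyz[, 2] + m[2, 4]
    r$z <- xyz[, 3] + m[3, 4]
    if (k > 1L) r$chain <- paste0(r$chain, k)
    out[[k]] <- r
  }
  model$residues <- do.call(rbind, out)
  model
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein_model: %d residue(s) in %d chain(s)\n",
              nrow(x$residues), length(unique(x$residues$chain))))
  invisible(x)
}

#' In-silico point mutations on a protein model
#'
#' Changes residue identities only; the backbone (CA) coordinates and the
#' residue count are untouched, so the mutant keeps the wild-type 3D
#' backbone structure.
#'
#' @param model a \code{protein_model}.
#' @param mutations data.frame with columns \code{chain}, \code{resno},
#'   \code{three} (new three-letter code), or a list of such triples.
#' @return the mutated \code{protein_model}.
#' @export
mutate_protein <- function(model, mutations) {
  stopifnot(inherits(model, "protein_model"))
  if (is.null(mutations) || (is.data.frame(mutations) && !nrow(mutations))) {
    return(model)
  }
  if (!is.data.frame(mutations)) {
    mutations <- do.call(rbind, lapply(mutations, function(m) {
      data.frame(chain = m[[1]], resno = as.integer(m[[2]]), three = m[[3]],
                 stringsAsFactors = FALSE)
    }))
  }
  for (k in seq_len(nrow(mutations))) {
    hit <- model$residues$chain == mutations$chain[k] &
      model$residues$resno == mutations$resno[k]
    if (!any(hit)) {
      stop(sprintf("mutation target not found: chain %s residue %d",
                   mutations$chain[k], mutations$resno[k]))
    }
    model$residues$three[hit] <- mutations$three[k]
  }
  model
}

#' Protonation state of a residue side chain at a pH
#'
#' Step-function titration: an acidic side chain (its charged variant is
#' negative) is charged when pH > pKa, a basic one (positive variant) when
#' pH < pKa. Residues without an ionizable side chain (no pKa in the table)
#' are always neutral. Charges are integral per particle; no fractional
#' occupancies.
#'
#' @param residue three-letter code.
#' @param pH solution pH.
#' @param table amino-acid table (the \code{amino_acids} data.frame of a
#'   \code{particle_set}).
#' @return \code{"charged"} or \code{"neutral"}.
#' @export
protonation_state <- function(residue, pH, table) {
  row <- table[table$three == residue, , drop = FALSE]
  if (!nrow(row)) stop("unknown residue: ", residue)
  pka <- row$pka[1]
  if (is.na(pka) || is.na(row$charged_spices[1])) return("neutral")
  acidic <- residue_is_acidic(row)
  if (acidic) {
    if (pH > pka) "charged" else "neutral"
  } else {
    if (pH < pka) "charged" else "neutral"
  }
}

# a residue is acidic if its charged variant carries net negative charge
residue_is_acidic <- function(row) {
  g <- parse_spices(row$charged_spices[1])
  q <- sum(g$charge)
  if (q < 0) return(TRUE)
  if (q > 0) return(FALSE)
  # fall back on the pKa range when the variant notation is uncharged
  row$pka[1] < 7
}

#' Convert a protein model to a particle representation
#'
#' Assembles per-residue fragments exactly as \code{\link{peptide_to_spices}}
#' does (chained backbone-to-backbone per chain, protonation by pH,
#' SSBOND-derived disulfides), anchors every backbone particle at its
#' residue's CA coordinate scaled to box units by the set's DPD length
#' scale, and attaches segment labels for intra-protein force assignment.
#' Probe replacements relabel backbone particles only; the probe keeps the
#' original particle's interactions.
#'
#' @param model a \code{protein_model}.
#' @param set a \code{particle_set} with an amino-acid table.
#' @param pH solution pH.
#' @param mutations optional mutations (see \code{\link{mutate_protein}}).
#' @param segments optional data.frame \code{chain, from, to, segment}
#'   assigning a segment token to a residue-number range.
#' @param probes optional data.frame \code{chain, resno, probe} renaming
#'   the backbone particle of selected residues.
#' @param density DPD density used for the length scale.
#' @return object of class \code{protein_particles}: list with \code{graph}
#'   (\code{spices_graph}), \code{backbone_nodes} (integer vector, one per
#'   residue), \code{backbone_coords} (matrix, r_c units), \code{segments}
#'   (character per backbone node), \code{residues} (the residue table).
#' @export
protein_to_particles <- function(model, set, pH = 7, mutations = NULL,
                                 segments = NULL, probes = NULL, density = 3) {
  stopifnot(inherits(model, "protein_model"), inherits(set, "particle_set"))
  model <- mutate_protein(model, mutations)
  res <- model$residues
  aa <- set$amino_acids
  missing <- setdiff(unique(res$three), aa$three)
  if (length(missing)) {
    stop("residue(s) missing from amino-acid table: ",
         paste(missing, collapse = ", "))
  }
  scale <- dpd_length_scale(set, density)
  chains <- unique(res$chain)
  particles <- character(0); charge <- integer(0); backbone <- integer(0)
  tag <- character(0); depth <- integer(0)
  edges <- list()
  bb_nodes <- integer(nrow(res))
  sc_anchor <- rep(NA_integer_, nrow(res))
  offset <- 0L
  for (ch in chains) {
    idx <- which(res$chain == ch)
    prev_bb <- 0L
    for (r in idx) {
      row <- aa[aa$three == res$three[r], , drop = FALSE]
      state <- protonation_state(res$three[r], pH, aa)
      frag <- parse_spices(if (state == "charged" && !is.na(row$charged_spices[1]))
                             row$charged_spices[1] else row$spices[1])
      nf <- length(frag$particles)
      fq <- frag$charge
      tq <- set$types$charge[match(frag$particles, set$types$name)]
      fq[fq == 0L & !is.na(tq)] <- tq[fq == 0L & !is.na(tq)]
      particles <- c(particles, frag$particles)
      charge <- c(charge, fq)
      backbone <- c(backbone, rep(NA_integer_, nf))
      tag <- c(tag, rep(NA_character_, nf))
      depth <- c(depth, ifelse(seq_len(nf) == row$backbone_index[1], 0L, 1L))
      if (nrow(frag$edges)) {
        for (k in seq_len(nrow(frag$edges))) {
          edges[[length(edges) + 1L]] <- frag$edges[k, ] + offset
        }
      }
      bb <- offset + row$backbone_index[1]
      backbone[bb] <- r
      bb_nodes[r] <- bb
      if (nf > 1L) sc_anchor[r] <- offset + nf
      if (prev_bb > 0L) edges[[length(edges) + 1L]] <- c(prev_bb, bb)
      prev_bb <- bb
      offset <- offset + nf
    }
  }
  # disulfides from SSBOND
  if (nrow(model$ssbonds)) {
    for (k in seq_len(nrow(model$ssbonds))) {
      s <- model$ssbonds[k, ]
      r1 <- which(res$chain == s$chain1 & res$resno == s$resno1)
      r2 <- which(res$chain == s$chain2 & res$resno == s$resno2)
      if (length(r1) == 1L && length(r2) == 1L &&
          !is.na(sc_anchor[r1]) && !is.na(sc_anchor[r2])) {
        edges[[length(edges) + 1L]] <- c(sc_anchor[r1], sc_anchor[r2])
      }
    }
  }
  # probe replacement: backbone label only, interactions untouched; the
  # probe -> original mapping travels with the model so the engine can
  # resolve the probe's physical identity
  probe_map <- character(0)
  if (!is.null(probes) && nrow(probes)) {
    for (k in seq_len(nrow(probes))) {
      r <- which(res$chain == probes$chain[k] & res$resno == probes$resno[k])
      if (!length(r)) stop("probe target not found")
      probe_map[probes$probe[k]] <- particles[bb_nodes[r]]
      particles[bb_nodes[r]] <- probes$probe[k]
    }
  }
  seg_label <- rep(NA_character_, nrow(res))
  if (!is.null(segments) && nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      s <- segments[k, ]
      hit <- res$chain == s$chain & res$resno >= s$from & res$resno <= s$to
      if (s$from < min(res$resno[res$chain == s$chain]) ||
          s$to > max(res$resno[res$chain == s$chain])) {
        stop("segment range outside chain bounds: ", s$segment)
      }
      seg_label[hit] <- s$segment
    }
  }
  graph <- new_spices_graph(particles, charge, backbone, tag, depth, edges)
  validate_spices_graph(graph)
  coords <- as.matrix(res[, c("x", "y", "z")]) / scale
  structure(list(graph = graph, backbone_nodes = bb_nodes,
                 backbone_coords = coords, segments = seg_label,
                 residues = res, length_scale = scale,
                 probe_map = probe_map),
            class = "protein_particles")
}

#' @export
print.protein_particles <- function(x, ...) {
  cat(sprintf("protein_particles: %d particle(s), %d backbone node(s), %d bond(s)\n",
              length(x$graph$particles), length(x$backbone_nodes),
              nrow(x$graph$edges)))
  invisible(x)
}

#' Collapse side-chain particles onto their backbone particles
#'
#' Returns full particle positions for a protein particle model: every
#' backbone particle sits at its CA-derived coordinate, every side-chain
#' particle at its nearest bonded backbone particle's coordinate plus a
#' tiny jitter (at most \code{jitter} r_c) to avoid exactly coincident
#' pairs.
#'
#' @param pp a \code{protein_particles} object.
#' @param jitter maximal random displacement (r_c); 0 collapses exactly.
#' @return numeric matrix n x 3 (r_c units).
#' @export
collapse_sidechains <- function(pp, jitter = 0.01) {
  stopifnot(inherits(pp, "protein_particles"))
  g <- pp$graph
  n <- length(g$particles)
  pos <- matrix(NA_real_, n, 3)
  pos[pp$backbone_nodes, ] <- pp$backbone_coords
  is_bb <- logical(n)
  is_bb[pp$backbone_nodes] <- TRUE
  adj <- spices_adjacency(g)
  # BFS from backbone so nested side-chain particles inherit the coordinate
  # of the backbone particle they hang off
  anchor <- rep(NA_integer_, n)
  anchor[pp$backbone_nodes] <- pp$backbone_nodes
  q <- pp$backbone_nodes
  while (length(q)) {
    u <- q[1L]; q <- q[-1L]
    for (v in adj[[u]]) if (is.na(anchor[v])) {
      anchor[v] <- anchor[u]
      q <- c(q, v)
    }
  }
  side <- which(!is_bb)
  for (v in side) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2)) * stats::runif(1, 0, jitter)
    pos[v, ] <- pos[anchor[v], ] + if (jitter > 0) d else 0
  }
  pos
}

#' Shrink particle positions into a virtual sphere
#'
#' Scales positions about \code{center} so that all particles lie inside a
#' sphere whose volume equals the summed DPD volume of the particles:
#' radius \eqn{r = (3 \sum V / 4\pi)^{1/3}} (same units as the supplied
#' volumes; divide by a length scale first to work in r_c). Geometry is
#' preserved up to uniform scaling; already-compact inputs are recentred
#' only.
#'
#' @param positions n x 3 matrix.
#' @param volumes per-particle volumes (same length unit cubed as
#'   \code{positions} are expressed in).
#' @param center 3-vector sphere center.
#' @return list with \code{positions} (n x 3) and \code{radius}.
#' @export
shrink_to_sphere <- function(positions, volumes, center = c(0, 0, 0)) {
  positions <- rbind(positions)
  n <- nrow(positions)
  stopifnot(n >= 1L, length(volumes) %in% c(1L, n))
  if (length(volumes) == 1L) volumes <- rep(volumes, n)
  radius <- (3 * sum(volumes) / (4 * pi))^(1 / 3)
  if (n == 1L) {
    return(list(positions = matrix(center, 1, 3), radius = radius))
  }
  cm <- colMeans(positions)
  rel <- sweep(positions, 2, cm)
  rmax <- max(sqrt(rowSums(rel^2)))
  if (rmax > radius) rel <- rel * (radius / rmax)
  list(positions = sweep(rel, 2, center, `+`), radius = radius)
}
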