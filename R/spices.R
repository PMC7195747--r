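#' Parse a SPICES molecular line notation
#'
#' SPICES describes a molecule as a graph of particle tokens. The grammar
#' subset supported here:
#' \itemize{
#'   \item particle tokens (a letter followed by letters/digits) joined by
#'     \code{-} form chains;
#'   \item parenthesized groups branch from the preceding particle,
#'     e.g. \code{A(B)(C)-D} bonds B, C and D to A;
#'   \item an integer prefix \code{nP} repeats particle P n times as a
#'     linear chain (so \code{6Et} is a six-particle tail, not a star);
#'   \item bracket tags attach to the preceding particle:
#'     \code{[START]}/\code{[END]} orientation tags, \code{[3]} a backbone
#'     index, \code{[+]}, \code{[-]}, \code{[+2]} a formal charge;
#'   \item ring closures via matched numeric labels in braces: two particles
#'     carrying the same \code{{n}} label are bonded.
#' }
#' A tag or label after a repeated particle applies to the last particle of
#' the expansion. Line breaks and whitespace are stripped before parsing
#' (long peptide notations are often wrapped). Anything else is rejected
#' with the character position of the offending input.
#'
#' @param notation a SPICES string.
#' @return an object of class \code{spices_graph}: list with
#'   \code{particles} (character), \code{charge} (integer),
#'   \code{backbone_index} (integer, NA where unset), \code{tag}
#'   (\code{"START"}, \code{"END"} or NA), \code{depth} (branch nesting
#'   level, 0 = main chain) and \code{edges} (2-column integer matrix of
#'   bonds, 1-based).
#' @export
parse_spices <- function(notation) {
  if (length(notation) != 1L || !nzchar(notation)) stop("empty SPICES notation")
  s <- gsub("[[:space:]]+", "", notation)
  if (!nzchar(s)) stop("empty SPICES notation")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$particles <- character(0)
  env$charge <- integer(0)
  env$backbone <- integer(0)
  env$tag <- character(0)
  env$depth <- integer(0)
  env$edges <- list()
  env$rings <- list()  # label -> node index awaiting its partner

  perr <- function(msg, at = env$pos) {
    stop(sprintf("illegal SPICES line notation at position %d: %s", at, msg),
         call. = FALSE)
  }
  peek <- function() if (env$pos <= n) chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L

  add_node <- function(token, depth) {
    env$particles <- c(env$particles, token)
    env$charge <- c(env$charge, 0L)
    env$backbone <- c(env$backbone, NA_integer_)
    env$tag <- c(env$tag, NA_character_)
    env$depth <- c(env$depth, depth)
    length(env$particles)
  }
  add_edge <- function(i, j) {
    if (i == j) perr("self-bond")
    key <- paste(min(i, j), max(i, j))
    if (key %in% vapply(env$edges, function(e) paste(min(e), max(e)), ""))
      perr("duplicate bond")
    env$edges[[length(env$edges) + 1L]] <- c(i, j)
  }
  read_int <- function() {
    start <- env$pos
    while (grepl("[0-9]", peek())) advance()
    if (env$pos == start) return(NA_integer_)
    as.integer(paste(chars[start:(env$pos - 1L)], collapse = ""))
  }
  read_name <- function() {
    start <- env$pos
    if (!grepl("[A-Za-z]", peek())) perr("expected particle token")
    advance()
    while (grepl("[A-Za-z0-9]", peek())) advance()
    paste(chars[start:(env$pos - 1L)], collapse = "")
  }

  read_unit <- function(depth, prev) {
    count <- read_int()
    if (!is.na(count) && count < 1L) perr("repeat count must be >= 1")
    if (is.na(count)) count <- 1L
    token <- read_name()
    last <- prev
    for (k in seq_len(count)) {
      node <- add_node(token, depth)
      if (last > 0L) add_edge(last, node)
      last <- node
    }
    # suffixes attach to the last particle of the expansion
    repeat {
      c0 <- peek()
      if (c0 == "[") {
        at <- env$pos
        advance()
        start <- env$pos
        while (peek() != "]" && peek() != "") advance()
        if (peek() != "]") perr("unclosed '['", at)
        content <- paste(chars[start:(env$pos - 1L)], collapse = "")
        if (env$pos == start) perr("empty brackets", at)
        advance()
        if (content %in% c("START", "END")) {
          if (!is.na(env$tag[last])) perr("particle already tagged", at)
          env$tag[last] <- content
        } else if (grepl("^[+-][0-9]*$", content)) {
          mag <- sub("^[+-]", "", content)
          q <- if (nzchar(mag)) as.integer(mag) else 1L
          env$charge[last] <- if (substr(content, 1, 1) == "-") -q else q
        } else if (grepl("^[0-9]+$", content)) {
          env$backbone[last] <- as.integer(content)
        } else {
          perr(sprintf("unknown bracket content '%s'", content), at)
        }
      } else if (c0 == "{") {
        at <- env$pos
        advance()
        lab <- read_int()
        if (is.na(lab)) perr("ring label must be an integer", at)
        if (peek() != "}") perr("unclosed '{'", at)
        advance()
        key <- as.character(lab)
        if (!is.null(env$rings[[key]])) {
          add_edge(env$rings[[key]], last)
          env$rings[[key]] <- NULL
        } else {
          env$rings[[key]] <- last
        }
      } else break
    }
    last
  }

  parse_chain <- function(depth, prev) {
    repeat {
      last <- read_unit(depth, prev)
      while (peek() == "(") {
        advance()
        parse_chain(depth + 1L, last)
        if (peek() != ")") perr("unclosed '('")
        advance()
      }
      if (peek() == "-") {
        advance()
        prev <- last
      } else {
        return(last)
      }
    }
  }

  parse_chain(0L, 0L)
  if (env$pos <= n) perr(sprintf("unexpected character '%s'", peek()))
  if (length(env$rings)) perr(sprintf("unmatched ring label(s): %s",
                                      paste(names(env$rings), collapse = ", ")), n)
  g <- new_spices_graph(env$particles, env$charge, env$backbone, env$tag,
                        env$depth, env$edges)
  validate_spices_graph(g)
  g
}

new_spices_graph <- function(particles, charge, backbone, tag, depth, edges) {
  em <- if (length(edges)) {
    if (is.matrix(edges)) edges else do.call(rbind, edges)
  } else matrix(integer(0), 0, 2)
  storage.mode(em) <- "integer"
  structure(list(particles = particles, charge = as.integer(charge),
                 backbone_index = as.integer(backbone),
                 tag = as.character(tag), depth = as.integer(depth),
                 edges = em),
            class = "spices_graph")
}

validate_spices_graph <- function(g) {
  n <- length(g$particles)
  if (n == 0L) stop("empty molecule graph")
  if (sum(g$tag == "START", na.rm = TRUE) > 1L) stop("more than one [START] tag")
  if (sum(g$tag == "END", na.rm = TRUE) > 1L) stop("more than one [END] tag")
  bi <- g$backbone_index[!is.na(g$backbone_index)]
  if (anyDuplicated(bi)) stop("backbone indices must be unique")
  if (nrow(g$edges)) {
    if (any(g$edges[, 1] == g$edges[, 2])) stop("self-bond in molecule graph")
    if (any(g$edges < 1L) || any(g$edges > n)) stop("bond index out of range")
  }
  # connectivity
  if (n > 1L) {
    seen <- logical(n)
    queue <- 1L
    seen[1L] <- TRUE
    adj <- spices_adjacency(g)
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[u]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    if (!all(seen)) stop("molecule graph is not connected")
  }
  invisible(g)
}

spices_adjacency <- function(g) {
  n <- length(g$particles)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1]; j <- g$edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, sort)
}

#' @export
print.spices_graph <- function(x, ...) {
  cat(sprintf("spices_graph: %d particle(s), %d bond(s)\n",
              length(x$particles), nrow(x$edges)))
  cat("  ", write_spices(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a molecule graph to SPICES notation
#'
#' Canonical traversal: depth-first from the lowest-index node, branches in
#' node-index order; cycle-closing bonds are emitted as matched brace
#' labels. The output reparses to an isomorphic graph.
#'
#' @param graph a \code{spices_graph}.
#' @return a SPICES string.
#' @export
write_spices <- function(graph) {
  validate_spices_graph(graph)
  n <- length(graph$particles)
  adj <- spices_adjacency(graph)
  # spanning tree by DFS from node 1, ascending neighbor order
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  order <- integer(0)
  stack <- 1L
  visited[1L] <- TRUE
  tree_edges <- character(0)
  ring_suffix <- rep("", n)
  next_label <- 1L
  # iterative DFS recording tree edges
  dfs_children <- rep(list(integer(0)), n)
  st <- c(1L)
  while (length(st)) {
    u <- st[length(st)]; st <- st[-length(st)]
    for (v in rev(adj[[u]])) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        dfs_children[[u]] <- c(dfs_children[[u]], v)
        tree_edges <- c(tree_edges, paste(min(u, v), max(u, v)))
        st <- c(st, v)
      }
    }
  }
  if (!all(visited)) stop("disconnected graph cannot be serialized")
  # non-tree edges get ring labels on both endpoints
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      key <- paste(min(i, j), max(i, j))
      if (!key %in% tree_edges) {
        lab <- sprintf("{%d}", next_label)
        next_label <- next_label + 1L
        ring_suffix[i] <- paste0(ring_suffix[i], lab)
        ring_suffix[j] <- paste0(ring_suffix[j], lab)
      }
    }
  }
  emit_node <- function(u) {
    s <- graph$particles[u]
    q <- graph$charge[u]
    if (!is.na(q) && q != 0L) {
      s <- paste0(s, "[", if (q > 0) "+" else "-",
                  if (abs(q) > 1L) abs(q) else "", "]")
    }
    if (!is.na(graph$backbone_index[u])) {
      s <- paste0(s, "[", graph$backbone_index[u], "]")
    }
    if (!is.na(graph$tag[u])) s <- paste0(s, "[", graph$tag[u], "]")
    paste0(s, ring_suffix[u])
  }
  emit <- function(u) {
    s <- emit_node(u)
    ch <- sort(dfs_children[[u]])
    if (length(ch)) {
      for (c0 in ch[-length(ch)]) s <- paste0(s, "(", emit(c0), ")")
      s <- paste0(s, "-", emit(ch[length(ch)]))
    }
    s
  }
  emit(1L)
}

#' Expand monomer placeholders into a polymer graph
#'
#' Each node of \code{structure} whose particle token names a monomer in
#' \code{monomers} is replaced by that monomer's graph. Bonds from
#' lower-index neighbors of the placeholder attach to the monomer's head
#' (its lowest backbone index, or first node), bonds to higher-index
#' neighbors attach to its tail (highest backbone index, or last node).
#'
#' @param structure a SPICES string or \code{spices_graph} whose tokens may
#'   be monomer names.
#' @param monomers named list mapping monomer token to SPICES string or
#'   \code{spices_graph}.
#' @return the expanded \code{spices_graph}.
#' @export
expand_polymer <- function(structure, monomers) {
  g <- if (inherits(structure, "spices_graph")) structure else parse_spices(structure)
  monomers <- lapply(monomers, function(m) {
    if (inherits(m, "spices_graph")) m else parse_spices(m)
  })
  n <- length(g$particles)
  particles <- character(0); charge <- integer(0); backbone <- integer(0)
  tag <- character(0); depth <- integer(0)
  edges <- list()
  head_of <- integer(n); tail_of <- integer(n)  # new indices per old node
  offset <- 0L
  for (u in seq_len(n)) {
    tok <- g$particles[u]
    if (tok %in% names(monomers)) {
      m <- monomers[[tok]]
      nm <- length(m$particles)
      particles <- c(particles, m$particles)
      charge <- c(charge, m$charge)
      backbone <- c(backbone, rep(NA_integer_, nm))  # indices are local to the monomer
      tag <- c(tag, rep(NA_character_, nm))
      tag[offset + which(!is.na(m$tag))] <- m$tag[!is.na(m$tag)]
      depth <- c(depth, m$depth)
      if (nrow(m$edges)) {
        for (k in seq_len(nrow(m$edges))) {
          edges[[length(edges) + 1L]] <- m$edges[k, ] + offset
        }
      }
      bi <- m$backbone_index
      head_local <- if (any(!is.na(bi))) which.min(bi) else 1L
      tail_local <- if (any(!is.na(bi))) which.max(bi) else nm
      head_of[u] <- offset + head_local
      tail_of[u] <- offset + tail_local
      offset <- offset + nm
    } else {
      particles <- c(particles, tok)
      charge <- c(charge, g$charge[u])
      backbone <- c(backbone, g$backbone_index[u])
      tag <- c(tag, g$tag[u])
      depth <- c(depth, g$depth[u])
      head_of[u] <- tail_of[u] <- offset + 1L
      offset <- offset + 1L
    }
  }
  # unresolved placeholders: tokens that look like monomer references are the
  # caller's responsibility; an explicit check catches missing definitions
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1]; j <- g$edges[k, 2]
      lo <- min(i, j); hi <- max(i, j)
      edges[[length(edges) + 1L]] <- c(tail_of[lo], head_of[hi])
    }
  }
  out <- new_spices_graph(particles, charge, backbone, tag, depth, edges)
  validate_spices_graph(out)
  out
}

#' Convert a one-letter peptide sequence to a molecule graph
#'
#' Each residue contributes its fragment from the particle set's amino-acid
#' table (the pH-appropriate protonation variant); fragments are chained
#' backbone-to-backbone. A cyclic peptide gains one backbone ring-closure
#' bond; disulfide bridges bond the side-chain particles of the named
#' cysteine residues.
#'
#' @param sequence one-letter residue string.
#' @param set a \code{particle_set} with a non-empty amino-acid table.
#' @param cyclic close the backbone into a ring.
#' @param disulfides list/matrix of residue index pairs (1-based, both must
#'   be cysteine).
#' @param pH solution pH for protonation-state selection.
#' @return a \code{spices_graph}; backbone particles carry backbone indices
#'   1..n in residue order.
#' @export
peptide_to_spices <- function(sequence, set, cyclic = FALSE,
                              disulfides = NULL, pH = 7) {
  stopifnot(inherits(set, "particle_set"))
  if (!nzchar(sequence)) stop("empty peptide sequence")
  if (!nrow(set$amino_acids)) stop("particle set has no amino-acid table")
  letters1 <- strsplit(sequence, "")[[1]]
  aa <- set$amino_acids
  particles <- character(0); charge <- integer(0); backbone <- integer(0)
  tag <- character(0); depth <- integer(0)
  edges <- list()
  bb_node <- integer(length(letters1))      # backbone node per residue
  sc_node <- rep(NA_integer_, length(letters1))  # side-chain bond anchor
  res_three <- character(length(letters1))
  offset <- 0L
  for (r in seq_along(letters1)) {
    row <- aa[aa$one == letters1[r], , drop = FALSE]
    if (!nrow(row)) stop("unknown residue letter: ", letters1[r])
    res_three[r] <- row$three[1]
    state <- protonation_state(row$three[1], pH, aa)
    frag <- parse_spices(if (state == "charged" && !is.na(row$charged_spices[1]))
                           row$charged_spices[1] else row$spices[1])
    nf <- length(frag$particles)
    # node charges default to the particle type's declared charge
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
    bb_node[r] <- bb
    if (nf > 1L) sc_node[r] <- offset + nf  # highest-index fragment node
    if (r > 1L) edges[[length(edges) + 1L]] <- c(bb_node[r - 1L], bb)
    offset <- offset + nf
  }
  if (cyclic && length(letters1) > 2L) {
    edges[[length(edges) + 1L]] <- c(bb_node[1L], bb_node[length(letters1)])
  } else if (cyclic) {
    stop("cyclic peptide needs at least 3 residues")
  }
  if (!is.null(disulfides)) {
    if (is.matrix(disulfides)) disulfides <- asplit(disulfides, 1)
    for (p in disulfides) {
      p <- as.integer(p)
      if (length(p) != 2L || any(p < 1L) || any(p > length(letters1))) {
        stop("invalid disulfide residue index")
      }
      if (any(res_three[p] != "Cys")) {
        stop("disulfide indices must reference cysteines")
      }
      if (any(is.na(sc_node[p]))) stop("cysteine fragment has no side-chain particle")
      edges[[length(edges) + 1L]] <- sc_node[p]
    }
  }
  out <- new_spices_graph(particles, charge, backbone, tag, depth, edges)
  validate_spices_graph(out)
  out
}

#' Tube start geometry for a molecule graph
#'
#' Lays the molecule's main chain (the longest graph path over a spanning
#' tree) along \code{orientation} at \code{bond_length} spacing; branch
#' particles are placed adjacent to their attachment particle. Overlong
#' bonds (ring closures of laid-out cycles) are relaxed by iterative
#' pair-pulling so that every bonded distance is at most
#' \code{2 * bond_length}.
#'
#' @param graph a \code{spices_graph}.
#' @param bond_length spacing in r_c.
#' @param origin 3-vector, position of the first chain particle.
#' @param orientation 3-vector, normalized internally.
#' @return numeric matrix n x 3 of particle positions (r_c units). Uses the
#'   R random number generator for branch directions; seed upstream for
#'   reproducibility.
#' @export
tube_coordinates <- function(graph, bond_length = 1, origin = c(0, 0, 0),
                             orientation = c(0, 0, 1)) {
  validate_spices_graph(graph)
  n <- length(graph$particles)
  pos <- matrix(0, n, 3)
  if (n == 1L) {
    pos[1, ] <- origin
    return(pos)
  }
  o <- orientation / sqrt(sum(orientation^2))
  adj <- spices_adjacency(graph)
  bfs <- function(start) {
    dist <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    dist[start] <- 0L
    q <- start
    while (length(q)) {
      u <- q[1L]; q <- q[-1L]
      for (v in adj[[u]]) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L; par[v] <- u; q <- c(q, v)
      }
    }
    list(dist = dist, parent = par)
  }
  # graph diameter path via double BFS
  b1 <- bfs(1L)
  e1 <- which.max(b1$dist)
  b2 <- bfs(e1)
  e2 <- which.max(b2$dist)
  chain <- e2
  while (!is.na(b2$parent[chain[1L]])) chain <- c(b2$parent[chain[1L]], chain)
  if (chain[1L] > chain[length(chain)]) chain <- rev(chain)
  placed <- logical(n)
  cyclic <- nrow(graph$edges) >= n
  if (cyclic && length(chain) > 2L) {
    # lay the main chain on a circle so the closing bond stays short
    m <- length(chain)
    R <- m * bond_length / (2 * pi)
    # orthonormal frame with the first axis along the orientation
    a1 <- o
    ref <- if (abs(o[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a2 <- ref - sum(ref * o) * o
    a2 <- a2 / sqrt(sum(a2^2))
    for (k in seq_len(m)) {
      th <- 2 * pi * (k - 1L) / m
      pos[chain[k], ] <- origin + R * (cos(th) - 1) * a2 + R * sin(th) * a1
      placed[chain[k]] <- TRUE
    }
  } else {
    for (k in seq_along(chain)) {
      pos[chain[k], ] <- origin + (k - 1L) * bond_length * o
      placed[chain[k]] <- TRUE
    }
  }
  # branches: BFS out from the chain, each node adjacent to its parent
  q <- chain
  while (length(q)) {
    u <- q[1L]; q <- q[-1L]
    for (v in adj[[u]]) if (!placed[v]) {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      pos[v, ] <- pos[u, ] + bond_length * d
      placed[v] <- TRUE
      q <- c(q, v)
    }
  }
  # relax overlong bonds (cycles laid out straight)
  if (nrow(graph$edges)) {
    for (sweep in 1:400) {
      worst <- 0
      for (k in seq_len(nrow(graph$edges))) {
        i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
        d <- pos[j, ] - pos[i, ]
        len <- sqrt(sum(d^2))
        worst <- max(worst, len)
        if (len > 1.5 * bond_length && len > 0) {
          pull <- 0.5 * (len - bond_length) * d / len
          pos[i, ] <- pos[i, ] + pull
          pos[j, ] <- pos[j, ] - pull
        }
      }
      if (worst <= 2 * bond_length) break
    }
  }
  pos
}
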