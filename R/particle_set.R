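#' Parse a particle-set file
#'
#' A particle set is the force-field analogue of molecular fragment DPD: it
#' declares the particle (fragment) types, the symmetric pairwise repulsion
#' parameters \eqn{a_{ij}} per temperature, and optionally the amino-acid
#' fragment decompositions used for peptide and protein mapping.
#'
#' The text dialect is sectioned: section headers in square brackets on their
#' own line, \code{#} comments, whitespace-separated records, LF or CRLF line
#' endings. Sections:
#' \describe{
#'   \item{\code{[Particle description]}}{(mandatory) one record per type:
#'     \code{name mass charge volume [color] [radius]} with mass in Da,
#'     charge in elementary charges, volume in cubic Angstrom.}
#'   \item{\code{[Particle interactions]}}{(mandatory) a header line
#'     \code{pair T1 T2 ...} declaring the temperatures (K), then one record
#'     per unordered pair keyed \code{A_B} with one repulsion value per
#'     declared temperature.}
#'   \item{\code{[Amino acids]}}{(optional) one record per residue:
#'     \code{oneLetter threeLetter spices backboneIndex pKa chargedVariant}
#'     where \code{pKa} and \code{chargedVariant} may be \code{-}; the
#'     charged variant is \code{state=SPICES}.}
#' }
#' Unknown sections are skipped with a warning.
#'
#' @param text particle-set file content as a single string or character
#'   vector of lines, or a file path (when \code{is_path = TRUE}).
#' @param name set name (defaults to "particle_set").
#' @param is_path treat \code{text} as a file path.
#' @return an object of class \code{particle_set} with elements
#'   \code{name}, \code{types} (data.frame), \code{interactions} (long-format
#'   data.frame with columns a, b, temperature, repulsion) and
#'   \code{amino_acids} (data.frame, possibly empty).
#' @export
parse_particle_set <- function(text, name = "particle_set", is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\r?\n")[[1]]
  }
  lines <- sub("#.*$", "", gsub("\r$", "", text))
  lines <- trimws(lines)
  if (!any(nzchar(lines))) stop("empty particle-set text")

  section <- NA_character_
  sections <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(sections[[section]])) sections[[section]] <- character(0)
    } else {
      if (is.na(section)) stop("particle-set format error: content before first section header")
      sections[[section]] <- c(sections[[section]], ln)
    }
  }
  known <- c("Particle description", "Particle interactions", "Amino acids")
  unknown <- setdiff(names(sections), known)
  if (length(unknown)) {
    warning("ignoring unknown particle-set section(s): ",
            paste(unknown, collapse = ", "))
  }
  for (mand in c("Particle description", "Particle interactions")) {
    if (is.null(sections[[mand]])) {
      stop(sprintf("particle-set format error: missing mandatory section [%s]", mand))
    }
  }

  ## [Particle description]
  recs <- strsplit(sections[["Particle description"]], "\\s+")
  types <- do.call(rbind, lapply(recs, function(f) {
    if (length(f) < 4L) stop("particle-set format error: particle record needs name mass charge volume")
    data.frame(name = f[1], mass = as.numeric(f[2]), charge = as.integer(f[3]),
               volume = as.numeric(f[4]),
               color = if (length(f) >= 5L) f[5] else NA_character_,
               radius = if (length(f) >= 6L) as.numeric(f[6]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(types$name)) {
    stop("duplicate particle name: ",
         paste(unique(types$name[duplicated(types$name)]), collapse = ", "))
  }
  if (any(!is.finite(types$mass)) || any(types$mass <= 0)) stop("particle mass must be positive")
  if (any(!is.finite(types$volume)) || any(types$volume <= 0)) stop("particle volume must be positive")

  ## [Particle interactions]
  irec <- strsplit(sections[["Particle interactions"]], "\\s+")
  if (length(irec) < 1L || irec[[1]][1] != "pair") {
    stop("particle-set format error: [Particle interactions] must start with header 'pair T1 T2 ...'")
  }
  temps <- as.numeric(irec[[1]][-1])
  if (!length(temps) || any(!is.finite(temps))) {
    stop("particle-set format error: interaction header declares no valid temperature")
  }
  inter <- list()
  for (f in irec[-1]) {
    pair <- strsplit(f[1], "_", fixed = TRUE)[[1]]
    if (length(pair) != 2L) stop("interaction row key must be 'A_B': ", f[1])
    vals <- as.numeric(f[-1])
    if (length(vals) != length(temps)) {
      stop("interaction row ", f[1], " has ", length(vals),
           " values for ", length(temps), " temperatures")
    }
    for (nm in pair) {
      if (!nm %in% types$name) {
        stop("interaction references undeclared particle: ", nm)
      }
    }
    if (any(!is.finite(vals))) stop("non-finite repulsion in row ", f[1])
    inter[[length(inter) + 1L]] <- data.frame(
      a = pair[1], b = pair[2], temperature = temps, repulsion = vals,
      stringsAsFactors = FALSE)
  }
  interactions <- if (length(inter)) do.call(rbind, inter) else
    data.frame(a = character(0), b = character(0),
               temperature = numeric(0), repulsion = numeric(0))

  ## [Amino acids]
  aa <- data.frame(one = character(0), three = character(0),
                   spices = character(0), backbone_index = integer(0),
                   pka = numeric(0), charged_state = character(0),
                   charged_spices = character(0), stringsAsFactors = FALSE)
  if (!is.null(sections[["Amino acids"]])) {
    arec <- strsplit(sections[["Amino acids"]], "\\s+")
    aa <- do.call(rbind, lapply(arec, function(f) {
      if (length(f) < 4L) stop("amino-acid record needs oneLetter threeLetter spices backboneIndex")
      pka <- if (length(f) >= 5L && f[5] != "-") as.numeric(f[5]) else NA_real_
      cs <- NA_character_; cv <- NA_character_
      if (length(f) >= 6L && f[6] != "-") {
        kv <- strsplit(f[6], "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("charged variant must be state=SPICES: ", f[6])
        cs <- kv[1]; cv <- kv[2]
      }
      data.frame(one = f[1], three = f[2], spices = f[3],
                 backbone_index = as.integer(f[4]), pka = pka,
                 charged_state = cs, charged_spices = cv,
                 stringsAsFactors = FALSE)
    }))
  }

  set <- structure(list(name = name, types = types,
                        interactions = interactions, amino_acids = aa),
                   class = "particle_set")
  validate_particle_set(set)
  set
}

validate_particle_set <- function(set) {
  stopifnot(inherits(set, "particle_set"))
  declared <- set$types$name
  bad <- setdiff(unique(c(set$interactions$a, set$interactions$b)), declared)
  if (length(bad)) stop("interaction references undeclared particle: ",
                        paste(bad, collapse = ", "))
  if (nrow(set$amino_acids)) {
    for (k in seq_len(nrow(set$amino_acids))) {
      for (sp in stats::na.omit(c(set$amino_acids$spices[k],
                                  set$amino_acids$charged_spices[k]))) {
        g <- parse_spices(sp)
        if (!all(g$particles %in% declared)) {
          stop("amino-acid fragment of ", set$amino_acids$three[k],
               " uses undeclared particle: ",
               paste(setdiff(g$particles, declared), collapse = ", "))
        }
        bi <- set$amino_acids$backbone_index[k]
        if (bi < 1L || bi > length(g$particles)) {
          stop("backbone index out of range for ", set$amino_acids$three[k])
        }
      }
    }
  }
  invisible(set)
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set '%s': %d type(s), %d interaction entr%s, %d amino acid(s)\n",
              x$name, nrow(x$types), nrow(x$interactions),
              if (nrow(x$interactions) == 1L) "y" else "ies",
              nrow(x$amino_acids)))
  invisible(x)
}

#' Serialize a particle set to its text format
#'
#' @param set a \code{particle_set}.
#' @param path optional file path; when given, the text is written there.
#' @return the text lines, invisibly when \code{path} is given.
#' @export
write_particle_set <- function(set, path = NULL) {
  stopifnot(inherits(set, "particle_set"))
  out <- c("[Particle description]")
  for (k in seq_len(nrow(set$types))) {
    t <- set$types[k, ]
    fields <- c(t$name, format(t$mass), format(t$charge), format(t$volume))
    if (!is.na(t$color)) fields <- c(fields, t$color)
    if (!is.na(t$radius)) fields <- c(fields, format(t$radius))
    out <- c(out, paste(fields, collapse = " "))
  }
  out <- c(out, "", "[Particle interactions]")
  temps <- sort(unique(set$interactions$temperature))
  out <- c(out, paste(c("pair", format(temps)), collapse = " "))
  key <- paste(set$interactions$a, set$interactions$b, sep = "_")
  for (k in unique(key)) {
    rows <- set$interactions[key == k, ]
    vals <- rows$repulsion[match(temps, rows$temperature)]
    out <- c(out, paste(c(k, format(vals)), collapse = " "))
  }
  if (nrow(set$amino_acids)) {
    out <- c(out, "", "[Amino acids]")
    for (k in seq_len(nrow(set$amino_acids))) {
      a <- set$amino_acids[k, ]
      out <- c(out, paste(
        a$one, a$three, a$spices, a$backbone_index,
        if (is.na(a$pka)) "-" else format(a$pka),
        if (is.na(a$charged_state)) "-" else paste0(a$charged_state, "=", a$charged_spices)))
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Duplicate a particle type within a set
#'
#' Creates a new type copying every field of the source type and replicates
#' all interactions involving the source for the new name, including the
#' self-interaction (target-target = source-source). The input set is not
#' modified.
#'
#' @param set a \code{particle_set}.
#' @param source name of the existing type.
#' @param target name of the new type (must not exist).
#' @return a new \code{particle_set}.
#' @export
duplicate_particle <- function(set, source, target) {
  stopifnot(inherits(set, "particle_set"))
  if (!source %in% set$types$name) stop("unknown source particle: ", source)
  if (target %in% set$types$name) stop("particle name collision: ", target)
  new_type <- set$types[set$types$name == source, , drop = FALSE]
  new_type$name <- target
  set$types <- rbind(set$types, new_type)
  it <- set$interactions
  self <- it[it$a == source & it$b == source, , drop = FALSE]
  cross <- it[xor(it$a == source, it$b == source), , drop = FALSE]
  add <- list()
  if (nrow(self)) {
    s2 <- self; s2$a <- target; s2$b <- target
    add[[length(add) + 1L]] <- s2
    # target-source pair inherits the source self-interaction
    s3 <- self; s3$a <- source; s3$b <- target
    add[[length(add) + 1L]] <- s3
  }
  if (nrow(cross)) {
    c2 <- cross
    c2$a <- ifelse(c2$a == source, target, c2$a)
    c2$b <- ifelse(c2$b == source, target, c2$b)
    # avoid re-adding source-target rows created above
    c2 <- c2[!(c2$a == target & c2$b == target), , drop = FALSE]
    add[[length(add) + 1L]] <- c2
  }
  if (length(add)) set$interactions <- rbind(it, do.call(rbind, add))
  rownames(set$types) <- NULL
  rownames(set$interactions) <- NULL
  set
}

#' Look up a pairwise repulsion parameter
#'
#' Symmetric lookup of the DPD repulsion \eqn{a_{ij}} for a particle pair.
#' When no entry exists at the requested temperature, the nearest declared
#' temperature for that pair is used (no interpolation).
#'
#' @param set a \code{particle_set}.
#' @param a,b particle type names.
#' @param temperature temperature in K.
#' @return the repulsion parameter (scalar).
#' @export
repulsion <- function(set, a, b, temperature = 298) {
  stopifnot(inherits(set, "particle_set"))
  for (nm in c(a, b)) {
    if (!nm %in% set$types$name) stop("unknown particle: ", nm)
  }
  it <- set$interactions
  hit <- (it$a == a & it$b == b) | (it$a == b & it$b == a)
  if (!any(hit)) stop("no interaction entry for pair ", a, "-", b)
  rows <- it[hit, , drop = FALSE]
  rows$repulsion[which.min(abs(rows$temperature - temperature))]
}

#' Full repulsion matrix for a set at a temperature
#'
#' @param set a \code{particle_set}.
#' @param temperature temperature in K.
#' @param types optional subset/order of type names.
#' @return symmetric numeric matrix with dimnames.
#' @export
repulsion_matrix <- function(set, temperature = 298, types = set$types$name) {
  n <- length(types)
  m <- matrix(NA_real_, n, n, dimnames = list(types, types))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- repulsion(set, types[i], types[j], temperature)
    }
  }
  m
}

#' Physical length of one DPD interaction radius
#'
#' In reduced units the interaction radius r_c is 1; its physical size
#' follows from requiring that \code{density} particles of the smallest
#' declared volume fill one r_c cube:
#' \eqn{r_c = (\rho V_{min})^{1/3}} Angstrom.
#'
#' @param set a \code{particle_set}.
#' @param density DPD number density (particles per r_c^3), default 3.
#' @return length of r_c in Angstrom.
#' @export
dpd_length_scale <- function(set, density = 3) {
  stopifnot(inherits(set, "particle_set"), density > 0, nrow(set$types) > 0)
  (density * min(set$types$volume))^(1 / 3)
}
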