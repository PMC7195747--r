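#' Write a configuration frame as extended XYZ
#'
#' Line 1: particle count; line 2: a comment carrying the box edges,
#' periodicity, step number and density; then one record per particle:
#' token x y z moleculeId.
#'
#' @param positions n x 3 matrix, or a \code{start_configuration} (then
#'   the remaining arguments are taken from it).
#' @param path output file path.
#' @param types particle type tokens.
#' @param molecule_id per-particle molecule ids.
#' @param box a \code{box_spec}.
#' @param step step number stored in the comment line.
#' @export
write_xyz <- function(positions, path, types = NULL, molecule_id = NULL,
                      box = NULL, step = 0) {
  if (inherits(positions, "start_configuration")) {
    cfg <- positions
    positions <- as.matrix(cfg$particles[, c("x", "y", "z")])
    types <- cfg$particles$type
    molecule_id <- cfg$particles$molecule_id
    box <- cfg$box
  }
  n <- nrow(positions)
  comment <- sprintf("box=\"%.10g %.10g %.10g\" periodic=\"%s\" density=%.10g step=%.10g",
                     box$edges[1], box$edges[2], box$edges[3],
                     paste(ifelse(box$periodic, "T", "F"), collapse = " "),
                     box$density, step)
  rec <- sprintf("%s %.10g %.10g %.10g %d", types, positions[, 1],
                 positions[, 2], positions[, 3], as.integer(molecule_id))
  writeLines(c(as.character(n), comment, rec), path)
  invisible(path)
}

#' Read an extended XYZ frame
#'
#' @param path file written by \code{\link{write_xyz}}.
#' @return list with \code{positions}, \code{types}, \code{molecule_id},
#'   \code{box} (a \code{box_spec}) and \code{step}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  comment <- lines[2]
  grab <- function(key) sub(paste0(".*", key, "=\"([^\"]*)\".*"), "\\1", comment)
  edges <- as.numeric(strsplit(grab("box"), " ")[[1]])
  periodic <- strsplit(grab("periodic"), " ")[[1]] == "T"
  density <- as.numeric(sub(".*density=([0-9.eE+-]+).*", "\\1", comment))
  step <- as.numeric(sub(".*step=([0-9.eE+-]+).*", "\\1", comment))
  f <- strsplit(lines[2 + seq_len(n)], " ")
  types <- vapply(f, `[`, "", 1L)
  pos <- t(vapply(f, function(x) as.numeric(x[2:4]), numeric(3)))
  mid <- as.integer(vapply(f, `[`, "", 5L))
  list(positions = pos, types = types, molecule_id = mid,
       box = box_spec(edges, density, periodic), step = step)
}

#' Convert an XYZ frame back into a start configuration
#'
#' Bonds cannot be recovered from XYZ; supply them if needed.
#'
#' @param frame list as returned by \code{\link{read_xyz}}.
#' @param bonds optional 2-column bond matrix.
#' @param molecule_type optional per-particle molecule type names.
#' @return a \code{start_configuration}.
#' @export
xyz_to_configuration <- function(frame, bonds = NULL, molecule_type = NULL) {
  particles <- data.frame(type = frame$types,
                          molecule_id = frame$molecule_id,
                          molecule_type = if (is.null(molecule_type))
                            frame$types else molecule_type,
                          x = frame$positions[, 1],
                          y = frame$positions[, 2],
                          z = frame$positions[, 3],
                          stringsAsFactors = FALSE)
  structure(list(particles = particles,
                 bonds = if (is.null(bonds)) matrix(integer(0), 0, 2) else bonds,
                 box = frame$box),
            class = "start_configuration")
}
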