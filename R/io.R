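#' Write a configuration in GRO format
#'
#' Fixed-width GROMACS coordinate file with velocities and the cubic box
#' line. Residue names follow the bead species (TP, TW, P4, AF).
#'
#' @param state A `cg_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(state, path) {
  n <- nrow(state$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("lnpsim CG configuration", con)
  writeLines(sprintf("%5d", n), con)
  resid <- state$mol %% 100000L
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                   resid, state$species, substr(state$bead_name, 1, 5),
                   seq_len(n) %% 100000L,
                   state$pos[, 1], state$pos[, 2], state$pos[, 3],
                   state$vel[, 1], state$vel[, 2], state$vel[, 3])
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", state$box, state$box, state$box), con)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Returns positions, velocities (when present), names and the box side.
#' For analysis-only use of external configurations.
#'
#' @param path GRO file path.
#' @return A list with `pos`, `vel`, `atom_name`, `res_name`, `box`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  pos <- cbind(as.numeric(substr(body, 21, 28)),
               as.numeric(substr(body, 29, 36)),
               as.numeric(substr(body, 37, 44)))
  has_vel <- nchar(body[1]) >= 68
  vel <- if (has_vel) {
    cbind(as.numeric(substr(body, 45, 52)),
          as.numeric(substr(body, 53, 60)),
          as.numeric(substr(body, 61, 68)))
  } else {
    matrix(0, n, 3)
  }
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1]
  list(pos = pos, vel = vel,
       res_name = trimws(substr(body, 6, 10)),
       atom_name = trimws(substr(body, 11, 15)),
       box = box)
}

#' Write a trajectory (or single state) in XYZ format
#'
#' Plain-text XYZ with one block per frame; the comment line carries the
#' nominal time (ps) and box side (nm). Coordinates are written in
#' Angstrom, the XYZ convention.
#'
#' @param x A `cg_trajectory` or `cg_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "cg_system")) {
    frames <- list(x$pos); times <- 0; boxes <- x$box
    names <- x$bead_name
  } else {
    frames <- x$frames; times <- x$frame_time; boxes <- x$frame_box
    names <- x$state$bead_name
  }
  for (f in seq_along(frames)) {
    writeLines(sprintf("%d", nrow(frames[[f]])), con)
    writeLines(sprintf("t= %.3f ps box= %.5f nm", times[f], boxes[f]), con)
    writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", names,
                       frames[[f]][, 1] * 10, frames[[f]][, 2] * 10,
                       frames[[f]][, 3] * 10), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file path.
#' @return A list with `frames` (positions in nm), `times` (ps), `boxes`
#'   (nm) and `names`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); boxes <- numeric(0); names <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    hdr <- lines[i + 1]
    tm <- as.numeric(sub(".*t= *([0-9.eE+-]+).*", "\\1", hdr))
    bx <- as.numeric(sub(".*box= *([0-9.eE+-]+).*", "\\1", hdr))
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3) / 10
    times <- c(times, tm)
    boxes <- c(boxes, bx)
    if (is.null(names)) names <- parts[, 1]
    i <- i + 2 + n
  }
  list(frames = frames, times = times, boxes = boxes, names = names)
}

#' Write a configuration in PDB format
#'
#' Uses bio3d; coordinates in Angstrom, box in CRYST1. Suitable as a
#' topology sidecar for visualisation. An optional `chain` vector (one
#' letter per bead) supports tracer export.
#'
#' @param state A `cg_system`.
#' @param path Output file.
#' @param chain Optional per-bead chain identifiers.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(state, path, chain = NULL) {
  n <- nrow(state$pos)
  if (is.null(chain)) chain <- rep("A", n)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(state$pos)) * 10,
    resno = state$mol %% 10000L,
    resid = state$species,
    eleno = seq_len(n),
    elety = state$bead_name,
    chain = chain
  )
  invisible(path)
}
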