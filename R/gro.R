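#' Read a (possibly multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO format (coordinates in nm) into
#' frames with coordinates in Angstrom. Residue names are taken as molecule
#' kinds and atom names as bead names. Multi-frame files (concatenated GRO
#' blocks) become trajectories. Frame times are read from a `t_us=` tag in
#' the title line when present, otherwise frames are numbered 0, 1, 2, ...
#' microseconds apart `dt_us`.
#'
#' @param path Path to a `.gro` file.
#' @param dt_us Fallback inter-frame spacing in microseconds when no time
#'   tags are present.
#' @return A [cg_frame()] for single-frame files, otherwise a
#'   [cg_trajectory()].
#' @export
read_gro <- function(path, dt_us = 1e-3) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) abort(sprintf("Malformed GRO atom count at line %d of %s.", i + 1L, path))
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    resid <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    atomname <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28)) * 10
    y <- as.numeric(substr(atom_lines, 29, 36)) * 10
    z <- as.numeric(substr(atom_lines, 37, 44)) * 10
    box <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1] * 10
    tm <- regmatches(title, regexpr("t_us=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t_us=\\s*", "", tm)) else k * dt_us
    frames[[length(frames) + 1L]] <- cg_frame(
      tibble::tibble(molecule_id = resid, kind = resname, bead = atomname,
                     x = x, y = y, z = z),
      box = box, time = time
    )
    i <- i + 3L + natoms
    k <- k + 1L
  }
  if (!length(frames)) abort(sprintf("No frames found in %s.", path))
  if (length(frames) == 1L) frames[[1L]] else cg_trajectory(frames)
}

#' Write frames to a GRO coordinate file
#'
#' Writes the fixed-column GRO format, converting coordinates from Angstrom
#' to nm. The frame time is stored as a `t_us=` tag in the title line so
#' that [read_gro()] round-trips it.
#'
#' @param x A [cg_frame()] or [cg_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path) {
  frames <- if (inherits(x, "cg_trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    b <- fr$beads
    writeLines(sprintf("micellemix frame t_us= %.9g", fr$time), con)
    writeLines(sprintf("%5d", nrow(b)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$molecule_id %% 100000L, b$kind, b$bead,
                       seq_len(nrow(b)) %% 100000L,
                       b$x / 10, b$y / 10, b$z / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box / 10, fr$box / 10,
                       fr$box / 10), con)
  }
  invisible(path)
}

#' Write frames to an extended XYZ file
#'
#' A simple whitespace dialect carrying molecule kind, molecule id and bead
#' name per atom line, with the box edge and time on the comment line;
#' coordinates in Angstrom. Round-trips through [read_xyz()].
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "cg_trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    b <- fr$beads
    writeLines(as.character(nrow(b)), con)
    writeLines(sprintf("box_A= %.9g t_us= %.9g", fr$box, fr$time), con)
    writeLines(sprintf("%s %d %s %.6f %.6f %.6f",
                       b$kind, b$molecule_id, b$bead, b$x, b$y, b$z), con)
  }
  invisible(path)
}

#' Read an extended XYZ file written by [write_xyz()]
#'
#' @param path Path to the file.
#' @return A [cg_frame()] or [cg_trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    hdr <- lines[i + 1L]
    box <- as.numeric(sub(".*box_A=\\s*([-0-9.eE+]+).*", "\\1", hdr))
    time <- as.numeric(sub(".*t_us=\\s*([-0-9.eE+]+).*", "\\1", hdr))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    frames[[length(frames) + 1L]] <- cg_frame(
      tibble::tibble(
        kind = vapply(rows, `[`, character(1), 1L),
        molecule_id = as.integer(vapply(rows, `[`, character(1), 2L)),
        bead = vapply(rows, `[`, character(1), 3L),
        x = as.numeric(vapply(rows, `[`, character(1), 4L)),
        y = as.numeric(vapply(rows, `[`, character(1), 5L)),
        z = as.numeric(vapply(rows, `[`, character(1), 6L))
      ),
      box = box, time = time
    )
    i <- i + 2L + n
  }
  if (!length(frames)) abort(sprintf("No frames found in %s.", path))
  if (length(frames) == 1L) frames[[1L]] else cg_trajectory(frames)
}
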