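## XYZ-per-frame trajectory format. Each frame is
##   <n_atoms>
##   time=<ps> box=<a> <b> <c>
##   <atom name> <x> <y> <z>        (n_atoms lines, Angstrom)
## The comment line carries the frame time and the orthorhombic box, which
## plain XYZ lacks; files without those fields still parse (time defaults to
## the frame counter, box to a large cell).

read_trajectory_xyz <- function(topology, path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0(path, ": empty file"))
  na_top <- nrow(topology)
  pos <- 1L
  nline <- length(lines)
  coords_list <- list()
  times <- numeric(0)
  boxes <- list()
  f <- 0L
  while (pos <= nline) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n))
      abort(sprintf("%s: expected an atom count at line %d, got '%s'",
                    path, pos, lines[pos]))
    f <- f + 1L
    if (n != na_top)
      abort(sprintf("%s: frame %d has %d atoms but the topology has %d",
                    path, f, n, na_top))
    comment <- lines[pos + 1L]
    t_m <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    b_m <- regmatches(comment,
                      regexec("box=([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
                              comment))[[1]]
    times[f] <- if (length(t_m) == 2) as.numeric(t_m[2]) else f - 1
    boxes[[f]] <- if (length(b_m) == 4) as.numeric(b_m[2:4]) else c(9999, 9999, 9999)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- tryCatch(
      scan(text = block, what = list(name = "", x = 0, y = 0, z = 0),
           quiet = TRUE),
      error = function(e)
        abort(sprintf("%s: malformed coordinate block in frame %d (%s)",
                      path, f, conditionMessage(e))))
    if (length(parts$x) != n)
      abort(sprintf("%s: malformed coordinate block in frame %d", path, f))
    coords_list[[f]] <- cbind(parts$x, parts$y, parts$z)
    pos <- pos + 2L + n
  }
  nf <- length(coords_list)
  coords <- array(NA_real_, dim = c(nf, na_top, 3))
  for (i in seq_len(nf)) coords[i, , ] <- coords_list[[i]]
  new_trajectory(topology, coords, times = times,
                 box = do.call(rbind, boxes))
}

write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- n_atoms(traj)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(
      as.character(na),
      sprintf("time=%.6g box=%.6g %.6g %.6g", traj$times[f],
              traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]),
      sprintf("%-4s %12.6f %12.6f %12.6f", traj$topology$name,
              xyz[, 1], xyz[, 2], xyz[, 3])
    ), con)
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Reads an ordered set of frames against a known topology, from either a
#' multi-model PDB file or an XYZ-per-frame file whose comment line carries
#' `time=<ps> box=<a> <b> <c>`. The frame spacing `dt` is inferred from the
#' first two frames and checked against the rest; a single-frame file has
#' `dt = NA`.
#'
#' @param topology A [topology()] tibble the frames must match.
#' @param path Path to the trajectory file.
#' @param dialect `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @param dt Frame spacing in ps for PDB files, which carry no time stamps.
#' @return A [new_trajectory()] object.
#' @export
read_trajectory <- function(topology, path, dialect = c("auto", "xyz", "pdb"),
                            dt = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  traj <- switch(dialect,
                 xyz = read_trajectory_xyz(topology, path),
                 pdb = read_trajectory_pdb(topology, path, dt))
  if (n_frames(traj) == 1)
    warn("single-frame trajectory: dt is undefined")
  traj
}

#' Write a trajectory
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @param dialect `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("auto", "xyz", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  switch(dialect,
         xyz = write_trajectory_xyz(traj, path),
         pdb = write_trajectory_pdb(traj, path))
}
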