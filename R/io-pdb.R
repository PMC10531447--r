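## Fixed-column PDB reading and writing.
##
## The subset handled is what channel-trajectory work touches: ATOM/HETATM
## records, MODEL/ENDMDL for multi-model files and CRYST1 for the
## orthorhombic box. Residue names occupy columns 18-21 so that 4-character
## MD names (TIP3, POPC) survive a round-trip; 3-character PDB names parse
## identically. Only orthorhombic cells are supported: a CRYST1 record with
## angles other than 90 degrees is refused rather than silently mishandled.

parse_pdb_lines <- function(lines, path = "<connection>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  is_endmdl <- grepl("^ENDMDL", lines)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- NULL
  if (length(cryst) > 0) {
    l <- cryst[1]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
    ang <- suppressWarnings(as.numeric(c(substr(l, 34, 40), substr(l, 41, 47),
                                         substr(l, 48, 54))))
    if (any(!is.na(ang) & abs(ang - 90) > 1e-3))
      abort(paste0(path, ": triclinic cells (CRYST1 angles != 90) are not supported"))
  }
  if (!any(is_atom))
    abort(paste0(path, ": no ATOM/HETATM records found"))

  ## frame id per atom line: number of MODEL records seen before it
  model_id <- cumsum(is_model)
  frame_of_atom <- model_id[is_atom]
  if (all(frame_of_atom == 0)) frame_of_atom <- rep(1L, sum(is_atom))
  frame_of_atom[frame_of_atom == 0] <- 1L

  al <- lines[is_atom]
  lineno <- which(is_atom)
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad) > 0)
    abort(sprintf("%s: malformed ATOM/HETATM record at line %d: %s",
                  path, lineno[bad[1]], al[bad[1]]))
  tibble::tibble(
    frame = frame_of_atom,
    name = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 21)),
    resid = resid,
    chain = trimws(substr(al, 22, 22)),
    element = trimws(substr(al, 77, 78)),
    x = x, y = y, z = z
  ) -> at
  at$chain[at$chain == ""] <- "A"
  at$element[at$element == ""] <- NA_character_
  list(atoms = at, box = box)
}

#' Read a structure file (PDB)
#'
#' Parses ATOM/HETATM records from a PDB file. Multi-model files expose
#' model 1; use [read_trajectory()] to load all models as frames.
#'
#' @param path Path to a PDB file.
#' @return A list with elements `topology` (a [topology()] tibble), `coords`
#'   (an `n x 3` matrix, Angstrom) and `box` (length-3 numeric from CRYST1,
#'   or `NULL` when absent).
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0(path, ": empty file"))
  p <- parse_pdb_lines(lines, path)
  at <- dplyr::filter(p$atoms, .data$frame == min(.data$frame))
  top <- topology(name = at$name, resname = at$resname, resid = at$resid,
                  chain = at$chain, element = at$element)
  list(topology = top, coords = as.matrix(at[, c("x", "y", "z")]), box = p$box)
}

format_pdb_atoms <- function(top, coords) {
  name4 <- ifelse(nchar(top$name) < 4, sprintf(" %-3s", top$name),
                  sprintf("%-4s", substr(top$name, 1, 4)))
  ele <- ifelse(is.na(top$element), "", top$element)
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ((top$index - 1L) %% 99999L) + 1L, name4, substr(top$resname, 1, 4),
          substr(top$chain, 1, 1), top$resid %% 10000L,
          coords[, 1], coords[, 2], coords[, 3], 1, 0, ele)
}

#' Write a structure file (PDB)
#'
#' @param topology A [topology()] tibble.
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param path Output path.
#' @param box Optional length-3 orthorhombic box, written as CRYST1.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path, box = NULL) {
  stopifnot(nrow(coords) == nrow(topology), ncol(coords) == 3)
  lines <- character(0)
  if (!is.null(box))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90)
  lines <- c(lines, format_pdb_atoms(topology, coords), "END")
  writeLines(lines, path)
  invisible(path)
}

read_trajectory_pdb <- function(topology, path, dt) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0(path, ": empty file"))
  p <- parse_pdb_lines(lines, path)
  frames <- sort(unique(p$atoms$frame))
  nf <- length(frames)
  na <- nrow(topology)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (i in seq_len(nf)) {
    at <- p$atoms[p$atoms$frame == frames[i], , drop = FALSE]
    if (nrow(at) != na)
      abort(sprintf("%s: frame %d has %d atoms but the topology has %d",
                    path, i, nrow(at), na))
    coords[i, , ] <- as.matrix(at[, c("x", "y", "z")])
  }
  dt <- dt %||% 1
  box <- p$box %||% c(9999, 9999, 9999)
  new_trajectory(topology, coords, times = (seq_len(nf) - 1) * dt, box = box)
}

write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90),
             con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(format_pdb_atoms(traj$topology, frame_coords(traj, f)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
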