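#' Build an atom topology table
#'
#' A topology is a tibble with one row per atom and columns `index` (1-based
#' integer, unique), `name` (atom name, e.g. `"CA"` or `"OH2"`), `resname`
#' (residue name, e.g. `"SER"`, `"SEP"` for phosphoserine, `"TIP3"`), `resid`
#' (residue id, non-negative integer, 1-based as in PDB files), `chain`
#' (chain identifier, e.g. `"A"`–`"D"`) and `element`.
#'
#' @param name Character vector of atom names.
#' @param resname Character vector of residue names (recycled).
#' @param resid Integer vector of residue ids (recycled).
#' @param chain Character vector of chain ids (recycled).
#' @param element Character vector of element symbols (recycled); guessed
#'   from the first letter of `name` when `NA`.
#' @return A tibble of class `channel_topology`.
#' @examples
#' topology(name = c("CA", "CB", "OH2"),
#'          resname = c("ALA", "ALA", "TIP3"),
#'          resid = c(1, 1, 2), chain = "A")
#' @export
topology <- function(name, resname, resid, chain = "A", element = NA_character_) {
  n <- length(name)
  stopifnot(n >= 1)
  top <- tibble::tibble(
    index = seq_len(n),
    name = as.character(name),
    resname = rep_len(as.character(resname), n),
    resid = as.integer(rep_len(resid, n)),
    chain = rep_len(as.character(chain), n),
    element = rep_len(as.character(element), n)
  )
  top$element <- ifelse(is.na(top$element),
                        toupper(substr(gsub("[^A-Za-z].*$", "", top$name), 1, 1)),
                        top$element)
  validate_topology(top)
}

validate_topology <- function(top) {
  if (!all(c("index", "name", "resname", "resid", "chain") %in% names(top)))
    abort("topology must have columns index, name, resname, resid, chain")
  if (anyDuplicated(top$index))
    abort("atom indices must be unique within a topology")
  if (any(top$resid < 0, na.rm = TRUE))
    abort("residue ids must be non-negative")
  class(top) <- unique(c("channel_topology", class(tibble::as_tibble(top))))
  top
}

#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.channel_topology <- function(x) nrow(x)

#' Atom indices of water molecule positions
#'
#' Waters are recognised by residue name (`TIP3`, `HOH`, `SOL`, `WAT`); the
#' oxygen atom is used as the molecule's position. Atoms whose element is
#' not oxygen are excluded so three-site water models contribute one
#' position each.
#'
#' @param top A topology.
#' @return An [atom_selection()] of water oxygen atoms.
#' @export
water_selection <- function(top) {
  keep <- top$resname %in% .water_resnames &
    (is.na(top$element) | top$element == "O" |
       grepl("^O", top$name))
  atom_selection(which(keep), expression = "water oxygens")
}

#' Construct an atom selection from indices
#'
#' @param indices Integer vector of 1-based atom row indices.
#' @param expression Provenance string (the selection expression, if any).
#' @return An integer vector of class `atom_selection`.
#' @export
atom_selection <- function(indices, expression = NA_character_) {
  idx <- as.integer(indices)
  structure(idx, expression = expression, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", length(x), " atoms",
      if (!is.na(attr(x, "expression"))) paste0("  [", attr(x, "expression"), "]"),
      "\n", sep = "")
  print(unclass(x))
  invisible(x)
}
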