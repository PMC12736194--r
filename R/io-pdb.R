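#' Read a single-molecule PDB file as a pose
#'
#' All `ATOM` and `HETATM` records become atoms, in file order.  The element
#' is taken from the element columns (77-78) when present; when blank it is
#' inferred from the atom-name field by stripping digits and, for names that
#' start with a letter in column 14 (e.g. `" CA "`), taking the first letter
#' (so `" CA "` is carbon, not calcium, following PDB alignment rules).
#' Parsing is delegated to \pkg{bio3d}.  The pose id is the filename stem
#' and radii are left unassigned.
#'
#' @param path Path to a PDB file with at least one coordinate record.
#' @param form Pose form, as in [molecule_pose()].
#' @return A `molecule_pose`.
#' @export
read_pdb <- function(path, form = "monomer") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop("no ATOM/HETATM coordinate records in ", path)
  el <- at$elesy
  blank <- is.na(el) | !nzchar(trimws(el))
  if (any(blank)) el[blank] <- infer_element_from_name(at$elety[blank])
  el <- normalize_element_case(trimws(el))
  molecule_pose(id = sub("\\.[^.]*$", "", basename(path)),
                element = el,
                xyz = cbind(at$x, at$y, at$z),
                form = form)
}

# Atom-name heuristics for PDB files lacking element columns: drop digits
# and primes, then keep a leading two-letter symbol only if it is a common
# heteroelement; otherwise the first letter (" CA " alpha-carbon -> C).
infer_element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1L, 2L)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU", "SI")
  ifelse(nchar(nm) >= 2L & two %in% known2, two, substr(nm, 1L, 1L))
}

normalize_element_case <- function(el) {
  paste0(toupper(substr(el, 1L, 1L)),
         tolower(substr(el, 2L, nchar(el))))
}
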