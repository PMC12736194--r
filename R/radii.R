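#' Van der Waals radius table
#'
#' Element-to-radius lookup used by [assign_radii()].  The default is the
#' Bondi (1964) set for the main-group elements that dominate drug-like
#' molecules, extended with Fe (2.05 Angstrom, Batsanov) for ferrocene-type
#' scaffolds.  Elements missing from the table fall back to `default_radius`
#' with a warning, so volume estimation never silently drops atoms.
#'
#' @param radii Named numeric vector, element symbol -> radius (Angstrom).
#'   Lookup is case-insensitive.  All radii must lie in (0.5, 3.5).
#' @param default_radius Fallback radius (Angstrom) for unlisted elements.
#' @param name Short label recorded in serialized matrix headers.
#' @return An object of class `radius_table`.
#' @examples
#' tab <- radius_table()
#' tab[["C"]]   # 1.70
#' @export
radius_table <- function(radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                                   F = 1.47, P = 1.80, S = 1.80, Cl = 1.75,
                                   Br = 1.85, I = 1.98, Fe = 2.05),
                         default_radius = 2.0,
                         name = "bondi") {
  radii <- unlist(radii)
  if (is.null(names(radii)) || any(!nzchar(names(radii))))
    stop("all radii must be named by element symbol")
  if (any(!is.finite(radii)) || any(radii <= 0.5) || any(radii >= 3.5))
    stop("vdW radii must lie in (0.5, 3.5) Angstrom")
  if (!is.finite(default_radius) || default_radius <= 0.5 || default_radius >= 3.5)
    stop("default_radius must lie in (0.5, 3.5) Angstrom")
  structure(list(radii = radii, lower = tolower(names(radii)),
                 default_radius = default_radius, name = name),
            class = "radius_table")
}

#' @export
print.radius_table <- function(x, ...) {
  cat(sprintf("<radius_table '%s'> %d elements, default %.2f A\n",
              x$name, length(x$radii), x$default_radius))
  print(x$radii)
  invisible(x)
}

#' @export
`[[.radius_table` <- function(x, i) {
  lookup_radius(x, i)
}

lookup_radius <- function(table, element) {
  idx <- match(tolower(element), table$lower)
  out <- unname(table$radii[idx])
  out[is.na(idx)] <- table$default_radius
  out
}

#' Assign van der Waals radii to a pose
#'
#' Every atom receives `table[[element]]`, or the table's fallback radius for
#' elements the table does not list (each fallback is reported via a
#' warning).  Returns a new pose; the input is not modified.  Idempotent.
#'
#' @param pose A [molecule_pose()].
#' @param table A [radius_table()].
#' @return The pose with all radii assigned.
#' @export
assign_radii <- function(pose, table = radius_table()) {
  stopifnot(inherits(pose, "molecule_pose"), inherits(table, "radius_table"))
  miss <- is.na(match(tolower(pose$element), table$lower))
  if (any(miss)) {
    warning(sprintf(
      "pose '%s': default radius %.2f A used for unlisted element(s): %s",
      pose$id, table$default_radius,
      paste(unique(pose$element[miss]), collapse = ", ")))
  }
  pose$radius <- lookup_radius(table, pose$element)
  pose$radius_source <- table$name
  pose
}
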