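#' Construct a rigid molecular pose
#'
#' A `molecule_pose` is the package's central geometric object: a rigid
#' molecule (or molecular aggregate) whose Cartesian coordinates live in a
#' common receptor-fixed frame, in Angstrom.  All volume, overlap and shape
#' computations operate on the union of atom-centered van der Waals spheres,
#' so a pose needs only elements, coordinates and (once assigned) radii;
#' bonds and formal charges are carried along solely for pharmacophore
#' feature typing and SDF round-tripping.
#'
#' Radii are *not* read from files.  A freshly read pose has `NA` radii (an
#' explicit "unassigned" sentinel); call [assign_radii()] before any
#' volumetric operation.
#'
#' @param id Non-empty pose label, e.g. `"7b"`, `"7b.2"`, `"don"`.
#' @param element Character vector of element symbols, one per atom.
#' @param xyz Numeric n x 3 matrix of coordinates (Angstrom), finite.
#' @param radius Numeric vector of vdW radii (Angstrom) or `NA` (unassigned).
#' @param form One of `"monomer"`, `"dimer"`, `"reference"`.
#' @param binding_energy Optional docking binding energy Eb = -deltaG in
#'   kcal/mol (larger means stronger predicted binding), or `NULL`.
#' @param bonds Integer m x 2 matrix of 1-based atom index pairs (may have
#'   zero rows).
#' @param charge Integer vector of formal charges, one per atom.
#' @return An object of class `molecule_pose`.
#' @examples
#' p <- molecule_pose("don", "C", matrix(0, 1, 3))
#' p <- assign_radii(p)
#' @export
molecule_pose <- function(id, element, xyz,
                          radius = NA_real_,
                          form = c("monomer", "dimer", "reference"),
                          binding_energy = NULL,
                          bonds = NULL,
                          charge = NULL) {
  form <- match.arg(form)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("'xyz' must have 3 columns")
  n <- nrow(xyz)
  if (n < 1L) stop("a pose must contain at least one atom")
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  element <- as.character(element)
  if (length(element) != n) stop("'element' length must match atom count")
  radius <- rep_len(as.numeric(radius), n)
  if (any(!is.na(radius) & radius <= 0)) stop("assigned radii must be > 0")
  if (!is.null(binding_energy)) {
    binding_energy <- as.numeric(binding_energy)
    if (length(binding_energy) != 1L || !is.finite(binding_energy))
      stop("'binding_energy' must be a single finite number")
  }
  if (is.null(bonds)) bonds <- matrix(integer(0), 0L, 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n)))
    stop("bond indices out of range")
  if (is.null(charge)) charge <- integer(n)
  charge <- rep_len(as.integer(charge), n)
  dimnames(xyz) <- NULL
  structure(
    list(id = id, form = form, element = element, xyz = xyz,
         radius = radius, binding_energy = binding_energy,
         bonds = bonds, charge = charge),
    class = "molecule_pose"
  )
}

#' @export
print.molecule_pose <- function(x, ...) {
  eb <- if (is.null(x$binding_energy)) "none"
        else sprintf("%.2f kcal/mol", x$binding_energy)
  cat(sprintf("<molecule_pose> id=%s form=%s atoms=%d radii=%s Eb=%s\n",
              x$id, x$form, nrow(x$xyz),
              if (anyNA(x$radius)) "unassigned" else "assigned", eb))
  invisible(x)
}

n_atoms <- function(pose) nrow(pose$xyz)

has_radii <- function(pose) !anyNA(pose$radius)

stopifnot_radii <- function(pose) {
  if (!has_radii(pose))
    stop(sprintf("pose '%s' has unassigned radii; call assign_radii() first",
                 pose$id), call. = FALSE)
}

pose_centroid <- function(pose) colMeans(pose$xyz)

#' Apply a rigid transform to a pose
#'
#' Coordinates are mapped as `x -> R x + t`.  Radii, identity and annotations
#' are untouched: a rigid motion of a rigid body.
#'
#' @param pose A [molecule_pose()].
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Numeric 3-vector (Angstrom).
#' @return The transformed pose.
#' @export
transform_pose <- function(pose, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  check_rotation(rotation)
  pose$xyz <- pose$xyz %*% t(rotation) +
    matrix(translation, nrow(pose$xyz), 3L, byrow = TRUE)
  pose
}

check_rotation <- function(R, tol = 1e-6) {
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation matrix is not orthogonal")
  if (abs(det(R) - 1) > tol)
    stop("rotation matrix must be proper (det = +1); reflections are not rigid motions of a chiral molecule")
  invisible(R)
}

# Unique-id check for a pose set; returns named list keyed by id.
check_pose_set <- function(poses) {
  if (!length(poses)) stop("empty pose set")
  ids <- vapply(poses, function(p) p$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate pose ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(poses) <- ids
  poses
}
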