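# Gaussian description of molecular shape (Grant-Pickup style): each atom is
# a spherical Gaussian whose integral equals its hard-sphere volume, with
# fixed amplitude p = 2.7; only first-order (pairwise) overlaps are summed.
# The Gaussians exist to make rigid alignment smooth; all *reported* Tanimoto
# coefficients use hard-sphere volumes from the volumetrics estimators.
GAUSS_AMPLITUDE <- 2.7

gauss_alpha <- function(radius) {
  pi * (3 * GAUSS_AMPLITUDE / (4 * pi * radius^3))^(2 / 3)
}

gauss_overlap_xyz <- function(xyz_a, r_a, xyz_b, r_b) {
  ai <- gauss_alpha(r_a)
  aj <- gauss_alpha(r_b)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * tcrossprod(xyz_a, xyz_b)
  s <- outer(ai, aj, "+")
  sum(GAUSS_AMPLITUDE^2 * exp(-(outer(ai, aj) / s) * d2) * (pi / s)^1.5)
}

#' Gaussian shape overlap of two poses
#'
#' Sum over all atom pairs of the closed-form integral of two spherical
#' Gaussians, each parameterized so its integral equals the atom's
#' hard-sphere volume.  Smooth in relative placement, symmetric, and maximal
#' when a pose is compared with itself at the identity transform; it decays
#' to zero as the poses separate.  Used as the differentiable objective for
#' [align_to_reference()].
#'
#' @param a,b Poses with radii assigned.
#' @return Overlap measure in Angstrom^3.
#' @export
gaussian_overlap <- function(a, b) {
  stopifnot_radii(a); stopifnot_radii(b)
  gauss_overlap_xyz(a$xyz, a$radius, b$xyz, b$radius)
}

# Rodrigues rotation from a rotation vector (axis * angle).
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Principal axes (columns, decreasing spread), forced proper (det = +1).
principal_axes <- function(xyz_centered) {
  v <- eigen(crossprod(xyz_centered) / nrow(xyz_centered),
             symmetric = TRUE)$vectors
  if (det(v) < 0) v[, 3L] <- -v[, 3L]
  v
}

#' Rigidly align a probe pose onto a reference
#'
#' Maximizes the Gaussian shape overlap over proper rigid motions
#' (rotation + translation; reflections are never searched because molecules
#' are chiral objects).  Both poses are centered at their centroids; four
#' starting rotations are built from the principal-axes sign combinations
#' with determinant +1; each start is refined by quasi-Newton ascent (BFGS)
#' on a (rotation-vector, translation) parameterization, stopping when the
#' score improves by less than `tol` or after `max_iter` iterations.  The
#' best refined solution is returned, and its score is never below the score
#' at any start.
#'
#' A degenerate probe (all atoms coincident or collinear, so the principal
#' frame is undefined) falls back to translation-only alignment with a
#' warning.
#'
#' @param ref,probe Poses with radii assigned.
#' @param max_iter Maximum refinement iterations per start.
#' @param tol Absolute score-improvement convergence tolerance (Angstrom^3).
#' @return A list with `transform` (list with 3x3 `rotation` and 3-vector
#'   `translation`, mapping original probe coordinates into the reference
#'   frame), `pose` (the aligned probe), `score` (maximized Gaussian
#'   overlap), and `start_scores`/`refined_scores` for each start.
#' @export
align_to_reference <- function(ref, probe, max_iter = 200, tol = 1e-6) {
  stopifnot_radii(ref); stopifnot_radii(probe)
  cr <- pose_centroid(ref)
  cp <- pose_centroid(probe)
  a_c <- sweep(ref$xyz, 2L, cr)
  b_c <- sweep(probe$xyz, 2L, cp)
  ev_probe <- eigen(crossprod(b_c) / nrow(b_c), symmetric = TRUE)$values
  if (nrow(b_c) < 3L || ev_probe[2L] < 1e-8) {
    warning(sprintf(
      "probe '%s' is degenerate (coincident or collinear atoms); translation-only alignment",
      probe$id))
    tr <- list(rotation = diag(3), translation = cr - cp)
    return(list(transform = tr,
                pose = transform_pose(probe, tr$rotation, tr$translation),
                score = gauss_overlap_xyz(a_c, ref$radius, b_c, probe$radius),
                start_scores = NA_real_, refined_scores = NA_real_))
  }
  vr <- principal_axes(a_c)
  vp <- principal_axes(b_c)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  starts <- lapply(signs, function(s) vr %*% diag(s) %*% t(vp))
  objective <- function(par, r0) {
    r <- rotvec_to_matrix(par[1:3]) %*% r0
    moved <- b_c %*% t(r) +
      matrix(par[4:6], nrow(b_c), 3L, byrow = TRUE)
    gauss_overlap_xyz(a_c, ref$radius, moved, probe$radius)
  }
  start_scores <- refined_scores <- numeric(length(starts))
  best <- NULL
  for (k in seq_along(starts)) {
    r0 <- starts[[k]]
    start_scores[k] <- objective(numeric(6), r0)
    fit <- stats::optim(numeric(6), function(p) -objective(p, r0),
                        method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-10,
                                       abstol = tol))
    refined_scores[k] <- -fit$value
    if (is.null(best) || refined_scores[k] > best$score) {
      best <- list(score = refined_scores[k],
                   rotation = rotvec_to_matrix(fit$par[1:3]) %*% r0,
                   shift = fit$par[4:6])
    }
  }
  # full transform in the original frame: x -> R (x - cp) + shift + cr
  rot <- best$rotation
  trans <- as.numeric(cr + best$shift - rot %*% cp)
  tr <- list(rotation = rot, translation = trans)
  list(transform = tr,
       pose = transform_pose(probe, rot, trans),
       score = best$score,
       start_scores = start_scores, refined_scores = refined_scores)
}

#' Shape Tanimoto coefficient
#'
#' `Tc = V_int / (V_ref + V_probe - V_int)` on hard-sphere volumes evaluated
#' on a shared grid, after Gaussian-overlap alignment when `align = TRUE`.
#' Identical poses score 1; poses sharing no volume score 0.  With
#' `align = FALSE` the coefficient is symmetric and evaluated in the common
#' receptor frame as-is.
#'
#' @param ref,probe Poses with radii assigned.
#' @param align Align `probe` onto `ref` first?
#' @param settings A [volume_settings()] for the hard-sphere volumes.
#' @return Tc in \[0, 1\].
#' @export
shape_tanimoto <- function(ref, probe, align = TRUE,
                           settings = volume_settings()) {
  stopifnot_radii(ref); stopifnot_radii(probe)
  if (align) probe <- align_to_reference(ref, probe)$pose
  if (spheres_disjoint(ref, probe)) return(0)
  v <- pair_volumes(ref, probe, settings)
  tc <- v[["vint"]] / (v[["va"]] + v[["vb"]] - v[["vint"]])
  min(1, max(0, tc))
}

# ---- pharmacophore ("color") features ----

FEATURE_TYPES <- c("donor", "acceptor", "cation", "anion", "ring",
                   "hydrophobe")

#' Construct pharmacophore feature points
#'
#' @param type Character vector of feature types (subset of donor, acceptor,
#'   cation, anion, ring, hydrophobe).
#' @param position n x 3 matrix of feature centers (Angstrom).
#' @param sigma Gaussian feature width(s), Angstrom, > 0.
#' @return A data.frame with columns `type`, `x`, `y`, `z`, `sigma`.
#' @export
feature_points <- function(type, position, sigma = 1.0) {
  position <- matrix(as.numeric(position), ncol = 3L)
  type <- as.character(type)
  if (length(type) != nrow(position)) stop("one type per feature position")
  bad <- setdiff(unique(type), FEATURE_TYPES)
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  sigma <- rep_len(as.numeric(sigma), length(type))
  if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be > 0")
  data.frame(type = type, x = position[, 1L], y = position[, 2L],
             z = position[, 3L], sigma = sigma, stringsAsFactors = FALSE)
}

#' Derive pharmacophore features from a pose
#'
#' Minimal rule-based typing (a declared simplification of vendor color
#' force fields): donor = N/O with at least one H within 1.2 Angstrom;
#' acceptor = any N/O; cation/anion = atoms with positive/negative formal
#' charge (from the SDF charge block); ring = centroid of each 5- or 6-atom
#' cycle detected in the bond block; hydrophobe = C with no N/O within
#' 2.0 Angstrom.  All features use a fixed Gaussian width of 1.0 Angstrom.
#'
#' @param pose A [molecule_pose()].
#' @return Feature data.frame as in [feature_points()]; may have zero rows.
#' @export
derive_features <- function(pose) {
  el <- toupper(pose$element)
  xyz <- pose$xyz
  d <- as.matrix(stats::dist(xyz))
  types <- character(0)
  pos <- matrix(numeric(0), 0L, 3L)
  add <- function(ty, p) {
    types <<- c(types, rep(ty, nrow(p)))
    pos <<- rbind(pos, p)
  }
  is_no <- el %in% c("N", "O")
  is_h <- el == "H"
  if (any(is_no)) {
    add("acceptor", xyz[is_no, , drop = FALSE])
    if (any(is_h)) {
      don <- which(is_no)[vapply(which(is_no), function(i)
        any(d[i, is_h] <= 1.2), logical(1))]
      if (length(don)) add("donor", xyz[don, , drop = FALSE])
    }
  }
  if (any(pose$charge > 0L))
    add("cation", xyz[pose$charge > 0L, , drop = FALSE])
  if (any(pose$charge < 0L))
    add("anion", xyz[pose$charge < 0L, , drop = FALSE])
  is_c <- el == "C"
  if (any(is_c)) {
    phobe <- which(is_c)[vapply(which(is_c), function(i)
      !any(d[i, is_no] <= 2.0), logical(1))]
    if (length(phobe)) add("hydrophobe", xyz[phobe, , drop = FALSE])
  }
  for (ring in find_rings(pose$bonds, n_atoms(pose), sizes = 5:6))
    add("ring", matrix(colMeans(xyz[ring, , drop = FALSE]), 1L, 3L))
  feature_points(types, pos, sigma = 1.0)
}

# Fundamental cycles of the bond graph via a BFS spanning forest; returns
# the unique cycles whose length is in `sizes`.  Adequate for the small
# simple rings pharmacophore typing needs.
find_rings <- function(bonds, n, sizes = 5:6) {
  if (!nrow(bonds)) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  extra <- list()
  for (root in seq_len(n)) {
    if (!is.na(depth[root]) || is.null(adj[[root]])) next
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.na(depth[v])) {
          depth[v] <- depth[u] + 1L
          parent[v] <- u
          queue <- c(queue, v)
        } else if (v != parent[u] %||% -1L && u < v) {
          extra[[length(extra) + 1L]] <- c(u, v)
        }
      }
    }
  }
  path_to_root <- function(u) {
    p <- u
    while (!is.na(parent[u])) { u <- parent[u]; p <- c(p, u) }
    p
  }
  rings <- list()
  seen <- character(0)
  for (e in extra) {
    pu <- path_to_root(e[1L])
    pv <- path_to_root(e[2L])
    common <- intersect(pu, pv)
    if (!length(common)) next
    lca <- common[[1L]]
    cyc <- c(pu[seq_len(match(lca, pu))], rev(pv[seq_len(match(lca, pv) - 1L)]))
    if (length(cyc) %in% sizes) {
      key <- paste(sort(cyc), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- cyc
      }
    }
  }
  rings
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# Summed same-type Gaussian feature overlap between two feature sets.
feature_overlap <- function(fa, fb) {
  if (!nrow(fa) || !nrow(fb)) return(0)
  total <- 0
  for (ty in intersect(unique(fa$type), unique(fb$type))) {
    a <- fa[fa$type == ty, , drop = FALSE]
    b <- fb[fb$type == ty, , drop = FALSE]
    pa <- as.matrix(a[, c("x", "y", "z")])
    pb <- as.matrix(b[, c("x", "y", "z")])
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    s2 <- outer(a$sigma^2, b$sigma^2, "+")
    pref <- (2 * pi * outer(a$sigma^2, b$sigma^2) / s2)^1.5
    total <- total + sum(pref * exp(-d2 / (2 * s2)))
  }
  total
}

transform_features <- function(features, transform) {
  if (!nrow(features)) return(features)
  p <- as.matrix(features[, c("x", "y", "z")]) %*% t(transform$rotation)
  p <- sweep(p, 2L, transform$translation, "+")
  features$x <- p[, 1L]; features$y <- p[, 2L]; features$z <- p[, 3L]
  features
}

#' Color (pharmacophore) Tanimoto coefficient
#'
#' Tanimoto ratio of summed same-type Gaussian feature overlaps:
#' `O_ab / (O_aa + O_bb - O_ab)`.  Compounds sharing no feature type score
#' exactly 0 — the mechanism behind chemically unrelated compounds showing
#' extremely low color scores despite passable shape overlap.  When
#' `transform` is supplied (typically from [align_to_reference()]), it is
#' applied to the probe features first, so color is scored in the
#' shape-aligned frame.
#'
#' @param ref,probe Poses (used for feature derivation defaults).
#' @param ref_features,probe_features Feature data.frames; default
#'   [derive_features()] of the poses.
#' @param transform Optional rigid transform applied to `probe_features`.
#' @return Tc color in \[0, 1\].
#' @export
color_tanimoto <- function(ref, probe,
                           ref_features = derive_features(ref),
                           probe_features = derive_features(probe),
                           transform = NULL) {
  if (!nrow(ref_features) || !nrow(probe_features)) {
    warning("empty feature set; color Tanimoto is 0")
    return(0)
  }
  if (!is.null(transform))
    probe_features <- transform_features(probe_features, transform)
  o_ab <- feature_overlap(ref_features, probe_features)
  if (o_ab <= 0) return(0)
  o_aa <- feature_overlap(ref_features, ref_features)
  o_bb <- feature_overlap(probe_features, probe_features)
  min(1, max(0, o_ab / (o_aa + o_bb - o_ab)))
}

#' Rank probe compounds against a lead by combo Tanimoto
#'
#' For each probe: align onto the reference by Gaussian shape overlap, score
#' the shape Tanimoto on hard-sphere volumes, score the color Tanimoto in
#' the aligned frame, and sum them (`tc_combo = w_shape * tc_shape +
#' w_color * tc_color`; unit weights by default, the usual vendor
#' convention).  Rows are ordered by descending combo score, ties broken
#' lexicographically by id; the ranking is deterministic and independent of
#' input order.
#'
#' @param ref The lead pose (radii assigned).
#' @param probes List of probe poses with unique ids.
#' @param settings A [volume_settings()].
#' @param ref_features Optional feature set for the lead.
#' @param weights Length-2 numeric, shape and color weights.
#' @return Data frame `id`, `tc_shape`, `tc_color`, `tc_combo`, ordered by
#'   rank, with the per-probe alignment transforms in attribute
#'   `"transforms"`.
#' @export
rank_by_combo <- function(ref, probes, settings = volume_settings(),
                          ref_features = derive_features(ref),
                          weights = c(shape = 1, color = 1)) {
  probes <- check_pose_set(probes)
  stopifnot(length(weights) == 2L, all(weights >= 0))
  rows <- lapply(probes, function(p) {
    al <- align_to_reference(ref, p)
    tcs <- shape_tanimoto(ref, al$pose, align = FALSE, settings = settings)
    tcc <- suppressWarnings(
      color_tanimoto(ref, p, ref_features = ref_features,
                     transform = al$transform))
    list(tc_shape = tcs, tc_color = tcc, transform = al$transform)
  })
  out <- data.frame(
    id = names(probes),
    tc_shape = vapply(rows, `[[`, numeric(1), "tc_shape"),
    tc_color = vapply(rows, `[[`, numeric(1), "tc_color"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$tc_combo <- weights[[1L]] * out$tc_shape + weights[[2L]] * out$tc_color
  ord <- order(-out$tc_combo, out$id)
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "transforms") <- lapply(rows, `[[`, "transform")[ord]
  out
}
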