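#' Parameters of a synthetic docking study
#'
#' Defines the generative model the analysis pipeline assumes: rigid
#' ligand-like atom clusters docked at a small number of well-separated
#' binding sites (compounds sharing a site overlap strongly; compounds at
#' different sites overlap not at all); binding energies Eb = -deltaG drawn
#' per ground-truth class; binary displacement activity determined by
#' whether a compound occupies the reference (propidium) site, with optional
#' label noise; and a graded inhibition endpoint linear in Eb with Gaussian
#' noise, clamped to \[0, 100\]%.
#'
#' Defaults mimic the scale of a small docking cohort: 19 compounds over 2
#' sites (gorge mouth vs. catalytic site), 10-40 atoms per compound, Bondi
#' radius choices, class mean energies 8.5 vs 6.5 +/- 0.6 kcal/mol, 5% label
#' noise.  The default inhibition noise SD is solved in closed form so the
#' population energy-inhibition correlation [expected_r()] is 0.80, and the
#' inhibition intercept maps the class mean energies to 61% and 81% mean
#' inhibition.
#'
#' @param n_compounds Number of compounds.
#' @param n_sites Number of binding sites.
#' @param site_centers List of 3-vectors (Angstrom); pairwise distance must
#'   exceed 25 Angstrom.  Default: sites every 40 Angstrom along x.
#' @param site_jitter_sd SD (Angstrom) of the per-compound placement jitter.
#' @param atoms_per_compound Length-2 integer range.
#' @param radius_choices vdW radii (Angstrom) sampled per atom.
#' @param reference_site Index of the site the propidium analog occupies.
#' @param eb_mean_active,eb_mean_inactive,eb_sd Binding-energy model
#'   (kcal/mol); the active mean must exceed the inactive mean.
#' @param label_flip_prob Probability of flipping an observed label, in
#'   \[0, 0.5).
#' @param inhib_slope Inhibition slope, percent per kcal/mol.
#' @param inhib_noise_sd Inhibition noise SD (percent); `NULL` solves it so
#'   that `expected_r(params) == 0.80`.
#' @param donepezil_raw_pct Raw displacement of the donepezil reference used
#'   to de-normalize displacement values.
#' @param seed Integer master seed; per-compound substreams are derived from
#'   it, so adding a compound never perturbs earlier compounds.
#' @return An object of class `study_params`.
#' @export
study_params <- function(n_compounds = 19L,
                         n_sites = 2L,
                         site_centers = NULL,
                         site_jitter_sd = 0.5,
                         atoms_per_compound = c(10L, 40L),
                         radius_choices = c(1.2, 1.52, 1.55, 1.7, 2.05),
                         reference_site = 1L,
                         eb_mean_active = 8.5,
                         eb_mean_inactive = 6.5,
                         eb_sd = 0.6,
                         label_flip_prob = 0.05,
                         inhib_slope = 10,
                         inhib_noise_sd = NULL,
                         donepezil_raw_pct = 11.9,
                         seed = 42L) {
  if (is.null(site_centers))
    site_centers <- lapply(seq_len(n_sites) - 1L, function(k) c(40 * k, 0, 0))
  if (length(site_centers) != n_sites) stop("one center per site required")
  if (n_sites >= 2L) {
    ctr <- do.call(rbind, site_centers)
    if (min(stats::dist(ctr)) <= 25)
      stop("site centers must be pairwise more than 25 Angstrom apart")
  }
  if (eb_mean_active <= eb_mean_inactive)
    stop("eb_mean_active must exceed eb_mean_inactive")
  if (label_flip_prob < 0 || label_flip_prob >= 0.5)
    stop("label_flip_prob must lie in [0, 0.5)")
  if (length(atoms_per_compound) != 2L || atoms_per_compound[1L] < 3L ||
      atoms_per_compound[2L] < atoms_per_compound[1L])
    stop("atoms_per_compound must be an increasing range with minimum >= 3")
  if (!reference_site %in% seq_len(n_sites))
    stop("reference_site out of range")
  params <- list(
    n_compounds = as.integer(n_compounds), n_sites = as.integer(n_sites),
    site_centers = site_centers, site_jitter_sd = site_jitter_sd,
    atoms_per_compound = as.integer(atoms_per_compound),
    radius_choices = radius_choices,
    reference_site = as.integer(reference_site),
    eb_mean_active = eb_mean_active, eb_mean_inactive = eb_mean_inactive,
    eb_sd = eb_sd, label_flip_prob = label_flip_prob,
    inhib_slope = inhib_slope,
    inhib_intercept = 71 - inhib_slope * (eb_mean_active + eb_mean_inactive) / 2,
    inhib_noise_sd = inhib_noise_sd,
    donepezil_raw_pct = donepezil_raw_pct,
    seed = as.integer(seed))
  class(params) <- "study_params"
  if (is.null(params$inhib_noise_sd))
    params$inhib_noise_sd <- inhibition_noise_for_r(params, 0.80)
  params
}

#' @export
print.study_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<study_params> %d compounds, %d sites, %d-%d atoms, seed %d\n",
    "  Eb: %.2f/%.2f +/- %.2f kcal/mol, flip %.2f\n",
    "  inhibition: %.1f + %.1f*Eb +/- %.2f%%  (expected r = %.3f)\n"),
    x$n_compounds, x$n_sites, x$atoms_per_compound[1L],
    x$atoms_per_compound[2L], x$seed, x$eb_mean_active, x$eb_mean_inactive,
    x$eb_sd, x$label_flip_prob, x$inhib_intercept, x$inhib_slope,
    x$inhib_noise_sd, expected_r(x)))
  invisible(x)
}

# Marginal SD of Eb implied by the params: a two-component normal mixture
# with reference-site probability 1/n_sites.
marginal_eb_sd <- function(params) {
  p <- 1 / params$n_sites
  dmu <- params$eb_mean_active - params$eb_mean_inactive
  sqrt(params$eb_sd^2 + p * (1 - p) * dmu^2)
}

#' Population energy-inhibition correlation implied by study parameters
#'
#' Closed form for the linear-plus-noise inhibition model:
#' `rho = slope * sd(Eb) / sqrt(slope^2 sd(Eb)^2 + noise_sd^2)`, where
#' `sd(Eb)` is the marginal binding-energy SD implied by the class mixture.
#' The clamping of inhibition to \[0, 100\] is ignored here, which is why
#' recovery tests hold only when the intercept keeps the bulk of the
#' distribution inside the range.
#'
#' @param params A [study_params()].
#' @return Population correlation in (0, 1\].
#' @export
expected_r <- function(params) {
  if (params$inhib_noise_sd < 0) stop("inhib_noise_sd must be >= 0")
  s <- params$inhib_slope * marginal_eb_sd(params)
  tot <- sqrt(s^2 + params$inhib_noise_sd^2)
  if (tot == 0) stop("zero total inhibition variance; correlation undefined")
  s / tot
}

#' Inhibition noise SD achieving a target population correlation
#'
#' Inverts [expected_r()]: `noise = slope * sd(Eb) * sqrt(1/rho^2 - 1)`.
#'
#' @param params A [study_params()].
#' @param rho Target population correlation in (0, 1].
#' @return Noise SD in percent.
#' @export
inhibition_noise_for_r <- function(params, rho) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  params$inhib_slope * marginal_eb_sd(params) * sqrt(1 / rho^2 - 1)
}

# Derived substream seed, kept well below 2^31.
substream_seed <- function(seed, k, tag) {
  ((seed %% 100000L) * 1009L + k * 101L + tag) %% 2147483647L
}

# element symbol matching each sampled radius (Bondi values), for SDF export
element_for_radius <- function(r) {
  map <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Fe = 2.05)
  idx <- vapply(r, function(ri) {
    m <- which(abs(map - ri) < 1e-6)
    if (length(m)) m[[1L]] else match("C", names(map))
  }, integer(1))
  names(map)[idx]
}

#' Generate one rigid synthetic compound
#'
#' Atom positions are drawn from an isotropic Gaussian (SD 2.0 Angstrom)
#' and resampled until every atom lies within 2.5 Angstrom of another atom
#' (a connected, ligand-like cluster); radii are sampled from
#' `radius_choices`.  Deterministic for a fixed seed.  No valence model is
#' applied: downstream stages consume geometry and statistics, not
#' chemistry.
#'
#' @param n_atoms Number of atoms (>= 3).
#' @param radius_choices vdW radii to sample from (Angstrom).
#' @param seed Integer seed.
#' @param id Pose id.
#' @return A [molecule_pose()] with radii assigned.
#' @export
make_compound <- function(n_atoms, radius_choices = c(1.2, 1.52, 1.55, 1.7, 2.05),
                          seed = 1L, id = "cpd") {
  if (n_atoms < 3L) stop("a synthetic compound needs at least 3 atoms")
  withr::with_seed(as.integer(seed), {
    xyz <- matrix(stats::rnorm(3L * n_atoms, sd = 2.0), n_atoms, 3L)
    for (iter in seq_len(200L)) {
      d <- as.matrix(stats::dist(xyz))
      diag(d) <- Inf
      lonely <- which(apply(d, 1L, min) > 2.5)
      if (!length(lonely)) break
      xyz[lonely, ] <- matrix(stats::rnorm(3L * length(lonely), sd = 2.0),
                              length(lonely), 3L)
    }
    if (length(lonely)) stop("could not produce a connected atom cluster")
    r <- sample(radius_choices, n_atoms, replace = TRUE)
    pose <- molecule_pose(id, element_for_radius(r), xyz, radius = r)
    pose$radius_source <- "synthetic"
    pose
  })
}

#' Generate a synthetic docking study
#'
#' Draws, per compound and from its own seed substream: a latent binding
#' site (uniform over sites), a rigid pose translated to the site center
#' plus Gaussian jitter, a ground-truth class (active iff the compound
#' occupies the reference site), an observed label (flipped with
#' `label_flip_prob`), a binding energy from the ground-truth class normal,
#' an inhibition value linear in Eb with Gaussian noise (clamped to
#' \[0, 100\]), and a displacement value consistent with the observed label
#' under the strict >50% rule (observed actives draw a truncated normal
#' centered near the mid-80s; observed inactives are 0, the all-or-nothing
#' phenomenon the binary endpoint encodes).  A larger propidium-analog
#' reference pose (`"prm"`) is placed at the reference site.
#'
#' After generation the realized geometry is checked: poses at different
#' sites must have disjoint bounding spheres (so cross-site overlap is
#' exactly zero); violations are an error.
#'
#' @param params A [study_params()].
#' @param geometry Generate poses?  `FALSE` skips pose construction (for
#'   large statistical replicates that only need energies/labels/
#'   inhibition); all non-geometric fields are identical either way.
#' @return An object of class `synthetic_study`: list with `poses`
#'   (including the reference, or `NULL`), `reference_id`, `activity`,
#'   `endpoints`, `truth` and `params`.
#' @export
make_study <- function(params = study_params(), geometry = TRUE) {
  stopifnot(inherits(params, "study_params"))
  n <- params$n_compounds
  ids <- sprintf("cpd%02d", seq_len(n))
  site <- integer(n); truth_active <- logical(n); flipped <- logical(n)
  eb <- numeric(n); inhib <- numeric(n); norm_pct <- numeric(n)
  n_at <- integer(n); jitter <- matrix(0, n, 3L)
  for (k in seq_len(n)) {
    withr::with_seed(substream_seed(params$seed, k, 1L), {
      site[k] <- sample.int(params$n_sites, 1L)
      n_at[k] <- sample(seq(params$atoms_per_compound[1L],
                            params$atoms_per_compound[2L]), 1L)
      jitter[k, ] <- stats::rnorm(3L, sd = params$site_jitter_sd)
      truth_active[k] <- site[k] == params$reference_site
      flipped[k] <- stats::runif(1L) < params$label_flip_prob
      observed_active <- xor(truth_active[k], flipped[k])
      mu <- if (truth_active[k]) params$eb_mean_active
            else params$eb_mean_inactive
      eb[k] <- stats::rnorm(1L, mu, params$eb_sd)
      inhib[k] <- min(100, max(0, params$inhib_intercept +
        params$inhib_slope * eb[k] +
        stats::rnorm(1L, 0, params$inhib_noise_sd)))
      norm_pct[k] <- if (observed_active) {
        repeat {
          v <- stats::rnorm(1L, 84.1, 10.5)
          if (v > 50.5 && v < 130) break
        }
        v
      } else 0
    })
  }
  observed <- ifelse(xor(truth_active, flipped), "active", "inactive")
  poses <- NULL
  if (geometry) {
    poses <- vector("list", n + 1L)
    for (k in seq_len(n)) {
      p <- make_compound(n_at[k], params$radius_choices,
                         seed = substream_seed(params$seed, k, 2L),
                         id = ids[k])
      ctr <- params$site_centers[[site[k]]] + jitter[k, ]
      p <- transform_pose(p, diag(3), ctr - pose_centroid(p))
      p$binding_energy <- eb[k]
      poses[[k]] <- p
    }
    ref <- make_compound(params$atoms_per_compound[2L] + 20L,
                         params$radius_choices,
                         seed = substream_seed(params$seed, 0L, 2L),
                         id = "prm")
    ref$form <- "reference"
    ref <- transform_pose(ref, diag(3),
                          params$site_centers[[params$reference_site]] -
                            pose_centroid(ref))
    poses[[n + 1L]] <- ref
    names(poses) <- c(ids, "prm")
    check_site_separation(poses, c(site, params$reference_site))
  }
  raw_pct <- norm_pct * params$donepezil_raw_pct / 100
  study <- structure(list(
    poses = poses,
    reference_id = "prm",
    activity = data.frame(id = ids, raw_pct = raw_pct, norm_pct = norm_pct,
                          label = observed, stringsAsFactors = FALSE),
    endpoints = data.frame(id = ids, form = "monomer", binding_energy = eb,
                           displacement_raw_pct = raw_pct,
                           inhibition_pct = inhib, stringsAsFactors = FALSE),
    truth = list(site = site, class_true = ifelse(truth_active, "active",
                                                  "inactive"),
                 flipped = flipped, n_atoms = n_at),
    params = params), class = "synthetic_study")
  study
}

check_site_separation <- function(poses, site) {
  n <- length(poses)
  sph <- lapply(poses, bounding_sphere)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (site[i] == site[j]) next
      gap <- sqrt(sum((sph[[i]]$center - sph[[j]]$center)^2)) -
        sph[[i]]$radius - sph[[j]]$radius
      if (gap <= 0)
        stop("site geometry violates the separation invariant: poses '",
             poses[[i]]$id, "' and '", poses[[j]]$id,
             "' at different sites have intersecting bounding spheres")
    }
  }
  invisible(TRUE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d compounds%s, %d active / %d inactive (observed)\n",
              nrow(x$activity),
              if (is.null(x$poses)) " (no geometry)" else " + reference pose",
              sum(x$activity$label == "active"),
              sum(x$activity$label == "inactive")))
  invisible(x)
}

#' Emulate a dimer pose from a monomer
#'
#' Two copies of the compound's atoms, the second shifted by `offset`, with
#' the pair recentered at `center` — a structural stand-in for a docked
#' dimer occupying a different site than the monomer form.
#'
#' @param pose A [molecule_pose()].
#' @param center 3-vector target centroid (Angstrom).
#' @param offset 3-vector displacement between the two copies.
#' @return A `molecule_pose` with `form = "dimer"` and id `<id>.2`.
#' @export
make_dimer <- function(pose, center, offset = c(3, 0, 0)) {
  xyz <- rbind(pose$xyz, sweep(pose$xyz, 2L, offset, "+"))
  dim_pose <- molecule_pose(paste0(pose$id, ".2"),
                            rep(pose$element, 2L), xyz,
                            radius = rep(pose$radius, 2L), form = "dimer",
                            bonds = NULL, charge = rep(pose$charge, 2L))
  dim_pose$radius_source <- pose$radius_source
  transform_pose(dim_pose, diag(3), center - pose_centroid(dim_pose))
}

#' Docking-derived LDA features of a synthetic study
#'
#' Computes, per compound, the percent overlap of its pose with the
#' propidium-analog reference pose and pairs it with the binding energy —
#' the two-variable feature set the displacement classifier uses.
#'
#' @param study A [make_study()] result generated with geometry.
#' @param settings A [volume_settings()].
#' @return Data frame `id`, `propidium_overlap_pct`, `binding_energy`,
#'   `label`.
#' @export
study_features <- function(study, settings = volume_settings()) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(study$poses))
    stop("study was generated without geometry; rerun make_study(geometry = TRUE)")
  ref <- study$poses[[study$reference_id]]
  ids <- study$activity$id
  ov <- vapply(ids, function(id)
    overlap_percent(study$poses[[id]], ref, settings), numeric(1))
  data.frame(id = ids,
             propidium_overlap_pct = unname(ov),
             binding_energy = study$endpoints$binding_energy,
             label = study$activity$label,
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk
#'
#' Writes `poses.sdf` (all poses incl. the reference), `endpoints.csv`
#' (endpoint schema of [read_endpoints()]) and `truth.json` (ground-truth
#' parameters and latent assignments).  Output is byte-identical for
#' identical parameters and seed.
#'
#' @param study A [make_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(study$poses))
    write_sdf(study$poses, file.path(dir, "poses.sdf"))
  write_endpoints(study$endpoints, file.path(dir, "endpoints.csv"))
  truth <- study$truth
  truth$params <- unclass(study$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
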