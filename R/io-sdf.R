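#' Read docked poses from a (multi-record) SDF file
#'
#' Reads every record of a V2000 or V3000 connection-table SDF into a list
#' of [molecule_pose()] objects, one per record, in file order.  Docking
#' pipelines typically concatenate one SDF per ligand into a single
#' multi-ligand file; all records are assumed to share the receptor-fixed
#' frame, and coordinates are copied verbatim in Angstrom.  Radii are left
#' unassigned (see [assign_radii()]).
#'
#' Pose ids come from the record title line; blank titles become
#' `"record_<k>"` (1-based file order) and colliding ids are deduplicated by
#' suffixing `_2`, `_3`, ...  The bond block and formal charges (atom-block
#' charge codes, overridden by `M  CHG` properties) are retained for
#' pharmacophore feature typing; bonds play no role in volume estimation.
#' Data fields named `binding_energy` and `form` (as written by
#' [write_sdf()]) are restored onto the pose.
#'
#' @param path Path to an SDF file.
#' @return A list of `molecule_pose` objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty SDF file: ", path)
  # split into records on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)  # single record, no terminator
  starts <- c(1L, head(ends, -1L) + 1L)
  poses <- list()
  ids <- character(0)
  k <- 0L
  for (rec in seq_along(starts)) {
    block <- lines[starts[rec]:ends[rec]]
    block <- block[!grepl("^\\$\\$\\$\\$", block)]
    if (all(!nzchar(trimws(block)))) next  # trailing blank record
    k <- k + 1L
    pose <- parse_sdf_record(block, k)
    if (!nzchar(pose$id)) pose$id <- sprintf("record_%d", k)
    base <- pose$id
    j <- 1L
    while (pose$id %in% ids) {
      j <- j + 1L
      pose$id <- sprintf("%s_%d", base, j)
    }
    ids <- c(ids, pose$id)
    poses[[k]] <- pose
  }
  if (!length(poses)) stop("no molecule records found in ", path)
  names(poses) <- ids
  poses
}

parse_sdf_record <- function(block, index) {
  if (length(block) < 4L)
    stop(sprintf("SDF record %d: truncated header block", index))
  title <- trimws(block[1L])
  counts <- block[4L]
  if (grepl("V3000", counts)) {
    parsed <- parse_v3000_ctab(block, index)
  } else {
    parsed <- parse_v2000_ctab(block, index)
  }
  fields <- parse_sdf_data_fields(block)
  eb <- NULL
  if (!is.null(fields[["binding_energy"]])) {
    eb <- suppressWarnings(as.numeric(fields[["binding_energy"]]))
    if (is.na(eb)) eb <- NULL
  }
  form <- fields[["form"]]
  if (is.null(form) || !form %in% c("monomer", "dimer", "reference"))
    form <- "monomer"
  molecule_pose(id = if (nzchar(title)) title else "x",
                element = parsed$element, xyz = parsed$xyz,
                form = form, binding_energy = eb,
                bonds = parsed$bonds, charge = parsed$charge) -> pose
  pose$id <- title  # may be blank; caller fills in record_<k>
  pose
}

parse_v2000_ctab <- function(block, index) {
  counts <- block[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L)
    stop(sprintf("SDF record %d: malformed counts line: '%s'", index, counts))
  if (length(block) < 4L + na + nb)
    stop(sprintf("SDF record %d: connection table shorter than counts line claims", index))
  atom_lines <- block[5L:(4L + na)]
  x <- as.numeric(substr(atom_lines, 1L, 10L))
  y <- as.numeric(substr(atom_lines, 11L, 20L))
  z <- as.numeric(substr(atom_lines, 21L, 30L))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop(sprintf("SDF record %d: unparseable atom coordinates", index))
  el <- trimws(substr(atom_lines, 32L, 34L))
  # old-style charge code: 0 none, 1..3 -> +3..+1, 5..7 -> -1..-3
  code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  code[is.na(code)] <- 0L
  charge <- integer(na)
  charge[code %in% 1:3] <- (4L - code[code %in% 1:3])
  charge[code %in% 5:7] <- (4L - code[code %in% 5:7])
  bonds <- matrix(integer(0), 0L, 2L)
  if (nb > 0L) {
    bond_lines <- block[(5L + na):(4L + na + nb)]
    b1 <- as.integer(substr(bond_lines, 1L, 3L))
    b2 <- as.integer(substr(bond_lines, 4L, 6L))
    bonds <- cbind(b1, b2)
  }
  # M  CHG properties override all old-style codes
  chg_lines <- grep("^M  CHG", block, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(na)
    for (ln in chg_lines) {
      tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
      cnt <- tok[1L]
      for (i in seq_len(cnt)) {
        charge[tok[2L * i]] <- tok[2L * i + 1L]
      }
    }
  }
  list(element = el, xyz = cbind(x, y, z), bonds = bonds, charge = charge)
}

parse_v3000_ctab <- function(block, index) {
  v30 <- sub("^M  V30 ", "", grep("^M  V30 ", block, value = TRUE))
  a0 <- match("BEGIN ATOM", v30); a1 <- match("END ATOM", v30)
  if (is.na(a0) || is.na(a1) || a1 <= a0 + 1L)
    stop(sprintf("SDF record %d: V3000 block without atoms", index))
  atoms <- v30[(a0 + 1L):(a1 - 1L)]
  tok <- strsplit(trimws(atoms), "\\s+")
  el <- vapply(tok, `[[`, character(1), 2L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  charge <- vapply(tok, function(t) {
    m <- grep("^CHG=", t, value = TRUE)
    if (length(m)) as.integer(sub("^CHG=", "", m[1L])) else 0L
  }, integer(1))
  bonds <- matrix(integer(0), 0L, 2L)
  b0 <- match("BEGIN BOND", v30); b1 <- match("END BOND", v30)
  if (!is.na(b0) && !is.na(b1) && b1 > b0 + 1L) {
    btok <- strsplit(trimws(v30[(b0 + 1L):(b1 - 1L)]), "\\s+")
    bonds <- t(vapply(btok, function(t) as.integer(t[3:4]), integer(2)))
  }
  list(element = el, xyz = xyz, bonds = bonds, charge = charge)
}

parse_sdf_data_fields <- function(block) {
  hdr <- grep("^> ", block)
  out <- list()
  for (h in hdr) {
    name <- sub("^.*<([^>]+)>.*$", "\\1", block[h])
    val <- character(0)
    i <- h + 1L
    while (i <= length(block) && nzchar(trimws(block[i]))) {
      val <- c(val, block[i])
      i <- i + 1L
    }
    out[[name]] <- paste(val, collapse = "\n")
  }
  out
}

#' Write poses to a V2000 SDF file
#'
#' Coordinates are written in the standard fixed-point `%10.4f` fields, so a
#' write/read round trip preserves them to 1e-4 Angstrom.  Formal charges are
#' emitted as `M  CHG` properties; binding energy and form are stored as data
#' fields and restored by [read_sdf()].  Output is byte-stable for identical
#' input.
#'
#' @param poses A `molecule_pose` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(poses, path) {
  if (inherits(poses, "molecule_pose")) poses <- list(poses)
  poses <- check_pose_set(poses)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pose in poses) {
    n <- n_atoms(pose)
    nb <- nrow(pose$bonds)
    lines <- c(
      pose$id,
      "  poseoverlap",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              pose$xyz[, 1L], pose$xyz[, 2L], pose$xyz[, 3L], pose$element)
    )
    if (nb > 0L)
      lines <- c(lines, sprintf("%3d%3d%3d  0", pose$bonds[, 1L],
                                pose$bonds[, 2L], 1L))
    chg <- which(pose$charge != 0L)
    while (length(chg)) {
      take <- head(chg, 8L)
      chg <- chg[-seq_along(take)]
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(take)),
        paste(sprintf("%4d%4d", take, pose$charge[take]), collapse = "")))
    }
    lines <- c(lines, "M  END")
    if (!is.null(pose$binding_energy))
      lines <- c(lines, "> <binding_energy>",
                 format(pose$binding_energy, digits = 15), "")
    lines <- c(lines, "> <form>", pose$form, "", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
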