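# Geometric evaluation of docked ligand poses: polar-contact filtering
# against named receptor site atoms and symmetry-corrected RMSD.
#
# A pose is a tibble with columns `element`, `x`, `y`, `z` (Angstrom).
# Poses are compared in a common coordinate frame (docked and experimental
# poses share the receptor frame); no re-superposition is performed.

#' Construct a ligand pose
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param ligand_id Optional identifier carried as an attribute.
#' @return A pose tibble (`element`, `x`, `y`, `z`).
#' @export
pose <- function(element, x, y, z, ligand_id = NA_character_) {
  if (!length(element)) abort("A pose needs at least one atom.")
  atomic_number(element) # validates symbols
  coords <- cbind(x, y, z)
  if (nrow(coords) != length(element) || !all(is.finite(coords))) {
    abort("Coordinates must be finite and match `element` in length.")
  }
  out <- tibble(element = as.character(element),
                x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(out, "ligand_id") <- ligand_id
  out
}

as_pose <- function(data, arg = "pose") {
  check_columns(data, c("element", "x", "y", "z"), "as_pose")
  pose(data$element, data$x, data$y, data$z,
       ligand_id = attr(data, "ligand_id") %||% NA_character_)
}

pose_coords <- function(p) as.matrix(p[, c("x", "y", "z")])

# Optimal assignment (Hungarian algorithm) --------------------------------
#
# Shortest-augmenting-path form with row/column potentials, O(n^3), on a
# square cost matrix. Written here because the assignment step is the core
# of the symmetry-corrected RMSD; verified against a brute-force
# permutation oracle in the test suite.

solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(1L)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials, index 1 = virtual column
  p <- integer(n + 1)    # p[j + 1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      used_j <- which(used)
      u[p[used_j]] <- u[p[used_j]] + delta
      v[used_j] <- v[used_j] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n) # assignment[row] = column
  assignment[p[-1L]] <- seq_len(n)
  assignment
}

element_mismatch <- function(a, b) {
  ta <- table(a$element)
  tb <- table(b$element)
  all_el <- union(names(ta), names(tb))
  diff <- vapply(all_el, function(e) {
    (if (e %in% names(ta)) ta[[e]] else 0L) -
      (if (e %in% names(tb)) tb[[e]] else 0L)
  }, numeric(1))
  diff[diff != 0]
}

#' Symmetry-corrected RMSD between two poses of the same ligand
#'
#' Topologically equivalent atoms (e.g. the two oxygens of a carboxylate)
#' can swap labels between a docked and an experimental pose; naive
#' index-matched RMSD then overstates the discrepancy. Here atoms are
#' re-matched within each element class by solving the optimal assignment
#' (Hungarian algorithm) on the squared-distance cost matrix, and the RMSD
#' is computed over the optimal matching. Poses are compared in a common
#' frame; no superposition is applied.
#'
#' @param a,b Pose tibbles (see [pose()]) with identical element multisets.
#' @return RMSD in Angstrom.
#' @examples
#' p1 <- pose(c("O", "O"), x = c(0, 1), y = 0, z = 0)
#' p2 <- pose(c("O", "O"), x = c(1, 0), y = 0, z = 0) # labels swapped
#' symmetry_rmsd(p1, p2) # 0: the swap is a symmetry, not an error
#' @export
symmetry_rmsd <- function(a, b) {
  a <- as_pose(a, "a")
  b <- as_pose(b, "b")
  bad <- element_mismatch(a, b)
  if (length(bad)) {
    abort(paste0(
      "Poses have different element multisets (a minus b): ",
      paste(sprintf("%s: %+d", names(bad), bad), collapse = ", ")
    ))
  }
  ca <- pose_coords(a)
  cb <- pose_coords(b)
  total <- 0
  for (el in unique(a$element)) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    if (length(ia) == 1L) {
      total <- total + sum((ca[ia, ] - cb[ib, ])^2)
      next
    }
    cost <- outer(seq_along(ia), seq_along(ib), Vectorize(function(i, j) {
      sum((ca[ia[i], ] - cb[ib[j], ])^2)
    }))
    match_ <- solve_assignment(cost)
    total <- total + sum(cost[cbind(seq_along(ia), match_)])
  }
  sqrt(total / nrow(a))
}

#' Naive index-matched RMSD between two poses
#'
#' Baseline for [symmetry_rmsd()]: atoms are paired by their input order.
#' Always greater than or equal to the symmetry-corrected value.
#'
#' @inheritParams symmetry_rmsd
#' @return RMSD in Angstrom.
#' @export
naive_rmsd <- function(a, b) {
  a <- as_pose(a, "a")
  b <- as_pose(b, "b")
  if (nrow(a) != nrow(b)) {
    abort("Poses must have the same number of atoms for index-matched RMSD.")
  }
  sqrt(mean(rowSums((pose_coords(a) - pose_coords(b))^2)))
}

# Polar-contact filtering -------------------------------------------------

#' Define receptor site probes for polar-contact filtering
#'
#' @param residue Residue labels (e.g. `"S383"`, `"T201"`, `"H178"`).
#' @param atom Atom names within each residue (e.g. `"OG"`, `"NE2"`).
#' @param x,y,z Probe coordinates in Angstrom.
#' @param role Hydrogen-bond role, one of `"donor"`, `"acceptor"`,
#'   `"either"` (informational).
#' @return A site tibble usable with [polar_contact_filter()].
#' @export
site_definition <- function(residue, atom, x, y, z, role = "either") {
  out <- tibble(residue = as.character(residue), atom = as.character(atom),
                x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                role = rep_len(as.character(role), length(residue)))
  if (anyDuplicated(out[, c("residue", "atom")])) {
    abort("Site probes must be unique (residue, atom) pairs.")
  }
  if (!all(is.finite(c(out$x, out$y, out$z)))) {
    abort("Probe coordinates must be finite.")
  }
  out
}

#' Read site probes from a PDB-format file
#'
#' Extracts named probe atoms (e.g. the Ser383 OG hydroxyl oxygen) from a
#' PDB-format coordinate subset, for use with [polar_contact_filter()].
#'
#' @param file Path to a PDB-format file.
#' @param probes Data frame with columns `resno` (residue number) and
#'   `atom` (PDB atom name) naming the atoms to extract.
#' @return A site tibble (see [site_definition()]).
#' @export
read_site_pdb <- function(file, probes) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading PDB files requires the bio3d package.")
  }
  check_columns(probes, c("resno", "atom"), "read_site_pdb")
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  rows <- purrr::map2(probes$resno, probes$atom, function(rn, an) {
    hit <- at[at$resno == rn & trimws(at$elety) == an, , drop = FALSE]
    if (!nrow(hit)) {
      abort(sprintf("Probe atom %s of residue %s not found in %s.",
                    an, rn, file))
    }
    hit[1, , drop = FALSE]
  })
  rows <- do.call(rbind, rows)
  site_definition(
    residue = paste0(substr(rows$resid, 1, 1), rows$resno),
    atom = trimws(rows$elety),
    x = rows$x, y = rows$y, z = rows$z
  )
}

#' Polar-contact filter for a docked pose
#'
#' Checks whether the pose places a polar heavy atom (N or O by default)
#' near named receptor probes - the post-docking filter that required
#' candidate poses to approach the key serine/threonine/histidine polar
#' contacts of the binding site. Distances are heavy-atom to heavy-atom;
#' the cutoff is inclusive.
#'
#' @param data Pose tibble. Polar atoms are those whose element is in
#'   `polar_elements`, unless a logical `polar` column marks them
#'   explicitly.
#' @param site Site tibble from [site_definition()] or [read_site_pdb()].
#' @param cutoff Contact cutoff in Angstrom (default 3.5, the conventional
#'   heavy-atom hydrogen-bond limit).
#' @param require `"any"` (default: one satisfied probe passes, the
#'   S383-or-T201-or-H178 reading) or `"all"`.
#' @param polar_elements Elements counted as polar (default N and O).
#' @return A contact report: one row per probe with the minimum
#'   ligand-polar-atom distance and the achieving atom index, plus
#'   attributes `pass` (logical) and `reason`.
#' @export
polar_contact_filter <- function(data, site, cutoff = 3.5,
                                 require = c("any", "all"),
                                 polar_elements = c("N", "O")) {
  p <- as_pose(data)
  require <- match.arg(require)
  check_number(cutoff, "cutoff", lower = 0)
  check_columns(site, c("residue", "atom", "x", "y", "z"),
                "polar_contact_filter")
  polar_idx <- if ("polar" %in% names(data)) {
    which(as.logical(data$polar))
  } else {
    which(p$element %in% polar_elements)
  }
  if (!length(polar_idx)) {
    out <- tibble(residue = site$residue, atom = site$atom,
                  min_distance = NA_real_, ligand_atom = NA_integer_,
                  contact = FALSE)
    attr(out, "pass") <- FALSE
    attr(out, "reason") <- "no polar atoms"
    attr(out, "rule") <- require
    return(out)
  }
  lig <- pose_coords(p)[polar_idx, , drop = FALSE]
  res <- map(seq_len(nrow(site)), function(k) {
    d <- sqrt(rowSums((lig - matrix(c(site$x[k], site$y[k], site$z[k]),
                                    nrow(lig), 3, byrow = TRUE))^2))
    best <- which.min(d)
    tibble(residue = site$residue[k], atom = site$atom[k],
           min_distance = d[best], ligand_atom = polar_idx[best],
           contact = d[best] <= cutoff)
  })
  out <- bind_rows(res)
  pass <- if (require == "any") any(out$contact) else all(out$contact)
  attr(out, "pass") <- pass
  attr(out, "reason") <- if (pass) "contact satisfied" else
    sprintf("no probe within %.2f Angstrom", cutoff)
  attr(out, "rule") <- require
  out
}

# SD-format pose I/O ------------------------------------------------------

#' Read ligand poses from an SD-format file
#'
#' @param file Path to an SDF/SD file with 3-D coordinates.
#' @return A list of pose tibbles, one per record, named by record header.
#' @export
read_poses_sdf <- function(file) {
  # pose records carry no bond block, which ChemmineR flags; coordinates
  # and elements are all that pose analyses need
  sdf <- suppressWarnings(ChemmineR::read.SDFset(file))
  ids <- ChemmineR::sdfid(sdf)
  poses <- lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    el <- sub("_.*$", "", rownames(ab))
    pose(el, ab[, 1], ab[, 2], ab[, 3], ligand_id = ids[i])
  })
  names(poses) <- ids
  poses
}

#' Write ligand poses to an SD-format file
#'
#' Writes coordinates and elements as a minimal V2000 molfile per pose
#' (no bond block), sufficient for RMSD and contact analyses.
#'
#' @param poses A pose tibble or list of pose tibbles.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_poses_sdf <- function(poses, file) {
  if (is.data.frame(poses)) poses <- list(poses)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- as_pose(poses[[i]])
    id <- names(poses)[i] %||% attr(poses[[i]], "ligand_id") %||%
      sprintf("pose_%d", i)
    if (is.na(id) || !nzchar(id)) id <- sprintf("pose_%d", i)
    writeLines(c(id, "  dockpharm", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(p), 0L), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       p$x, p$y, p$z, p$element), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(file)
}
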