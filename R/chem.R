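# Molecular structures: SMILES parsing and circular fingerprints.
#
# SMILES handling (canonicalisation, graph perception) is delegated to
# OpenBabel through ChemmineOB/ChemmineR. The hashed circular fingerprint
# itself (the conventional ECFP4-style descriptor: radius-2 substructure
# environments folded to 2048 bits) is computed here, so that every
# Tanimoto threshold in the triage cascade is applied with one
# self-consistent fingerprinter. Bit-exact agreement with other toolkits'
# ECFP4 is not promised and not needed: all thresholds are interpreted
# relative to this fingerprinter.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

atomic_number <- function(element) {
  z <- match(element, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    abort(sprintf("Unknown element symbol%s: %s.",
                  if (sum(is.na(z)) > 1) "s" else "",
                  paste(unique(element[is.na(z)]), collapse = ", ")))
  }
  z
}

# Canonicalise SMILES through OpenBabel so that equivalent writings of the
# same structure ("CCO" vs "OCC") map to one string before perception.
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n")
  )
  can <- strsplit(out, "\n", fixed = TRUE)[[1]]
  can <- sub("\t.*$", "", can)
  can <- sub("[ \t]+$", "", can)
  bad <- which(!nzchar(can))
  if (length(can) != length(smiles) || length(bad)) {
    offending <- if (length(can) == length(smiles)) {
      smiles[bad]
    } else {
      smiles
    }
    abort(sprintf("Unparseable SMILES: %s",
                  paste0('"', offending, '"', collapse = ", ")))
  }
  can
}

# Ring-bond detection: an edge is a ring bond iff it is not a bridge of
# the molecular graph. Iterative DFS with discovery times and low-links.
ring_bonds <- function(n, edges) {
  # edges: 2-column matrix of atom indices
  m <- nrow(edges)
  if (!m) return(logical(0))
  adj_e <- vector("list", n)
  for (k in seq_len(m)) {
    i <- edges[k, 1]
    j <- edges[k, 2]
    adj_e[[i]] <- c(adj_e[[i]], k)
    adj_e[[j]] <- c(adj_e[[j]], k)
  }
  other <- function(k, i) if (edges[k, 1] == i) edges[k, 2] else edges[k, 1]
  disc <- integer(n)
  low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(v = root, pe = 0L, ei = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ei <= length(adj_e[[v]])) {
        k <- adj_e[[v]][fr$ei]
        stack[[length(stack)]]$ei <- fr$ei + 1L
        if (k == fr$pe) next
        w <- other(k, v)
        if (disc[w] > 0L) {
          low[v] <- min(low[v], disc[w])
        } else {
          timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, ei = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# Heavy-atom molecular graph from one canonical SMILES.
smiles_graph <- function(smiles_can) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles_can)),
    error = function(e) abort(sprintf('Unparseable SMILES: "%s"', smiles_can))
  )
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  heavy <- which(element != "H")
  idx <- match(seq_along(element), heavy) # old index -> heavy index or NA
  n <- length(heavy)
  edges <- matrix(integer(0), 0, 3) # i, j, order (heavy atoms only)
  if (length(bb) && nrow(bb)) {
    for (k in seq_len(nrow(bb))) {
      i <- idx[bb[k, 1]]
      j <- idx[bb[k, 2]]
      if (is.na(i) || is.na(j)) next
      edges <- rbind(edges, c(i, j, bb[k, 3]))
    }
  }
  in_ring_bond <- ring_bonds(n, edges[, 1:2, drop = FALSE])
  adj <- vector("list", n)
  ord <- vector("list", n)
  ringb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]
    j <- edges[k, 2]
    o <- edges[k, 3]
    r <- as.integer(in_ring_bond[k])
    adj[[i]] <- c(adj[[i]], j)
    ord[[i]] <- c(ord[[i]], o)
    ringb[[i]] <- c(ringb[[i]], r)
    adj[[j]] <- c(adj[[j]], i)
    ord[[j]] <- c(ord[[j]], o)
    ringb[[j]] <- c(ringb[[j]], r)
  }
  list(element = element[heavy], adj = adj, bond_order = ord,
       ring_bond = ringb)
}

fp_new <- function(bits, radius, n_bits, smiles = NA_character_) {
  structure(
    list(bits = as.integer(bits), radius = as.integer(radius),
         n_bits = as.integer(n_bits), smiles = smiles),
    class = "dockpharm_fp"
  )
}

#' @export
print.dockpharm_fp <- function(x, ...) {
  cat(sprintf("<circular fingerprint: radius %d, %d/%d bits set%s>\n",
              x$radius, length(x$bits), x$n_bits,
              if (is.na(x$smiles)) "" else paste0(", ", x$smiles)))
  invisible(x)
}

fp_from_graph <- function(graph, radius, n_bits) {
  n <- length(graph$element)
  z <- atomic_number(graph$element)
  degree <- vapply(graph$adj, length, integer(1))
  bosum <- vapply(graph$bond_order,
                  function(o) if (length(o)) sum(o) else 0, numeric(1))
  in_ring <- vapply(graph$ring_bond,
                    function(r) as.integer(any(r > 0)), integer(1))
  # implicit hydrogen count from default valence (organic subset)
  default_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                   Br = 1, I = 1, B = 3)
  dv <- default_val[graph$element]
  dv[is.na(dv)] <- 0
  n_h <- pmax(0, dv - bosum)
  inv <- vapply(seq_len(n), function(i) {
    hash_mix(c(0, z[i], degree[i], bosum[i], in_ring[i], n_h[i]))
  }, numeric(1))
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      inv_new <- vapply(seq_len(n), function(i) {
        nb <- graph$adj[[i]]
        if (!length(nb)) return(hash_mix(c(r, inv[i])))
        # bond label combines order and ring membership
        o <- graph$bond_order[[i]] + 10 * graph$ring_bond[[i]]
        key <- order(o, inv[nb])
        hash_mix(c(r, inv[i], rbind(o[key], inv[nb][key])))
      }, numeric(1))
      inv <- inv_new
      ids <- c(ids, inv)
    }
  }
  sort(unique(as.integer(ids %% n_bits)))
}

#' Hashed circular fingerprints from SMILES
#'
#' Computes radius-2 hashed circular substructure fingerprints (the
#' conventional ECFP4 equivalent) folded to a fixed bit length. Structures
#' are canonicalised first, so any SMILES writing of the same molecule
#' yields an identical fingerprint.
#'
#' @param smiles Character vector of SMILES strings.
#' @param radius Neighbourhood radius in bonds (default 2, i.e. ECFP4).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return For a single SMILES, a fingerprint object; otherwise a list of
#'   fingerprint objects, named after `names(smiles)` when present.
#' @examples
#' fp <- fingerprint("CCO")
#' identical(fp$bits, fingerprint("OCC")$bits)
#' @export
fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  radius <- check_count(radius, "radius", min = 0L)
  n_bits <- check_count(n_bits, "n_bits", min = 2L)
  if (!is.character(smiles) || !length(smiles)) {
    abort("`smiles` must be a non-empty character vector.")
  }
  can <- canonical_smiles(smiles)
  fps <- lapply(seq_along(smiles), function(i) {
    g <- smiles_graph(can[i])
    fp_new(fp_from_graph(g, radius, n_bits), radius, n_bits, smiles[i])
  })
  names(fps) <- names(smiles)
  if (length(fps) == 1L) fps[[1]] else fps
}

as_fp <- function(x, arg = "fingerprint") {
  if (!inherits(x, "dockpharm_fp")) {
    abort(sprintf("`%s` must be a fingerprint object (see `fingerprint()`).",
                  arg))
  }
  x
}

#' Tanimoto similarity between two fingerprints
#'
#' The Tanimoto (Jaccard) coefficient `|A n B| / |A u B|` on the set bits of
#' two fingerprints computed with identical radius and length. Two empty
#' fingerprints are defined to have similarity 0 (with a warning).
#'
#' @param a,b Fingerprint objects from [fingerprint()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(fingerprint("CCO"), fingerprint("CCN"))
#' @export
tanimoto <- function(a, b) {
  a <- as_fp(a, "a")
  b <- as_fp(b, "b")
  if (a$radius != b$radius || a$n_bits != b$n_bits) {
    abort("Fingerprints must share `radius` and `n_bits` to be compared.")
  }
  union_n <- length(union(a$bits, b$bits))
  if (union_n == 0L) {
    warn("Both fingerprints are empty; Tanimoto defined as 0.")
    return(0)
  }
  length(intersect(a$bits, b$bits)) / union_n
}

# Tanimoto of one fingerprint against a list, vectorised.
tanimoto_many <- function(fp, fps) {
  vapply(fps, function(x) tanimoto(fp, x), numeric(1))
}
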