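# Independent brute-force oracles used to verify the package's
# algorithms on small instances. These are deliberately naive and share
# no code with the implementation under test.

# All permutations of a vector (n! enumeration).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# Exhaustive-minimum symmetry RMSD: minimise over all same-element atom
# permutations independently per element class.
brute_force_rmsd <- function(a, b) {
  ca <- as.matrix(a[, c("x", "y", "z")])
  cb <- as.matrix(b[, c("x", "y", "z")])
  total <- 0
  for (el in unique(a$element)) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    best <- Inf
    for (p in all_perms(seq_along(ib))) {
      ss <- sum((ca[ia, , drop = FALSE] - cb[ib[p], , drop = FALSE])^2)
      best <- min(best, ss)
    }
    total <- total + best
  }
  sqrt(total / nrow(a))
}

# Independent greedy leader pass over a score-sorted record table, using
# a caller-supplied similarity function. Plain loops, no dplyr.
brute_force_leader <- function(ids, sim_fun, threshold) {
  leaders <- character(0)
  assigned <- character(length(ids))
  for (i in seq_along(ids)) {
    hit <- NA_character_
    for (l in leaders) {
      if (sim_fun(ids[i], l) >= threshold) {
        hit <- l
        break
      }
    }
    if (is.na(hit)) {
      leaders <- c(leaders, ids[i])
      hit <- ids[i]
    }
    assigned[i] <- hit
  }
  assigned
}

# Set-based Tanimoto on plain integer vectors (for constructed cases).
set_tanimoto <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Build a fingerprint object directly from a bit set (internal constructor).
make_fp <- function(bits, radius = 2, n_bits = 2048) {
  dockpharm:::fp_new(bits, radius, n_bits)
}
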