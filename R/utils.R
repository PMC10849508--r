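# Internal helpers shared across modules.

# Scalar validation -----------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %s is outside the allowed range [%s, %s].",
                  name, format(x), format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  as.integer(x)
}

check_columns <- function(data, cols, caller) {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s()` expects a data frame as its first argument.",
                  caller))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("`%s()` requires column%s %s.", caller,
                  if (length(missing) > 1) "s" else "",
                  paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(data)
}

# Deterministic integer hashing ------------------------------------------
#
# A multiplicative mixing hash over integer component vectors, carried out
# in double precision below 2^53 so it is exactly reproducible on every
# platform. Used by the circular fingerprinter; not cryptographic.

HASH_MOD <- 2147483629 # largest prime < 2^31

hash_mix <- function(components, seed = 5381) {
  h <- seed
  for (x in components) {
    h <- (h * 33 + x) %% HASH_MOD
  }
  h
}

# Seeded evaluation without touching the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
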