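#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points route their
# randomness through this so global RNG state is never consumed implicitly.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent lexicographic sort (radix), used for all tie-breaks.
sort_cstr <- function(x) sort(x, method = "radix")

# Recursive helpers over nested parameter lists whose leaves are numeric
# arrays.  Used by the optimizer and gradient accumulation.
params_map <- function(p, f) {
  if (is.list(p)) lapply(p, params_map, f = f) else f(p)
}

params_map2 <- function(p, q, f) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- params_map2(p[[i]], q[[i]], f)
    out
  } else {
    f(p, q)
  }
}

params_zeros_like <- function(p) params_map(p, function(x) x * 0)

params_axpy <- function(acc, g, a = 1) params_map2(acc, g, function(x, y) x + a * y)

params_scale <- function(p, a) params_map(p, function(x) x * a)

# Flatten a nested parameter list to a single numeric vector and back; used by
# the finite-difference gradient checker and for small diagnostics.
params_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, params_flatten), use.names = FALSE) else as.numeric(p)
}

# Inverse of params_flatten: pour a flat numeric vector back into the shape of
# `template` (dims and nesting preserved).
relist_params <- function(flat, template) {
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- p
    out[] <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  fill(template)
}
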