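# Internal helpers shared across modules.

# Evaluate an expression under a fixed RNG state, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stage/index pair; keeps every
# stage on its own reproducible stream while staying inside 32-bit range.
derive_seed <- function(seed, index, stage = 0L) {
  (as.double(seed) * 7919 + as.double(index) * 104729 + as.double(stage) * 15485863) %%
    2147483629
}

# Coerce a scalar or function(x_um, y_um) field to a vectorised function.
as_field_fun <- function(value, name) {
  if (is.function(value)) {
    return(value)
  }
  if (is.numeric(value) && length(value) == 1L && is.finite(value)) {
    force(value)
    return(function(x_um, y_um) rep(value, length(x_um)))
  }
  stop(sprintf("'%s' must be a finite scalar or a function(x_um, y_um)", name),
       call. = FALSE)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lo), format(hi)),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# Rows belonging to the choroid band at one A-scan: 1-based row i is inside
# iff rpe < i <= csj. Both curves are real-valued (sub-pixel boundaries).
band_row_range <- function(rpe, csj) {
  lo <- floor(rpe) + 1
  hi <- floor(csj)
  if (hi < lo) return(NULL)
  c(lo, hi)
}

# Logical H x W mask of the choroid band given per-column boundary rows.
band_mask <- function(h, rpe_curve, csj_curve) {
  w <- length(rpe_curve)
  rows <- matrix(seq_len(h), nrow = h, ncol = w)
  rows > rep(floor(rpe_curve), each = h) & rows <= rep(floor(csj_curve), each = h)
}
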