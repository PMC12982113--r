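#' @importFrom rlang %||%
#' @keywords internal
NULL

# Seeded evaluation without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Derive a reproducible child seed (kept within 32-bit integer range;
# arithmetic in doubles, exact below 2^53).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483647)
}
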