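# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Valid biological group labels plus the pooled-QC label.
GROUP_LEVELS <- c("ND_UT", "ND_TETA", "DM_UT", "DM_TETA", "QC")
BIO_GROUPS <- setdiff(GROUP_LEVELS, "QC")
ION_MODES <- c("positive", "negative")

# Classed error helper so callers can distinguish input, format and
# consistency failures programmatically.
mf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mf_error", "error", "condition")))
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Deterministic child seed derivation; keeps results < 2^31 so they remain
# valid R integers.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1103L + as.numeric(offset) * 12289L) %% 2147483587)
}
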