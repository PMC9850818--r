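#' @keywords internal
"_PACKAGE"

# Package-level logging: informational messages go to stderr and are silent
# unless the user opts in (the CLI sets this for its --verbose flag).
cc_log <- function(fmt, ...) {
  if (isTRUE(getOption("cisconstraint.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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
  force(code)
}

# Spearman rank correlation that returns NA on degenerate input instead of
# warning; used where a correlation is an intermediate quantity.
spearman_rho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
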