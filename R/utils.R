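# Classed conditions so the CLI can map failures to exit codes:
# input errors -> 2, invariant violations -> 3.
stopInput <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("sigreverse_input_error", "error")))
}

stopInvariant <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("sigreverse_invariant_error", "error")))
}

# Run expr under a local RNG state seeded with `seed` (restores the caller's
# RNG afterwards). All package randomness flows through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic descending / ascending orderings with the documented
# tie rule: ties broken by gene identifier ascending.
orderDesc <- function(values, genes) order(-values, genes, method = "radix")
orderAsc <- function(values, genes) order(values, genes, method = "radix")

# Full-precision number formatting for text outputs ("%.17g" round-trips
# doubles exactly).
formatFull <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[is.na(x)] <- "NA"
  out
}
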