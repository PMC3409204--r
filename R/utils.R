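# Internal helpers shared across modules.

# Validate a numeric vector of probabilities; indexed message on failure.
check_pvalues <- function(p, arg = "pvalues") {
  if (!is.numeric(p)) {
    abort(sprintf("`%s` must be numeric, got %s.", arg, class(p)[1]))
  }
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has %d non-finite or out-of-[0,1] entries (first offender at index %d: %s).",
      arg, length(bad), bad[1], format(p[bad[1]])
    ))
  }
  invisible(p)
}

# Optionally reseed R's RNG. NULL leaves the ambient stream untouched so
# callers (e.g. the scenario driver) can manage seeding themselves.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# Derive a per-(scenario, replicate) seed from a master seed; kept inside
# 32-bit integer range. Multipliers are distinct primes so nearby master
# seeds do not produce overlapping replicate streams in practice.
derive_seed <- function(master, scenario = 0L, replicate = 0L) {
  m <- (as.double(master) %% 2147483647) * 48271
  s <- (m + 2654435761 * (scenario %% 32768) + 97561 * replicate) %% 2147483629
  as.integer(s %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
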