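# Internal helpers: scoped RNG and content hashing.

# Run `expr` under a fixed RNG seed, then restore the caller's RNG state,
# so library functions never perturb user-level random streams.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stream index,
# kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

# MD5 of an arbitrary R object via its version-2 serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
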