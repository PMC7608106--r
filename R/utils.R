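# Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards: no function in the package touches
# global random state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fmValidationError("'seed' must be a single non-missing number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# name-preserving coercion to character (as.character drops names on
# plain character vectors)
asNamedChar <- function(x) if (is.character(x)) x else as.character(x)

collapse0 <- function(x) paste0(x, collapse = "")

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
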