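# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
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
  force(expr)
}

# Derive a reproducible child seed from a base seed and a string tag, keeping
# the result inside the 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

# Round half away from zero (Matlab-style), unlike base round()'s
# round-half-even. Coordinates are real-valued; pixel indices must be stable.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# MD5 of an arbitrary R object via its serialized bytes (tools::md5sum only
# hashes files, so spool through a tempfile).
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

file_md5 <- function(paths) {
  unname(tools::md5sum(paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Write/read a plain-text numeric matrix (tab-separated, no names).
write_text_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_text_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
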