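# Internal helpers shared across modules.

stc_stop <- function(msg, class) {
  stop(structure(class = c(class, "stcError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stc_validation_error <- function(msg) stc_stop(msg, "stcValidationError")
stc_not_found_error  <- function(msg) stc_stop(msg, "stcNotFoundError")
stc_format_error     <- function(msg) stc_stop(msg, "stcFormatError")

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stc_validation_error("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise normalization of an n x 3 matrix; zero rows stay zero.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  nz <- n > 0
  m[nz, ] <- m[nz, , drop = FALSE] / n[nz]
  m
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation calls do not clobber it.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
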