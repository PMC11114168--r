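# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a master seed and a sequence of
# string/number labels (stage names, subject ids). A small polynomial string
# hash keeps the derivation stable across platforms and R versions.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                         character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fixed-width right-padded ASCII field (EDF header pieces).
.pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("field wider than ", width, " bytes: ", x)
  formatC(x, width = -width, flag = " ")
}

.stop_missing <- function(what, where) {
  stop(sprintf("%s not found in %s", what, where), call. = FALSE)
}
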