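# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never clobber the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stage label.
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(what)) * seq_along(utf8ToInt(as.character(what))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

split_seq <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Canonical unordered-pair orientation: lexicographically smaller id first.
orient_pairs <- function(idA, idB) {
  a <- pmin(idA, idB)
  b <- pmax(idA, idB)
  tibble::tibble(idA = a, idB = b)
}

pair_key <- function(idA, idB) paste(pmin(idA, idB), pmax(idA, idB), sep = "\r")
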