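# Internal helpers shared across modules.

#' Derive a child seed from a parent seed
#'
#' Counter-based splitting: the seed for record `index` of stream `stream`
#' depends only on `(seed, index, stream)`, never on how many other records
#' are generated, so enlarging a cohort does not shift the noise of existing
#' records.
#'
#' @param seed parent integer seed.
#' @param index counter (record number, repeat number, ...).
#' @param stream integer stream label separating independent uses of the same
#'   counter (e.g. control vs treated records).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  z <- as.numeric(seed) %% m
  z <- (z * 48271 + as.numeric(stream) * 99991 + as.numeric(index) * 16807 + 12345) %% m
  z <- (z * 69621) %% m
  as.integer(z) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                             integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

# Recursively sort named lists so serialization is key-order independent.
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else {
    x
  }
}

# Canonical JSON for hashing/serialization: sorted keys, no indentation,
# full double precision.
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

# md5 of the canonical JSON serialization of an R object (config hashing).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(canonical_json(x), f, useBytes = TRUE)
  unname(tools::md5sum(f))
}
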