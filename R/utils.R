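#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' A small splittable scheme so every stage and every participant draws from
#' an independent, reproducible stream. The mixing is a nonlinear 32-bit
#' hash (xor-shift/multiply rounds): base R's seed scrambling is affine, so
#' affinely related seeds stay correlated through the generator — related
#' child indices must therefore be scattered nonlinearly. Stays below 2^31.
#'
#' @param seed Master integer seed.
#' @param ... One or more non-negative integer indices (stage, participant,
#'   video, ...).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 4294967296
  for (i in idx) {
    s <- (s + as.double(i) + 2654435769) %% 4294967296
    s <- mix32(s)
  }
  as.integer(mix32(s) %% 2147483645 + 1)
}

# splitmix32-style finalizer on doubles (exact 32-bit arithmetic)
mix32 <- function(z) {
  z <- xor32(z, floor(z / 65536))
  z <- mul32(z, 2246822519)
  z <- xor32(z, floor(z / 8192))
  z <- mul32(z, 3266489917)
  xor32(z, floor(z / 65536))
}

# 32-bit modular multiply / xor via 16-bit halves (doubles stay < 2^53)
mul32 <- function(a, b) {
  ((a %% 65536) * b + ((floor(a / 65536) * b) %% 65536) * 65536) %% 4294967296
}
xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(floor(a / 65536), floor(b / 65536)) * 65536
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Write a data frame as a tab-delimited table with header
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
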