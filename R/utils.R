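## Internal helpers: errors, seeding, rounding.

.stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "painAU_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a module seed from a global seed
#'
#' One global seed fans out to per-module / per-unit seeds through a small
#' deterministic splitter, so a single integer reproduces a whole
#' experiment. The result is always a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param label Character label naming the consumer (e.g. `"simulate"`,
#'   `"subject_12/seg_3"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 2654435 + h) %% 2147480009)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero, the convention
#' used for the package's percentage tables (so 0.005 -> 0.01).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Percentage formatting used by every report table.
.pct <- function(x, digits = 2) roundHalfUp(100 * x, digits)

## Content hash of an arbitrary R object (used for dataset determinism
## contracts; file-level hashes are unsuitable because HDF5 headers may
## embed write-time metadata).
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3L), f)
  unname(tools::md5sum(f))
}
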