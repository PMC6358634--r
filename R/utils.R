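#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats approx median quantile runif setNames
#' @importFrom utils head modifyList read.table tail write.csv
NULL

# Run expr with a given RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# md5 of an arbitrary R object via serialization; used for cache keys.
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle (radians) between rows of unit-vector matrix A and unit vector b,
# or between all row pairs of A when b is missing.
angle_between <- function(a, b) {
  d <- pmin(1, pmax(-1, rowSums(a * matrix(b, nrow(a), 3, byrow = TRUE))))
  acos(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
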