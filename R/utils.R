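#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that package functions never clobber the user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed_eval <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629) + 1L
}

# Half-up rounding as used for display in the result tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Content hash of an arbitrary R object (stable serialization v2).
hash_object <- function(x) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

#' Canonical class labels
#'
#' Fixed label order used throughout the package: healthy controls first,
#' then the three neurodegenerative disease groups.
#'
#' @return character vector `c("HC", "ALS", "PD", "HD")`.
#' @export
ndd_labels <- function() c("HC", "ALS", "PD", "HD")
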