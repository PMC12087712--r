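#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif uniroot
#' @importFrom utils write.csv read.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

REGION_LEVELS <- c("bone", "callus", "plate", "screw", "pad")
REGION_CODES <- stats::setNames(seq_along(REGION_LEVELS), REGION_LEVELS)

check_len3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stopf("'%s' must be a finite numeric vector of length 3", name)
  as.numeric(x)
}

# seeds derived from a master seed stay below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483587)
}
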