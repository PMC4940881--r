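#' @keywords internal
"_PACKAGE"

#' @importFrom stats pf phyper rnorm runif sd setNames aggregate median dist
#' @importFrom utils read.delim read.csv write.table head modifyList
NULL

STRAIN_LEVELS <- c("REF", "DEL")
COPPER_LEVELS <- c("DEFICIENT", "HIGH")

INTERACTION_TYPES <- c(
  "negative genetic", "positive genetic", "synthetic lethal",
  "synthetic growth defect", "dosage lethality", "synthetic rescue", "other"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_cf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a global seed
#'
#' Sub-generators (expression, network, regulons, qPCR) must not share an RNG
#' stream, otherwise changing one stage perturbs another. Child seeds are
#' derived deterministically from the global seed and a stage label, and kept
#' below 2^31 so they remain valid R integer seeds.
#'
#' @param seed integer global seed.
#' @param what character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
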