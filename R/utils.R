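#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad rnbinom rnorm runif rbinom quantile
#'   phyper fisher.test wilcox.test cor.test p.adjust prcomp sd var
#'   dnbinom setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

# stopifnot-style check with a formatted message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

.is_fraction <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# Evaluate expr with a private RNG stream; global .Random.seed untouched.
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# round-half-away-from-zero (base round() is banker's rounding)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# geometric mean of strictly positive values
.geomean <- function(x) exp(mean(log(x)))

# canonical chromosome naming: strip "chr" prefix, validate
.norm_chrom <- function(x) {
  out <- sub("^chr", "", as.character(x))
  out
}
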