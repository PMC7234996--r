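#' Derive a deterministic RNG substream seed
#'
#' Combines a master seed with a character key (for example a replicate
#' index or a stratum identifier) into a 31-bit seed for [set.seed()].
#' Every source of randomness in the package draws its seed through this
#' function, so adding strata or replicates never perturbs the streams of
#' existing ones, and any pipeline stage can be replayed in isolation.
#'
#' @param seed integer master seed.
#' @param key character scalar naming the substream.
#' @return An integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @examples
#' substream_seed(1, "stratum:[10,20)")
#' @export
substream_seed <- function(seed, key) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  h <- 0
  for (cp in utf8ToInt(as.character(key)))
    h <- (h * 31 + cp) %% 2147483647
  # 48271: minimal-standard multiplier; keeps everything inside 2^53
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

# shared stopper producing consistent error style
.fail <- function(...) stop(..., call. = FALSE)

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# format a double so that read.tree() round-trips it exactly
.fmt_exact <- function(x) sprintf("%.17g", x)
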