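#' Derive a reproducible child seed from a master seed and integer ids
#'
#' Hierarchical seeding: every landscape / scenario / replicate run gets its
#' own seed computed as a polynomial hash of the master seed and its ids,
#' modulo 2^31 - 1. Any single run can therefore be reproduced in isolation,
#' with no shared-stream coupling between runs.
#'
#' @param master Master integer seed.
#' @param ... Further non-negative integer ids (landscape, scenario,
#'   replicate, arm, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    # 48271 and 69621 are classic Lehmer multipliers; arithmetic stays exact
    # in doubles because all intermediates are < 2^53
    h <- (h * 48271 + (as.numeric(k) + 1) * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# wrap coordinates into [0, 1)
wrap01 <- function(x) x %% 1

# quantile with the package-wide convention (linear interpolation between
# order statistics, R's type 7), shared with the order-statistic oracles
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
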