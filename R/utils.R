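#' Derive a reproducible child seed for a cultivar/stage group
#'
#' Child seeds are derived from one master seed by a small stable string
#' hash so that per-group computations are reproducible and distinct
#' without sharing RNG streams. The hash is plain integer arithmetic on
#' UTF-8 code points, so it is identical across platforms, and the result
#' always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the group (e.g. cultivar, stage).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' groupSeed(42, "CS", "FLW")
#' @export
groupSeed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(c(as.character(as.integer(master)), ...), collapse = "/")
  h <- as.double(abs(as.integer(master)) %% 2147483647)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All seeded operations in the package go
## through this, which is what makes identical seeds give identical output.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

#' Convert a target Spearman correlation to the bivariate-normal Pearson
#' correlation that induces it
#'
#' For a bivariate normal with Pearson correlation `rho`, the population
#' Spearman correlation is `(6 / pi) * asin(rho / 2)`. The generator plants
#' correlations on the latent Gaussian (log) scale, so target Spearman
#' values are mapped through the inverse relation
#' `rho = 2 * sin(pi * rs / 6)`.
#'
#' @param rs target Spearman correlation(s) in (-1, 1).
#' @return Pearson correlation(s) of the latent Gaussian pair.
#' @examples
#' spearmanToPearson(0.95)
#' @export
spearmanToPearson <- function(rs) {
  stopifnot(all(abs(rs) < 1))
  2 * sin(pi * rs / 6)
}

## Inverse of spearmanToPearson (used in tests and docs).
pearsonToSpearman <- function(rho) (6 / pi) * asin(rho / 2)

## Encode unordered node pairs (given as character node ids within a fixed
## universe) as integers for fast set operations on edge lists.
encodePairs <- function(a, b, universe) {
  ia <- match(a, universe)
  ib <- match(b, universe)
  if (anyNA(ia) || anyNA(ib)) {
    stop("edge endpoint not found in the node universe")
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  (lo - 1) * length(universe) + hi
}

`%||%` <- function(x, y) if (is.null(x)) y else x
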