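# Internal helpers shared across modules.

# The 20 standard amino acids in AAindex I-line order
# (A R N D C Q E G H I / L K M F P S T W Y V).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Three-letter names in the same order, used by reporting functions.
AA20_NAMES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                "Thr", "Trp", "Tyr", "Val")

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions do not disturb user code.
# seed = NULL means "use the current stream as-is".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

#' Deterministic stratified fold assignment
#'
#' Assigns each observation to one of `k` cross-validation folds, keeping the
#' class proportions of `labels` as equal as possible across folds. The
#' assignment is a pure function of `(labels, k, seed)`: repeated calls give
#' identical folds, and the caller's RNG stream is left untouched. When
#' `k == length(labels)` the assignment degenerates to leave-one-out and no
#' stratification is attempted.
#'
#' @param labels class label per observation (any vector; grouped by value).
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, one per observation.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of observations")
  if (k == n) return(seq_len(n))
  folds <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(as.character(labels) == cl)
      if (length(idx) < k) {
        stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                     cl, length(idx), k))
      }
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Two-level orthogonal array
#'
#' Builds a two-level orthogonal array with `n_factors` balanced, mutually
#' orthogonal columns using the Walsh (parity) construction: with
#' `k = ceiling(log2(n_factors + 1))` the array has `2^k` runs, and column
#' `j` of run `i` is `1 + parity(popcount(bitwAnd(i, j)))`. For
#' `n_factors = 7` this is the classic L8 design used by the
#' orthogonal-array crossover operator.
#'
#' @param n_factors number of factor columns (1--31 supported).
#' @return integer matrix of levels in \{1, 2\} with `2^k` rows and
#'   `n_factors` columns. The first row is all level 1.
#' @export
oa_two_level <- function(n_factors) {
  if (n_factors < 1) stop("n_factors must be at least 1")
  if (n_factors > 31) {
    stop("orthogonal arrays with more than 31 factors are not supported")
  }
  k <- ceiling(log2(n_factors + 1))
  n_runs <- 2L^k
  parity <- function(x) {
    p <- 0L
    while (x > 0L) {
      p <- bitwXor(p, bitwAnd(x, 1L))
      x <- bitwShiftR(x, 1L)
    }
    p
  }
  oa <- matrix(0L, nrow = n_runs, ncol = n_factors)
  for (i in seq_len(n_runs)) {
    for (j in seq_len(n_factors)) {
      oa[i, j] <- 1L + parity(bitwAnd(i - 1L, j))
    }
  }
  oa
}

# Canonical label factor: positive class "high" first.
as_affinity_factor <- function(labels) {
  x <- as.character(labels)
  bad <- setdiff(unique(x[!is.na(x)]), c("high", "low"))
  if (length(bad) > 0 || anyNA(x)) {
    stop("labels must be 'high' or 'low' with no missing values")
  }
  factor(x, levels = c("high", "low"))
}

# stop() with sprintf-style formatting, without call noise.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
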