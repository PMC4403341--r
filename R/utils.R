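#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are pure functions of
#' their seed argument and never perturb ambient randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a seed and a stage name
#'
#' One global seed fans out to per-stage seeds by hashing the stage name, so
#' no pipeline stage consumes ambient randomness and inserting a stage never
#' shifts the random stream of another.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' stage_seed(1, "catalog")
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 40503 + h) %% 2147483647)
}

#' Format a count fraction as a percentage
#'
#' Reports `100 * k / n` rounded to `digits` decimal places, the convention
#' used for headline fractions such as the share of enhancers assigned to
#' genes or the share of foreground regions predicted as direct targets.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits decimal places (0 = nearest integer percent, the default).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(1404, 20122)      # 7
#' percent_of(2437, 6669, 1)    # 36.5
percent_of <- function(k, n, digits = 0) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0, k >= 0)
  round(100 * k / n, digits)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Standard Hubert-Arabie adjusted Rand index; used to compare recovered
#' sample clusters with planted state labels.
#'
#' @param a,b labelings of equal length.
#' @return numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' MD5 checksum of one or more files
#' @param paths file paths.
#' @return named character vector of checksums.
#' @keywords internal
file_checksums <- function(paths) {
  md5 <- tools::md5sum(paths)
  names(md5) <- basename(paths)
  md5
}
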