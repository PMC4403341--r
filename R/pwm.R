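## Position weight matrices: construction, MEME-minimal I/O, consensus and
## instance sampling. Probabilities are stored as a 4 x L matrix with rows
## A, C, G, T; a smoothing pseudo-weight keeps all entries positive.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x L numeric matrix of per-position base probabilities, rows
#'   in A, C, G, T order (columns summing to 1; a matrix of counts is
#'   normalized). Matrices given as L x 4 are transposed automatically.
#' @param name feature name.
#' @param pseudo smoothing weight mixed in as `(1 - pseudo) p + pseudo / 4`
#'   so probabilities stay positive (default 0.001).
#' @return a `PWM` object.
#' @export
pwm <- function(mat, name = "pwm", pseudo = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stop("PWM length must be >= 4")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  mat <- sweep(mat, 2L, colSums(mat), "/")
  mat <- (1 - pseudo) * mat + pseudo / 4
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  rownames(mat) <- DNA
  structure(list(name = name, mat = mat, pseudo = pseudo), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s' (length %d), consensus %s\n", x$name, ncol(x$mat),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence (most probable base per position)
#' @param x a `PWM`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA[apply(x$mat, 2L, which.max)], collapse = "")
}

#' Sample a motif instance from a PWM
#' @param x a `PWM`.
#' @param n number of instances.
#' @return character vector of length `n` (uses the current RNG stream).
#' @export
pwm_sample <- function(x, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(apply(x$mat, 2L, function(p) sample(DNA, 1L, prob = p)),
          collapse = "")
  }, character(1))
}

#' Read / write PWMs in MEME minimal motif format
#'
#' Supports the `MEME version` header, `ALPHABET= ACGT`, optional
#' `Background letter frequencies` line and `MOTIF` blocks with
#' `letter-probability matrix` sections.
#'
#' @param path file path.
#' @return `read_meme` returns a named list of `PWM` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s+", lines[i])) {
      name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
        j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
      motifs[[name]] <- pwm(t(mat), name = name)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  motifs
}

#' @rdname read_meme
#' @param pwms list of `PWM` objects to write.
#' @export
write_meme <- function(pwms, path) {
  if (is(pwms, "PWM")) pwms <- list(pwms)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$mat)), con)
    for (j in seq_len(ncol(p$mat)))
      writeLines(paste(sprintf("%.6f", p$mat[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Random decoy PWM
#'
#' Draws per-position base probabilities from a symmetric Dirichlet; used to
#' build decoy motif collections for calibration of enrichment scores.
#'
#' @param length motif length.
#' @param name feature name.
#' @param concentration Dirichlet concentration (small = informative).
#' @return a `PWM` (uses the current RNG stream).
#' @export
pwm_random <- function(length = 8L, name = "decoy", concentration = 0.5) {
  g <- matrix(stats::rgamma(4L * length, shape = concentration), nrow = 4L)
  pwm(g, name = name)
}
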