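## Differential activity of regions and genes between two cell states.
##
## Counts (H3K27ac / FAIRE coverage over catalog regions, or RNA-seq gene
## counts) are normalized with median-of-ratios size factors and tested
## per row with a negative-binomial Wald test using a moment dispersion
## estimate shrunk towards the matrix-wide mean. State signatures apply the
## |log2FC| >= 1 and adjusted p <= 0.05 cutoffs; state-specific region sets
## add a pooled binomial support filter standing in for an external
## differential peak caller.

#' Construct a count matrix with a two-state design
#'
#' @param counts integer matrix, rows = region or gene IDs, columns = samples.
#' @param design named character/factor: state label per sample (names must
#'   match `colnames(counts)`), exactly two levels for differential ops.
#' @return a `CountMatrix` (list with `counts`, `design`).
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be complete and non-negative")
  if (is.null(names(design))) names(design) <- colnames(counts)
  if (!all(colnames(counts) %in% names(design)))
    stop("every sample column needs a state label in 'design'")
  design <- design[colnames(counts)]
  ## an explicit factor keeps its level order (it fixes the contrast
  ## orientation); character input gets appearance order
  design <- if (is.factor(design)) droplevels(design)
            else factor(as.character(design),
                        levels = unique(as.character(design)))
  names(design) <- colnames(counts)
  structure(list(counts = counts, design = design), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$design), table(x$design)),
                    collapse = ", ")))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (is(x, "CountMatrix")) return(x)
  stop("expected a CountMatrix; see count_matrix()")
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factor: the median, over rows with a positive geometric
#' mean, of the ratio of the sample's count to the row geometric mean.
#' Multiplying all counts of one sample by c multiplies its factor by c.
#'
#' @param counts `CountMatrix` or count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (is(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (any(colSums(m) == 0)) stop("all-zero sample column")
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no row with all-positive counts; cannot estimate size factors")
  sf <- apply(m[use, , drop = FALSE], 2L,
              function(cnt) exp(median(log(cnt) - loggeo[use])))
  sf
}

#' Log2 transform of normalized counts
#'
#' `log2(count / factor + pseudocount)`; monotone in counts.
#'
#' @param counts `CountMatrix` or matrix.
#' @param factors size factors (default computed with [size_factors()]).
#' @param pseudocount added before the log (default 1, so count 0 maps to 0).
#' @return real-valued matrix of the same shape.
#' @export
log_transform <- function(counts, factors = NULL, pseudocount = 1) {
  m <- if (is(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(m)
  stopifnot(length(factors) == ncol(m), all(factors > 0))
  log2(sweep(m, 2L, factors, "/") + pseudocount)
}

#' Negative-binomial Wald test per row between two states
#'
#' A documented stand-in for an external NB differential caller, keeping the
#' pipeline self-contained: counts are normalized by median-of-ratios size
#' factors; per-row dispersion is estimated by the method of moments within
#' groups (Var = mu + alpha mu^2), pooled with degrees-of-freedom weights and
#' shrunk towards the matrix-wide mean dispersion; the log2 fold change uses
#' shrunken group means (normalized mean + 0.5) so it is always finite; the
#' Wald statistic is referred to a t distribution with moderated degrees of
#' freedom 2(n - 2), crediting the information the cross-row dispersion
#' shrinkage adds to the variance estimate; p-values are BH-adjusted across
#' rows. When a group has a single
#' sample its within-group variance is inestimable and the dispersion comes
#' from the other group plus shrinkage (small-sample mode). Rows that are
#' all-zero get p = 1 and log2fc = 0. Results from an external caller can be
#' substituted anywhere a result table is consumed downstream.
#'
#' @param counts `CountMatrix` (two design levels; log2fc is state B over
#'   state A where A is the first design level).
#' @param shrink weight of the matrix-wide mean dispersion in the per-row
#'   estimate (default 0.5).
#' @param min_disp dispersion floor (default 1e-8).
#' @return data.frame: `id`, `baseMean`, `log2fc`, `pvalue`, `padj`.
#' @export
nb_differential <- function(counts, shrink = 0.5, min_disp = 1e-8) {
  cm <- as_count_matrix(counts)
  lev <- levels(cm$design)
  if (length(lev) != 2L) stop("design must have exactly two states")
  a <- cm$design == lev[1]; b <- cm$design == lev[2]
  nA <- sum(a); nB <- sum(b)
  if (nA < 1L || nB < 1L) stop("each state needs at least one sample")
  q <- sweep(cm$counts, 2L, size_factors(cm), "/")
  muA <- rowMeans(q[, a, drop = FALSE]); muB <- rowMeans(q[, b, drop = FALSE])
  vA <- if (nA > 1L) apply(q[, a, drop = FALSE], 1L, var) else rep(NA_real_, nrow(q))
  vB <- if (nB > 1L) apply(q[, b, drop = FALSE], 1L, var) else rep(NA_real_, nrow(q))
  mom <- function(v, mu) ifelse(is.na(v) | mu <= 0, NA_real_,
                                pmax((v - mu) / mu^2, 0))
  aA <- mom(vA, muA); aB <- mom(vB, muB)
  wA <- max(nA - 1L, 0L); wB <- max(nB - 1L, 0L)
  num <- ifelse(is.na(aA), 0, wA * aA) + ifelse(is.na(aB), 0, wB * aB)
  den <- ifelse(is.na(aA), 0, wA) + ifelse(is.na(aB), 0, wB)
  disp_row <- ifelse(den > 0, num / den, NA_real_)
  disp_mean <- mean(disp_row, na.rm = TRUE)
  if (!is.finite(disp_mean)) disp_mean <- 0.1
  disp <- pmax((1 - shrink) * ifelse(is.na(disp_row), disp_mean, disp_row) +
                 shrink * disp_mean, min_disp)
  lfc <- log2((muB + 0.5) / (muA + 0.5))
  ## delta-method variance of log(mu-hat) per group: (1/n) (1/mu + alpha)
  se2 <- (1 / nA) * (1 / (muA + 0.5) + disp) + (1 / nB) * (1 / (muB + 0.5) + disp)
  se <- sqrt(se2) / log(2)
  stat <- lfc / se
  ## moderated degrees of freedom: the shrinkage towards the matrix-wide
  ## dispersion roughly doubles the information in the variance estimate
  df <- 2L * max(nA + nB - 2L, 1L)
  p <- 2 * pt(-abs(stat), df = df)
  zero <- muA + muB == 0
  p[zero] <- 1; lfc[zero] <- 0
  data.frame(id = rownames(cm$counts),
             baseMean = rowMeans(q),
             log2fc = lfc,
             pvalue = p,
             padj = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Define the two state gene signatures
#'
#' Membership iff `|log2fc| >= lfc_min` and `padj <= padj_max` (defaults 1 and
#' 0.05); the sign of the fold change assigns the state. The two signatures
#' are disjoint by construction.
#'
#' @param results data.frame from [nb_differential()].
#' @param lfc_min,padj_max thresholds.
#' @param states labels for the (down, up) sides of the contrast; defaults
#'   `c("A", "B")` meaning negative log2fc genes belong to the first state.
#' @return named list of two character vectors of IDs, plus a `thresholds`
#'   attribute.
#' @export
define_signature <- function(results, lfc_min = 1, padj_max = 0.05,
                             states = c("A", "B")) {
  stopifnot(all(c("id", "log2fc", "padj") %in% names(results)))
  pass <- abs(results$log2fc) >= lfc_min & results$padj <= padj_max &
    !is.na(results$padj)
  sig <- list(results$id[pass & results$log2fc < 0],
              results$id[pass & results$log2fc > 0])
  names(sig) <- states
  attr(sig, "thresholds") <- list(lfc_min = lfc_min, padj_max = padj_max)
  sig
}

#' Two-stage state-specific differential region calling
#'
#' Stage 1 is the NB Wald test at `padj <= padj_max` and `|log2fc| >=
#' lfc_min` (defaults 0.05 and 1). Stage 2 is a support filter standing in
#' for an external differential peak caller: per region, counts are
#' size-factor normalized and pooled within each state, and a binomial test
#' asks whether the pooled split deviates from the sample-size proportion;
#' regions need BH `q <= support_q` with the deviation concordant with the
#' stage-1 fold-change direction. `support_q >= 1` disables the support
#' filter, so the output reduces exactly to stage 1. The final sets are the
#' intersection of the two stages, split by direction.
#'
#' @param counts region `CountMatrix`.
#' @param padj_max,lfc_min stage-1 thresholds.
#' @param support_q stage-2 BH threshold (default 0.05).
#' @return list with per-state region ID vectors (`down` = first design
#'   level, `up` = second) and the full annotated `table`.
#' @export
differential_regions <- function(counts, padj_max = 0.05, lfc_min = 1,
                                 support_q = 0.05) {
  cm <- as_count_matrix(counts)
  res <- nb_differential(cm)
  stage1 <- !is.na(res$padj) & res$padj <= padj_max & abs(res$log2fc) >= lfc_min
  lev <- levels(cm$design)
  a <- cm$design == lev[1]; b <- cm$design == lev[2]
  q <- sweep(cm$counts, 2L, size_factors(cm), "/")
  kA <- round(rowSums(q[, a, drop = FALSE]))
  kB <- round(rowSums(q[, b, drop = FALSE]))
  n <- kA + kB
  p0 <- sum(b) / length(cm$design)
  pbin <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(kB[i], n[i], p = p0)$p.value
  }, numeric(1))
  qbin <- p.adjust(pbin, method = "BH")
  concord <- sign(kB / max(sum(b), 1) - kA / max(sum(a), 1)) ==
    sign(res$log2fc) | res$log2fc == 0
  stage2 <- if (support_q >= 1) rep(TRUE, nrow(res)) else
    (!is.na(qbin) & qbin <= support_q & concord)
  pass <- stage1 & stage2
  tab <- cbind(res, support_p = pbin, support_q = qbin,
               stage1 = stage1, stage2 = stage2, pass = pass)
  out <- list(res$id[pass & res$log2fc < 0], res$id[pass & res$log2fc > 0])
  names(out) <- lev
  out$table <- tab
  out
}

#' Per-region differential methylation from CpG beta values
#'
#' Per-CpG Welch t-tests between the two states flag significant probes at
#' `cpg_alpha` (default 1e-10). Regions covered by at least two CpG probes
#' are summarized by their per-sample median beta value, and a two-sample
#' t-test on those medians defines differentially methylated regions at
#' `region_alpha` (default 0.05). Regions with fewer than two probes are
#' excluded and reported.
#'
#' @param beta matrix of beta values in `[0, 1]`, rows = CpG probes.
#' @param design named two-level state factor over the columns.
#' @param region_map named character: region ID per CpG probe (subset of
#'   `rownames(beta)`).
#' @param cpg_alpha,region_alpha significance thresholds.
#' @return list with `cpg` (per-probe table), `regions` (per-region table
#'   with `significant` flag), `excluded` (region IDs with < 2 probes).
#' @export
methylation_region_stats <- function(beta, design, region_map,
                                     cpg_alpha = 1e-10, region_alpha = 0.05) {
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values must be in [0, 1]")
  design <- design[colnames(beta)]
  design <- if (is.factor(design)) droplevels(design)
            else factor(as.character(design),
                        levels = unique(as.character(design)))
  if (nlevels(design) != 2L) stop("design must have exactly two states")
  a <- design == levels(design)[1]; b <- design == levels(design)[2]
  welch <- function(x) {
    if (sd(x[a]) == 0 && sd(x[b]) == 0) {
      d <- mean(x[b]) - mean(x[a])
      return(c(diff = d, p = if (d == 0) 1 else 0))
    }
    tt <- t.test(x[b], x[a])
    c(diff = unname(tt$estimate[1] - tt$estimate[2]), p = tt$p.value)
  }
  cpg_stats <- t(apply(beta, 1L, welch))
  cpg <- data.frame(probe = rownames(beta), delta_beta = cpg_stats[, 1],
                    pvalue = cpg_stats[, 2],
                    significant = cpg_stats[, 2] <= cpg_alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  map <- region_map[rownames(beta)]
  map <- map[!is.na(map)]
  tabs <- split(names(map), map)
  n_probes <- lengths(tabs)
  excluded <- names(tabs)[n_probes < 2L]
  keep <- names(tabs)[n_probes >= 2L]
  regions <- do.call(rbind, lapply(keep, function(rid) {
    med <- apply(beta[tabs[[rid]], , drop = FALSE], 2L, median)
    tt <- t.test(med[b], med[a])
    data.frame(region_id = rid, n_probes = length(tabs[[rid]]),
               delta_beta = unname(tt$estimate[1] - tt$estimate[2]),
               pvalue = tt$p.value, stringsAsFactors = FALSE)
  }))
  if (is.null(regions))
    regions <- data.frame(region_id = character(), n_probes = integer(),
                          delta_beta = numeric(), pvalue = numeric())
  regions$significant <- regions$pvalue <= region_alpha
  list(cpg = cpg, regions = regions, excluded = excluded)
}
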