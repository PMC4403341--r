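## Ranking-and-recovery feature discovery over the region catalog.
##
## Every motif or track induces one complete ranking of the M catalog
## regions. A foreground region set (e.g. the regions activated in one cell
## state) is scored against each ranking by the area under its cumulative
## recovery curve over the top 0.25% of ranks; AUCs are normalized across
## the feature collection into NES values, significance comes from the
## hypergeometric tail, and the foreground regions inside the cutoff are the
## feature's candidate direct-target regions.

#' Best-site log-odds PWM score per region sequence
#'
#' Scores each sequence with the maximum, over all windows and both strands,
#' of the summed per-position `log2(p(base) / q(base))` log-odds. `N` bases
#' contribute the background expectation of the position's log-odds.
#' Sequences shorter than the PWM (including empty ones) get `-Inf`.
#'
#' @param sequences character vector or `DNAStringSet` (names = region IDs).
#' @param x a [pwm()] object.
#' @param background length-4 base frequencies (A, C, G, T), default uniform.
#' @return named numeric vector of scores.
#' @export
scan_pwm <- function(sequences, x, background = rep(0.25, 4)) {
  stopifnot(is(x, "PWM"), length(background) == 4L,
            abs(sum(background) - 1) < 1e-6, all(background > 0))
  seqs <- as.character(sequences)
  lom <- log2(sweep(x$mat, 1L, background, "/"))
  nrow_lom <- rbind(lom, N = colSums(background * lom))
  ## reverse complement: reverse columns, swap A<->T and C<->G rows
  rc <- lom[c(4, 3, 2, 1), rev(seq_len(ncol(lom))), drop = FALSE]
  rc <- rbind(rc, N = colSums(background * rc))
  out <- scan_pwm_cpp(seqs, nrow_lom, rc)
  names(out) <- names(sequences)
  out
}

#' Rank all catalog regions by a score vector
#'
#' Descending score; ties are broken by a seeded uniform shuffle (the seed is
#' recorded on the result) so that the ranking is a complete, reproducible
#' permutation.
#'
#' @param scores named numeric vector, one score per catalog region.
#' @param feature feature name.
#' @param kind `"motif"` or `"track"`.
#' @param tie_seed integer seed for tie-breaking.
#' @return a `FeatureRanking`: list with `feature`, `kind`, `ranks` (named
#'   integer vector, rank 1 = best), `scores`, `tie_seed`.
#' @export
rank_regions <- function(scores, feature = "feature", kind = "motif",
                         tie_seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by region ID")
  if (anyDuplicated(names(scores))) stop("duplicated region IDs in scores")
  ord <- with_seed(tie_seed, {
    jitter <- sample.int(length(scores))
    order(-scores, jitter)
  })
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- names(scores)
  structure(list(feature = feature, kind = kind, ranks = ranks,
                 scores = scores, tie_seed = tie_seed),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat(sprintf("FeatureRanking '%s' (%s) over %d regions\n", x$feature,
              x$kind, length(x$ranks)))
  invisible(x)
}

#' Rank catalog regions by the maximum overlapping peak score
#'
#' Region score = maximum score of the peaks overlapping it (1-bp overlap
#' counts), 0 for regions with no overlapping peak; then ranked with
#' [rank_regions()].
#'
#' @param peaks `GRanges` with a numeric `score` column (>= 0).
#' @param catalog `RegionCatalog` or named `GRanges`.
#' @param feature,tie_seed passed to [rank_regions()].
#' @return a `FeatureRanking` of kind `"track"`.
#' @export
track_ranking <- function(peaks, catalog, feature = "track", tie_seed = 1L) {
  gr <- if (is(catalog, "RegionCatalog")) catalog$regions else catalog
  if (is.null(names(gr))) names(gr) <- region_ids(gr)
  sc <- mcols(peaks)$score
  if (is.null(sc)) stop("peaks need a 'score' column")
  if (any(sc < 0)) stop("peak scores must be >= 0")
  region_score <- setNames(rep(0, length(gr)), names(gr))
  hits <- findOverlaps(gr, peaks, minoverlap = 1L)
  if (length(hits)) {
    mx <- tapply(sc[subjectHits(hits)], queryHits(hits), max)
    region_score[as.integer(names(mx))] <- as.numeric(mx)
  }
  rank_regions(region_score, feature = feature, kind = "track",
               tie_seed = tie_seed)
}

#' Order-statistics Q for combining rank ratios
#'
#' Joint cumulative probability that N independent uniforms have order
#' statistics below the observed rank ratios: with sorted ratios
#' `s_1 <= ... <= s_N`, `Q = N! V_N` where `V_0 = 1` and
#' `V_k = sum_{i=1..k} (-1)^(i-1) (V_{k-i} / i!) s_{N-k+1}^i`.
#' Used to merge rankings across score sources (species projections,
#' datasets): regions/genes are re-ranked by ascending Q.
#'
#' @param ratios numeric vector (or matrix, rows = items) of rank/M ratios in
#'   `(0, 1]`.
#' @return numeric Q (or vector of Qs for a matrix input).
#' @export
#' @examples
#' combine_rankings_orderstat(c(0.1, 0.2))  # 0.03
combine_rankings_orderstat <- function(ratios) {
  if (is.matrix(ratios))
    return(apply(ratios, 1L, combine_rankings_orderstat))
  if (any(ratios <= 0 | ratios > 1)) stop("rank ratios must be in (0, 1]")
  s <- sort(ratios)
  n <- length(s)
  v <- numeric(n + 1L)
  v[1L] <- 1
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[k + 1L] <- sum((-1)^(i - 1) * v[k - i + 1L] / factorial(i) *
                       s[n - k + 1L]^i)
  }
  factorial(n) * v[n + 1L]
}

#' Recovery-curve AUC of a foreground set against a ranking
#'
#' With `T = ceiling(cutoff_frac * M)` (default cutoff 0.25% of the
#' catalog), `recovery(x)` is the fraction of the foreground found at rank
#' `<= x`; the AUC is the mean of `recovery(x)` for `x = 1..T`, in `[0, 1]`.
#'
#' @param ranking a `FeatureRanking`.
#' @param foreground character vector of region IDs (non-empty, subset of
#'   the catalog).
#' @param cutoff_frac top fraction of ranks considered (default 0.0025).
#' @return numeric AUC.
#' @export
recovery_auc <- function(ranking, foreground, cutoff_frac = 0.0025) {
  stopifnot(is(ranking, "FeatureRanking"))
  if (length(foreground) == 0L) stop("foreground must be non-empty")
  if (!all(foreground %in% names(ranking$ranks)))
    stop("foreground contains IDs missing from the catalog ranking")
  M <- length(ranking$ranks)
  T_ <- as.integer(ceiling(cutoff_frac * M))
  r <- sort(ranking$ranks[foreground])
  r <- r[r <= T_]
  if (length(r) == 0L) return(0)
  ## sum over x=1..T of |{f: rank(f) <= x}| equals sum over hits of (T - rank + 1)
  sum(T_ - r + 1) / (length(foreground) * T_)
}

#' Normalized enrichment scores for a feature collection
#'
#' `NES_f = (AUC_f - mean(AUC)) / sd(AUC)` across all features scored
#' against the same foreground. Population standard deviation by default
#' (configurable).
#'
#' @param aucs named numeric vector of per-feature AUCs (>= 3 features).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return named numeric vector of NES values.
#' @export
nes_scores <- function(aucs, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(aucs) < 3L) stop("need at least 3 features to normalize")
  mu <- mean(aucs)
  sdev <- if (sd_type == "population")
    sqrt(mean((aucs - mu)^2)) else sd(aucs)
  if (sdev == 0) stop("degenerate feature collection: sd of AUCs is 0")
  (aucs - mu) / sdev
}

#' Hypergeometric enrichment of a foreground within the ranking cutoff
#'
#' `p = P(X >= k)` with `X ~ Hypergeom(M, |F|, T)` and `k` the number of
#' foreground regions within the top `T` ranks; Bonferroni adjustment across
#' the feature collection.
#'
#' @inheritParams recovery_auc
#' @param n_features collection size for the Bonferroni correction.
#' @return list with `k`, `pvalue`, `padj`.
#' @export
hypergeom_enrichment <- function(ranking, foreground, cutoff_frac = 0.0025,
                                 n_features = 1L) {
  stopifnot(is(ranking, "FeatureRanking"))
  M <- length(ranking$ranks)
  T_ <- as.integer(ceiling(cutoff_frac * M))
  k <- sum(ranking$ranks[foreground] <= T_)
  p <- phyper(k - 1, length(foreground), M - length(foreground), T_,
              lower.tail = FALSE)
  list(k = k, pvalue = p, padj = min(1, p * n_features))
}

#' Candidate direct-target regions of an enriched feature
#'
#' The foreground regions ranked within the recovery cutoff, ordered by rank.
#'
#' @inheritParams recovery_auc
#' @return character vector of region IDs.
#' @export
leading_targets <- function(ranking, foreground, cutoff_frac = 0.0025) {
  stopifnot(is(ranking, "FeatureRanking"))
  M <- length(ranking$ranks)
  T_ <- as.integer(ceiling(cutoff_frac * M))
  r <- ranking$ranks[foreground]
  names(sort(r[r <= T_]))
}

#' Intersect motif- and track-supported target regions
#'
#' The "optimal" direct-target set: regions supported by both the motif and
#' a ChIP track, ordered by the motif rank.
#'
#' @param motif_targets,track_targets character vectors of region IDs (as
#'   returned by [leading_targets()]).
#' @param motif_ranking optional `FeatureRanking` used for ordering; the
#'   order of `motif_targets` is used when omitted.
#' @return character vector of region IDs.
#' @export
intersect_motif_track <- function(motif_targets, track_targets,
                                  motif_ranking = NULL) {
  common <- base::intersect(motif_targets, track_targets)
  if (!is.null(motif_ranking))
    common <- common[order(motif_ranking$ranks[common])]
  common
}

#' Score a foreground set against a collection of feature rankings
#'
#' Computes per-feature recovery AUC, NES across the collection,
#' hypergeometric p-value with Bonferroni adjustment, and leading target
#' regions.
#'
#' @param rankings list of `FeatureRanking` objects.
#' @param foreground character vector of region IDs.
#' @param cutoff_frac recovery cutoff (default 0.0025).
#' @param sd_type NES standardization, see [nes_scores()].
#' @return list with `results` (data.frame: feature, kind, auc, nes, k,
#'   pvalue, padj, n_targets, sorted by descending NES, ties by name) and
#'   `targets` (named list of leading-target ID vectors).
#' @export
enrich_features <- function(rankings, foreground, cutoff_frac = 0.0025,
                            sd_type = "population") {
  stopifnot(length(rankings) >= 3L)
  nm <- vapply(rankings, function(r) r$feature, character(1))
  if (anyDuplicated(nm)) stop("duplicated feature names")
  names(rankings) <- nm
  aucs <- vapply(rankings, recovery_auc, numeric(1),
                 foreground = foreground, cutoff_frac = cutoff_frac)
  nes <- nes_scores(aucs, sd_type = sd_type)
  hyp <- lapply(rankings, hypergeom_enrichment, foreground = foreground,
                cutoff_frac = cutoff_frac, n_features = length(rankings))
  targets <- lapply(rankings, leading_targets, foreground = foreground,
                    cutoff_frac = cutoff_frac)
  res <- data.frame(
    feature = nm,
    kind = vapply(rankings, function(r) r$kind, character(1)),
    auc = unname(aucs), nes = unname(nes),
    k = vapply(hyp, function(h) h$k, numeric(1)),
    pvalue = vapply(hyp, function(h) h$pvalue, numeric(1)),
    padj = vapply(hyp, function(h) h$padj, numeric(1)),
    n_targets = lengths(targets),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$nes, res$feature), ]
  rownames(res) <- NULL
  list(results = res, targets = targets)
}
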