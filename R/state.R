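## Expression-state classification.
##
## Tumour or culture expression profiles are clustered into k states with
## non-negative matrix factorization on the high-variance genes, each
## cluster is contrasted against the rest to produce a signed
## -log10(adjusted p) gene ranking, and rankings from several datasets are
## merged with the order-statistics Q into a meta-ranking per state.

#' Filter genes by expression standard deviation
#'
#' Keeps genes whose across-sample standard deviation is strictly above
#' `sd_min` (default 1), the variance filter applied before NMF.
#'
#' @param expr_matrix genes x samples real-valued matrix.
#' @param sd_min threshold (strict inequality).
#' @return the filtered matrix.
#' @export
sd_filter <- function(expr_matrix, sd_min = 1) {
  if (ncol(expr_matrix) < 2L) stop("need >= 2 samples")
  sds <- apply(expr_matrix, 1L, sd)
  expr_matrix[sds > sd_min, , drop = FALSE]
}

nmf_lee_seung <- function(V, k, seed, max_iter, tol) {
  eps <- 1e-12
  with_seed(seed, {
    W <- matrix(runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(runif(k * ncol(V), 0.1, 1), k, ncol(V))
    errs <- numeric(0)
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      errs <- c(errs, err)
      if (is.finite(err_prev) &&
          (err_prev - err) / max(err_prev, eps) < tol) break
      err_prev <- err
    }
    list(W = W, H = H, error = err, trace = errs, n_iter = length(errs))
  })
}

#' NMF clustering of expression samples
#'
#' Frobenius-objective NMF by multiplicative updates, best of `n_restarts`
#' seeded runs; each sample is assigned to the basis component with the
#' largest coefficient in `H`. The input must be non-negative (e.g.
#' [log_transform()] output).
#'
#' @param expr_matrix non-negative genes x samples matrix (typically
#'   [sd_filter()]ed).
#' @param k factorization rank / cluster count (default 3: two
#'   transcriptional states plus an immune-like group).
#' @param seed RNG seed (restart r uses `seed + r - 1`).
#' @param n_restarts random restarts (default 10).
#' @param max_iter update cap per run (default 2000).
#' @param tol relative reconstruction-error change for convergence
#'   (default 1e-6).
#' @return an `NMFModel`: list with `W`, `H`, `k`, `cluster` (named integer
#'   vector), `error`, `trace`, `n_iter`, `seed`.
#' @export
nmf_cluster <- function(expr_matrix, k = 3L, seed = 1L, n_restarts = 10L,
                        max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(expr_matrix)
  if (any(V < 0)) stop("NMF input must be non-negative")
  if (k < 1L || k > ncol(V)) stop("invalid rank k")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_lee_seung(V, k, seed = seed + r - 1L, max_iter, tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  cl <- apply(best$H, 2L, which.max)
  names(cl) <- colnames(V)
  structure(list(W = best$W, H = best$H, k = k, cluster = cl,
                 error = best$error, trace = best$trace,
                 n_iter = best$n_iter, seed = seed),
            class = "NMFModel")
}

#' @export
print.NMFModel <- function(x, ...) {
  cat(sprintf("NMFModel: k = %d, %d iterations, error %.4g; clusters: %s\n",
              x$k, x$n_iter, x$error,
              paste(table(x$cluster), collapse = "/")))
  invisible(x)
}

#' Cluster-specific signed gene ranking
#'
#' Contrasts the samples of one cluster against all other samples with the
#' NB test and scores each gene by `sign(log2fc) * -log10(padj)` (p floored
#' at 1e-300), so cluster-specific upregulated genes rank on top.
#'
#' @param expr_counts `CountMatrix` of raw counts over all samples.
#' @param cluster_map named vector assigning samples to clusters.
#' @param cluster the cluster to contrast.
#' @return data.frame `gene`, `score`, `rank`, sorted by descending score.
#' @export
cluster_gene_ranking <- function(expr_counts, cluster_map, cluster) {
  cm <- as_count_matrix(expr_counts)
  memb <- cluster_map[colnames(cm$counts)]
  inside <- memb == cluster
  if (!any(inside) || all(inside))
    stop("cluster must be non-empty and not all samples")
  design <- setNames(factor(ifelse(inside, "cluster", "rest"),
                            levels = c("rest", "cluster")),
                     colnames(cm$counts))
  res <- nb_differential(count_matrix(cm$counts, design))
  score <- sign(res$log2fc) * -log10(pmax(res$padj, 1e-300))
  out <- data.frame(gene = res$id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Combine per-dataset gene rankings with order statistics
#'
#' Each dataset contributes a rank ratio `rank / n_genes` per gene over the
#' union of gene universes; genes absent from a dataset get the worst ratio
#' 1. The per-gene ratios are merged into the order-statistics Q
#' ([combine_rankings_orderstat()]) and ascending Q is the meta-ranking.
#'
#' @param rankings list (>= 2) of data.frames with `gene` and `rank`
#'   columns (as from [cluster_gene_ranking()]).
#' @return data.frame `gene`, `q`, `rank`, sorted by ascending Q.
#' @export
meta_rank <- function(rankings) {
  if (length(rankings) < 2L) stop("need >= 2 rankings")
  genes <- sort(unique(unlist(lapply(rankings, `[[`, "gene"))))
  ratios <- vapply(rankings, function(rk) {
    r <- rep(1, length(genes))
    i <- match(rk$gene, genes)
    r[i] <- rk$rank / nrow(rk)
    r
  }, numeric(length(genes)))
  q <- combine_rankings_orderstat(ratios)
  out <- data.frame(gene = genes, q = q, stringsAsFactors = FALSE)
  out <- out[order(out$q, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
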