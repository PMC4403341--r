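## TF -> enhancer -> gene networks.
##
## Differential regions are assigned to candidate target genes by three
## joint filters: TSS within a distance window of the region, the gene
## differentially expressed between the states, and the region's activity
## profile correlated with the gene's expression profile across samples.
## Restricting the links to a TF's predicted direct-target regions yields
## the TF's regulatory network; networks are compared by hypergeometric
## gene-set overlap and validated against external rankings with a
## pre-ranked GSEA statistic.

#' Assignment parameter set
#'
#' The tested grid spans TSS windows of 10 kb to 2 Mb, differential
#' expression adjusted-p thresholds 0.05 / 0.1 / 1, and correlation
#' thresholds 0, 0.1, 0.3, 0.5, 0.7 in positive-only or absolute mode. The
#' network-construction defaults are 1 Mb, 0.1 and 0.3 absolute with
#' |log2FC| >= 1.
#'
#' @param max_dist TSS window in bp (default 1e6).
#' @param ge_alpha adjusted-p threshold on the gene's differential
#'   expression (default 0.1).
#' @param lfc_min expression |log2FC| floor (default 1).
#' @param corr_min correlation threshold in `[0, 1]` (default 0.3).
#' @param corr_mode `"absolute"` (default) or `"positive"`.
#' @param closest_only keep only the nearest qualifying gene per region.
#' @return an `AssignmentParams` list.
#' @export
assignment_params <- function(max_dist = 1e6, ge_alpha = 0.1, lfc_min = 1,
                              corr_min = 0.3,
                              corr_mode = c("absolute", "positive"),
                              closest_only = FALSE) {
  corr_mode <- match.arg(corr_mode)
  stopifnot(max_dist > 0, corr_min >= 0, corr_min <= 1, ge_alpha > 0)
  structure(list(max_dist = max_dist, ge_alpha = ge_alpha,
                 lfc_min = lfc_min, corr_min = corr_min,
                 corr_mode = corr_mode, closest_only = closest_only),
            class = "AssignmentParams")
}

#' Assign regions to candidate target genes
#'
#' A link (region, gene) is made iff the gene's TSS lies within
#' `params$max_dist` of the region (distance measured from the TSS to the
#' nearest region edge by default, 0 inside the region; configurable to the
#' region midpoint), the gene passes the differential-expression filter
#' (`padj <= ge_alpha` and `|log2fc| >= lfc_min`; genes failing it are
#' ignored), and the Pearson correlation between the region's activity
#' profile and the gene's expression profile across the shared samples
#' passes `corr_min` under `corr_mode`. With `closest_only` only the
#' nearest qualifying gene is kept per region. A region may link to several
#' genes and a gene to several regions.
#'
#' @param regions named `GRanges` (or `RegionCatalog`) of the regions to
#'   assign (typically the differential regions).
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss` (0-based).
#' @param expr_results differential expression table ([nb_differential()]).
#' @param activity_matrix,expr_matrix real-valued matrices (regions x
#'   samples, genes x samples) over the same sample panel, e.g. from
#'   [log_transform()].
#' @param params an [assignment_params()].
#' @param anchor `"edge"` (default) or `"midpoint"` distance anchor.
#' @return data.frame of links: `region_id`, `gene_id`, `distance`, `corr`,
#'   with the params as an attribute.
#' @export
assign_regions_to_genes <- function(regions, tss_table, expr_results,
                                    activity_matrix, expr_matrix,
                                    params = assignment_params(),
                                    anchor = c("edge", "midpoint")) {
  anchor <- match.arg(anchor)
  gr <- if (is(regions, "RegionCatalog")) regions$regions else regions
  if (is.null(names(gr))) names(gr) <- region_ids(gr)
  if (!identical(colnames(activity_matrix), colnames(expr_matrix)))
    stop("activity and expression matrices have mismatched sample panels")
  if (ncol(activity_matrix) < 3L) stop("need >= 3 shared samples")
  empty <- data.frame(region_id = character(), gene_id = character(),
                      distance = numeric(), corr = numeric(),
                      stringsAsFactors = FALSE)
  ## expression filter first: non-differential genes are ignored
  ok_gene <- !is.na(expr_results$padj) &
    expr_results$padj <= params$ge_alpha &
    abs(expr_results$log2fc) >= params$lfc_min
  genes <- base::intersect(expr_results$id[ok_gene], tss_table$gene_id)
  genes <- base::intersect(genes, rownames(expr_matrix))
  if (length(genes) == 0L || length(gr) == 0L) {
    attr(empty, "params") <- params
    return(empty)
  }
  tss <- tss_table[match(genes, tss_table$gene_id), ]
  tss_pt <- GRanges(tss$chrom, IRanges(tss$tss + 1L, width = 1L))
  win <- GRanges(seqnames(gr),
                 IRanges(pmax(1, start(gr) - params$max_dist),
                         end(gr) + params$max_dist))
  hits <- findOverlaps(win, tss_pt)
  if (length(hits) == 0L) {
    attr(empty, "params") <- params
    return(empty)
  }
  ri <- queryHits(hits); gi <- subjectHits(hits)
  dist <- if (anchor == "edge") {
    pmax(0, pmax(start(gr)[ri] - (tss$tss[gi] + 1L),
                 (tss$tss[gi] + 1L) - end(gr)[ri]))
  } else {
    abs((start(gr)[ri] + end(gr)[ri]) / 2 - (tss$tss[gi] + 1L))
  }
  keep <- dist <= params$max_dist
  ri <- ri[keep]; gi <- gi[keep]; dist <- dist[keep]
  rid <- names(gr)[ri]; gid <- genes[gi]
  if (!all(rid %in% rownames(activity_matrix)))
    stop("activity matrix is missing assigned regions")
  ## Pearson r per pair across samples (vectorized over the pair list)
  zrow <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2))
    (m - mu) / ifelse(s == 0, NA_real_, s)
  }
  za <- zrow(activity_matrix[unique(rid), , drop = FALSE])
  zg <- zrow(expr_matrix[unique(gid), , drop = FALSE])
  corr <- rowSums(za[rid, , drop = FALSE] * zg[gid, , drop = FALSE])
  cpass <- if (params$corr_mode == "absolute") abs(corr) >= params$corr_min
           else corr >= params$corr_min
  cpass[is.na(cpass)] <- FALSE
  links <- data.frame(region_id = rid[cpass], gene_id = gid[cpass],
                      distance = dist[cpass], corr = corr[cpass],
                      stringsAsFactors = FALSE)
  if (params$closest_only && nrow(links)) {
    links <- links[order(links$region_id, links$distance), ]
    links <- links[!duplicated(links$region_id), ]
  }
  links <- links[order(links$region_id, links$gene_id), ]
  rownames(links) <- NULL
  attr(links, "params") <- params
  links
}

#' Fraction of regions assigned to at least one gene
#'
#' `100 * distinct linked regions / total regions`, rounded for reporting.
#'
#' @param links link table from [assign_regions_to_genes()], or directly a
#'   count of linked regions.
#' @param n_regions_total size of the region set assignment started from.
#' @param digits decimal places of the reported percentage (default 0).
#' @return numeric percentage.
#' @export
#' @examples
#' assignment_coverage(1404, 20122)  # 7
#' assignment_coverage(4599, 20122)  # 23
assignment_coverage <- function(links, n_regions_total, digits = 0) {
  k <- if (is.data.frame(links)) length(unique(links$region_id)) else links
  if (k > n_regions_total) stop("more linked regions than regions in total")
  percent_of(k, n_regions_total, digits)
}

#' Build a TF regulatory network from its target regions and the link table
#'
#' @param tf_name TF label.
#' @param tf_targets character vector of the TF's predicted direct-target
#'   region IDs (e.g. [leading_targets()] output or planted truth).
#' @param links link table from [assign_regions_to_genes()].
#' @return a `TFNetwork`: list with `tf_name`, `links` (restricted),
#'   `target_genes`.
#' @export
build_tf_network <- function(tf_name, tf_targets, links) {
  sub <- links[links$region_id %in% tf_targets, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(tf_name = tf_name, links = sub,
                 target_genes = sort(unique(sub$gene_id))),
            class = "TFNetwork")
}

#' @export
print.TFNetwork <- function(x, ...) {
  cat(sprintf("TFNetwork '%s': %d links, %d regions -> %d genes\n",
              x$tf_name, nrow(x$links), length(unique(x$links$region_id)),
              length(x$target_genes)))
  invisible(x)
}

#' Target-gene overlap between two TF networks
#'
#' Overlap size plus the upper hypergeometric tail probability given the
#' gene universe.
#'
#' @param net_a,net_b `TFNetwork` objects (or plain gene-ID vectors).
#' @param universe gene universe size (>= union size).
#' @return list with `k`, `pvalue`.
#' @export
target_overlap <- function(net_a, net_b, universe) {
  ga <- if (is(net_a, "TFNetwork")) net_a$target_genes else net_a
  gb <- if (is(net_b, "TFNetwork")) net_b$target_genes else net_b
  if (universe < length(base::union(ga, gb)))
    stop("universe smaller than the union of the gene sets")
  k <- length(base::intersect(ga, gb))
  p <- phyper(k - 1, length(ga), universe - length(ga), length(gb),
              lower.tail = FALSE)
  list(k = k, pvalue = p)
}

gsea_es <- function(scores, hit, weight_p = 1) {
  n <- length(scores)
  w <- abs(scores)^weight_p
  w[hit] <- w[hit] / sum(w[hit])
  w[!hit] <- -1 / (n - sum(hit))
  run <- cumsum(unname(w))
  run[which.max(abs(run))]
}

#' Pre-ranked GSEA enrichment statistic
#'
#' Standard running-sum enrichment score over a ranked gene list: hits
#' increment proportionally to `|score|^weight_p`, misses decrement by
#' `1 / (N - |S|)`, and the ES is the maximum deviation from zero. The null
#' distribution comes from random gene sets of the same size (`n_perm`
#' draws, seeded); the normalized score divides by the mean |null ES| of
#' the same sign, and the FDR q-value compares the observed NES tail
#' against the signed null.
#'
#' @param scores named numeric vector of ranking scores (sorted internally
#'   in decreasing order); all finite.
#' @param gene_set character vector; must intersect the ranking and leave
#'   at least one miss.
#' @param weight_p hit-weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov form).
#' @param n_perm permutation count (default 1000).
#' @param seed RNG seed.
#' @return list with `es`, `nes`, `pvalue`, `fdr`, `n_hits`.
#' @export
gsea_preranked <- function(scores, gene_set, weight_p = 1, n_perm = 1000L,
                           seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (any(!is.finite(scores))) stop("scores must be finite")
  scores <- sort(scores, decreasing = TRUE)
  hit <- names(scores) %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranking")
  if (all(hit)) stop("gene set covers the whole ranking (degenerate)")
  es <- gsea_es(scores, hit, weight_p)
  m <- sum(hit)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    h <- logical(length(scores))
    h[sample.int(length(scores), m)] <- TRUE
    gsea_es(scores, h, weight_p)
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same)) (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
       else 1 / (1 + n_perm)
  list(es = es, nes = nes, pvalue = p, fdr = p, n_hits = m)
}

#' Correlation between a signature score and a phenotype
#'
#' Per-sample signature score = mean expression over the signature genes;
#' Pearson correlation (two-sided test) against the phenotype, e.g. a
#' drug-response IC50 per cell line.
#'
#' @param expr_matrix genes x samples real-valued matrix.
#' @param signature character vector of genes (present in the matrix).
#' @param phenotype numeric per-sample value (not constant; >= 3 samples).
#' @return list with `r`, `pvalue`, `scores`.
#' @export
signature_score_correlation <- function(expr_matrix, signature, phenotype) {
  if (length(phenotype) != ncol(expr_matrix))
    stop("phenotype length must match the sample count")
  if (length(phenotype) < 3L) stop("need >= 3 samples")
  if (sd(phenotype) == 0) stop("phenotype is constant")
  sig <- base::intersect(signature, rownames(expr_matrix))
  if (length(sig) == 0L) stop("no signature gene present in the matrix")
  score <- colMeans(expr_matrix[sig, , drop = FALSE])
  ct <- cor.test(score, phenotype)
  list(r = unname(ct$estimate), pvalue = ct$p.value, scores = score)
}

#' Correlation arcs between a gene and its surrounding regions
#'
#' Pearson correlation between the activity profile of every region within
#' `window` of the gene's TSS and the gene's expression profile, for
#' comparison with 3D-interaction calls and arc plotting.
#'
#' @param activity_matrix regions x samples matrix.
#' @param regions named `GRanges` of the activity rows.
#' @param expr_matrix genes x samples matrix (same panel).
#' @param gene_id gene of interest.
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss`.
#' @param window bp window around the TSS (default 1e6).
#' @return data.frame: `region_id`, `distance`, `corr`.
#' @export
correlation_arcs <- function(activity_matrix, regions, expr_matrix, gene_id,
                             tss_table, window = 1e6) {
  if (ncol(activity_matrix) < 3L) stop("need >= 3 samples")
  g <- tss_table[tss_table$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("gene not found (or duplicated) in tss_table")
  if (is.null(names(regions))) names(regions) <- region_ids(regions)
  on_c <- as.character(seqnames(regions)) == g$chrom
  dist <- pmax(0, pmax(start(regions) - (g$tss + 1L),
                       (g$tss + 1L) - end(regions)))
  sel <- which(on_c & dist <= window)
  expr <- expr_matrix[gene_id, ]
  out <- data.frame(
    region_id = names(regions)[sel],
    distance = dist[sel],
    corr = vapply(sel, function(i)
      cor(activity_matrix[names(regions)[i], ], expr), numeric(1)),
    stringsAsFactors = FALSE)
  out[order(out$distance), ]
}
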