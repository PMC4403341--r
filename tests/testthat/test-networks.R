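## small hand-built assignment scenario shared by the rule tests
toy_assignment <- function() {
  si <- GenomeInfoDb::Seqinfo("chr1", 4e6)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2000001, 2000001), width = 500), seqinfo = si)[1]
  names(regions) <- "R1"
  tss <- data.frame(gene_id = c("g_near", "g_far", "g_neg"),
                    chrom = "chr1",
                    tss = c(2500000, 3600000, 1200000))
  expr_results <- data.frame(id = c("g_near", "g_far", "g_neg"),
                             log2fc = c(2, 2, -2),
                             pvalue = c(0.001, 0.001, 0.001),
                             padj = c(0.05, 0.05, 0.05))
  samples <- paste0("s", 1:8)
  base <- seq_len(8)
  act <- matrix(base, 1, 8, dimnames = list("R1", samples))
  expr <- rbind(g_near = base + rnorm(8, sd = 2),
                g_far = base, g_neg = -base)
  colnames(expr) <- samples
  list(regions = regions, tss = tss, res = expr_results, act = act,
       expr = expr)
}

test_that("assignment applies the distance, expression and correlation filters", {
  set.seed(1)
  d <- toy_assignment()
  ## g_near: 500 kb away, passing everything -> linked
  links <- assign_regions_to_genes(d$regions, d$tss, d$res, d$act, d$expr,
                                   assignment_params())
  expect_true("g_near" %in% links$gene_id)
  ## g_far: 1.6 Mb away -> never linked at 1 Mb
  expect_false("g_far" %in% links$gene_id)
  ## negative correlation: linked in absolute mode, dropped in positive mode
  expect_true("g_neg" %in% links$gene_id)
  pos <- assign_regions_to_genes(d$regions, d$tss, d$res, d$act, d$expr,
                                 assignment_params(corr_mode = "positive"))
  expect_false("g_neg" %in% pos$gene_id)
  ## expression filter: padj above ge_alpha is ignored
  strict <- d$res; strict$padj <- 0.2
  none <- assign_regions_to_genes(d$regions, d$tss, strict, d$act, d$expr,
                                  assignment_params(ge_alpha = 0.1))
  expect_equal(nrow(none), 0)
  ## 2 Mb window reaches g_far; closest_only keeps one gene per region
  wide <- assign_regions_to_genes(d$regions, d$tss, d$res, d$act, d$expr,
                                  assignment_params(max_dist = 2e6))
  expect_true(all(c("g_near", "g_far") %in% wide$gene_id))
  close1 <- assign_regions_to_genes(d$regions, d$tss, d$res, d$act, d$expr,
                                    assignment_params(max_dist = 2e6,
                                                      closest_only = TRUE))
  expect_equal(nrow(close1), 1)
  expect_equal(close1$gene_id, "g_near")
  ## mismatched sample panels rejected
  bad <- d$expr; colnames(bad) <- paste0("x", 1:8)
  expect_error(assign_regions_to_genes(d$regions, d$tss, d$res, d$act, bad,
                                       assignment_params()), "mismatch")
})

test_that("assignment coverage reproduces printed-percentage arithmetic", {
  expect_equal(assignment_coverage(1404, 20122), 7)
  expect_equal(assignment_coverage(4599, 20122), 23)
  expect_equal(assignment_coverage(data.frame(region_id = character(),
                                              gene_id = character()), 100), 0)
  expect_error(assignment_coverage(10, 5), "more linked")
})

test_that("relaxing assignment thresholds never removes links (grid monotonicity)", {
  ds <- default_dataset()
  link_key <- function(l) paste(l$region_id, l$gene_id)
  grid_dist <- c(1e4, 2e4, 1e5, 1e6, 2e6)
  grid_alpha <- c(0.05, 0.1, 1)
  grid_corr <- c(0, 0.1, 0.3, 0.5, 0.7)
  links_at <- function(dist, alpha, corr, mode)
    link_key(default_links(assignment_params(dist, alpha, 1, corr, mode)))
  ## containment along each axis, absolute vs positive, on the printed grid
  for (mode in c("positive", "absolute")) {
    prev <- NULL
    for (dd in grid_dist) {
      cur <- links_at(dd, 0.1, 0.3, mode)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
    prev <- NULL
    for (aa in grid_alpha) {
      cur <- links_at(1e6, aa, 0.3, mode)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
    prev <- NULL
    for (cc in rev(grid_corr)) {
      cur <- links_at(1e6, 0.1, cc, mode)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
  ## positive-only links are a subset of absolute links
  expect_true(all(links_at(1e6, 0.1, 0.3, "positive") %in%
                    links_at(1e6, 0.1, 0.3, "absolute")))
  ## closest_only output is a subset of the all-genes output
  all_g <- default_links(assignment_params())
  close_g <- default_links(assignment_params(closest_only = TRUE))
  expect_true(all(link_key(close_g) %in% link_key(all_g)))
})

test_that("planted TF network is recovered at the study assignment parameters", {
  ds <- default_dataset()
  links <- default_links(assignment_params(closest_only = TRUE))
  net <- build_tf_network("TF_A", ds$truth$tf_target_regions$TF_A, links)
  expect_true(all(net$links$region_id %in% ds$truth$tf_target_regions$TF_A))
  truth_edges <- paste(ds$truth$region_gene_links$region_id,
                       ds$truth$region_gene_links$gene_id)
  pred_edges <- paste(net$links$region_id, net$links$gene_id)
  expect_gte(mean(truth_edges %in% pred_edges), 0.9)   # recall
  expect_gte(mean(pred_edges %in% truth_edges), 0.8)   # precision
  ## no targets -> empty network; shared regions -> identical gene sets
  empty <- build_tf_network("none", character(), links)
  expect_equal(nrow(empty$links), 0)
  twin <- build_tf_network("TF_B", ds$truth$tf_target_regions$TF_A, links)
  expect_equal(twin$target_genes, net$target_genes)
})

test_that("network overlap follows the hypergeometric tail", {
  a <- paste0("g", 1:5); b <- paste0("g", 6:10)
  d <- target_overlap(a, b, 20)
  expect_equal(d$k, 0)
  expect_gt(d$pvalue, 0.9)
  nested <- target_overlap(a, a, 20)
  expect_equal(nested$k, 5)
  expect_equal(nested$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(target_overlap(a, b, 8), "universe")
})

test_that("GSEA ES matches oracles; planted sets reach small FDR", {
  set.seed(6)
  for (n in c(30, 50)) {
    scores <- sort(setNames(rnorm(n), paste0("g", seq_len(n))),
                   decreasing = TRUE)
    for (p in c(0, 1)) {
      for (m in c(4, 10)) {
        gene_set <- sample(names(scores), m)
        got <- gsea_preranked(scores, gene_set, weight_p = p, n_perm = 50,
                              seed = 1)
        expect_equal(got$es, oracle_gsea_es(scores, gene_set, p),
                     tolerance = 1e-12)
      }
    }
    ## cross-check against the independent fgsea implementation (p = 1)
    gene_set <- sample(names(scores), 8)
    got <- gsea_preranked(scores, gene_set, weight_p = 1, n_perm = 50,
                          seed = 1)
    idx <- which(names(scores) %in% gene_set)
    expect_equal(got$es,
                 fgsea::calcGseaStat(unname(scores), idx, gseaParam = 1),
                 tolerance = 1e-6)
  }
  ## set = top |S| genes with p = 0: running sum peaks at 1 after the last hit
  scores <- sort(setNames(rnorm(2000), paste0("g", 1:2000)), decreasing = TRUE)
  top <- names(scores)[1:50]
  es_top <- gsea_preranked(scores, top, weight_p = 0, n_perm = 10, seed = 1)$es
  expect_equal(es_top, 1, tolerance = 1e-12)
  expect_equal(es_top, oracle_gsea_es(scores, top, 0), tolerance = 1e-12)
  ## planted top-loaded set of 50/2000 -> FDR < 0.01; degenerate set rejected
  g <- gsea_preranked(scores, top, weight_p = 1, n_perm = 1000, seed = 2)
  expect_lt(g$fdr, 0.01)
  expect_error(gsea_preranked(scores, names(scores)), "degenerate")
  expect_error(gsea_preranked(scores, "absent"), "intersect")
})

test_that("signature scores correlate with phenotypes as expected", {
  set.seed(3)
  expr <- matrix(rnorm(50 * 39, 8, 2), 50, 39,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:39)))
  sig <- paste0("g", 1:10)
  score <- colMeans(expr[sig, ])
  ## phenotype equal to the score -> r = 1; sign flip negates r
  r1 <- signature_score_correlation(expr, sig, score)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- signature_score_correlation(expr, sig, -score)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  ## independent phenotype: |r| small on average, p roughly uniform
  ps <- replicate(200, signature_score_correlation(expr, sig,
                                                   rnorm(39))$pvalue)
  expect_gt(mean(ps > 0.5), 0.35)
  expect_error(signature_score_correlation(expr, sig, rep(1, 39)), "constant")
})

test_that("correlation arcs flag the linked region against its background", {
  ds <- default_dataset()
  link1 <- ds$truth$region_gene_links[1, ]
  arcs <- correlation_arcs(log_transform(ds$activity), ds$catalog$regions,
                           log_transform(ds$expression), link1$gene_id,
                           ds$annotation, window = 1e6)
  expect_true(link1$region_id %in% arcs$region_id)
  ## perfect proportionality gives r = 1 / -1
  act <- matrix(1:6, 1, 6, dimnames = list("R1", paste0("s", 1:6)))
  regs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1500))
  names(regs) <- "R1"
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000)
  up <- matrix(2 * (1:6) + 3, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  dn <- -up; rownames(dn) <- "g1"
  expect_equal(correlation_arcs(act, regs, up, "g1", tss, 1e4)$corr, 1)
  expect_equal(correlation_arcs(act, regs, dn, "g1", tss, 1e4)$corr, -1)
  ## planted linked region beats the 95th percentile of unlinked |r|
  linked_r <- abs(arcs$corr[arcs$region_id == link1$region_id])
  unlinked <- abs(arcs$corr[!arcs$region_id %in%
                              ds$truth$region_gene_links$region_id])
  expect_gt(linked_r, quantile(unlinked, 0.95))
})
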