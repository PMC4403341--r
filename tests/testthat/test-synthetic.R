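test_that("generators are deterministic and respect genome bounds", {
  spec <- genome_spec(seed = 1)
  t1 <- generate_feature_tracks(spec)
  t2 <- generate_feature_tracks(spec)
  expect_identical(t1, t2)
  for (gr in c(t1$tracks, list(t1$insulators, t1$exons))) {
    expect_true(all(GenomicRanges::start(gr) >= 1))
    lim <- GenomeInfoDb::seqlengths(gr)[as.character(GenomicRanges::seqnames(gr))]
    expect_true(all(GenomicRanges::end(gr) <= lim))
  }
  ## density 0 -> empty but valid
  t0 <- generate_feature_tracks(spec, density = 0)
  expect_true(all(lengths(t0$tracks) == 0))
  ## zero-length chromosome rejected at spec construction
  expect_error(genome_spec("chr1", 0), "> 0")
  ## catalog and annotation deterministic too
  expect_identical(synthetic_catalog(spec, 500, 200),
                   synthetic_catalog(spec, 500, 200))
  expect_identical(synthetic_annotation(spec, 100),
                   synthetic_annotation(spec, 100))
})

test_that("track interval counts follow the Poisson density", {
  spec <- genome_spec("chr1", 1e7, seed = 3)
  tr <- generate_feature_tracks(spec, n_tracks = 1, density = 100)
  n <- length(tr$tracks[[1]])
  expect_true(abs(n - 1000) <= 3 * sqrt(1000))
})

test_that("activity counts carry the planted effect with NB noise", {
  spec <- genome_spec(seed = 2)
  cat_ <- synthetic_catalog(spec, 1000, 200)
  ## effect 0: per-region group-mean log-ratios centred at 0
  cfg0 <- state_config(effect_log2fc = 0, n_regions_active_a = 10,
                       n_regions_active_b = 10)
  ac0 <- generate_activity_counts(cat_, cfg0, seed = 4)
  m <- ac0$counts$counts
  a <- ac0$counts$design == "proliferative"
  lr <- log2(rowMeans(m[, !a]) + 0.5) - log2(rowMeans(m[, a]) + 0.5)
  expect_lt(abs(mean(lr)), 0.1)
  ## planted effect 2 -> group-mean ratio ~ 4x
  cfg2 <- state_config(effect_log2fc = 2, n_regions_active_a = 100,
                       n_regions_active_b = 100)
  ac2 <- generate_activity_counts(cat_, cfg2, seed = 5)
  act_b <- ac2$truth$active_regions_by_state$invasive
  m2 <- ac2$counts$counts
  ratio <- mean(rowMeans(m2[act_b, !a]) / rowMeans(m2[act_b, a]))
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.8)
  ## small dispersion -> variance close to the mean (Poisson-like limit)
  cfgP <- state_config(effect_log2fc = 0, nb_dispersion = 1e-4,
                       n_regions_active_a = 1, n_regions_active_b = 1,
                       n_state_a = 50, n_state_b = 50)
  acP <- generate_activity_counts(cat_, cfgP, seed = 6)
  vm <- apply(acP$counts$counts, 1, var) / rowMeans(acP$counts$counts)
  expect_lt(abs(median(vm) - 1), 0.15)
  ## oversized active sets rejected
  expect_error(generate_activity_counts(
    cat_, state_config(n_regions_active_a = 2000), seed = 1), "exceed")
})

test_that("planted motif instances are recoverable where recorded", {
  spec <- genome_spec(seed = 9)
  cat_ <- synthetic_catalog(spec, 200, 300)
  p <- planted_pwm()
  ids <- names(cat_$regions)[1:20]
  seqs <- generate_sequences_with_motifs(cat_, p, ids, seed = 2)
  offs <- attr(seqs, "offsets")
  expect_named(offs, ids)
  ## an instance sits at each recorded offset: windows there score high
  L <- ncol(p$mat)
  for (id in ids[1:5]) {
    sub <- substr(as.character(seqs[[id]]), offs[[id]] + 1, offs[[id]] + L)
    win_score <- oracle_scan(sub, p$mat)
    ## a sampled instance may carry a mismatch or two but still scores far
    ## above background (perfect site: 19.6 bits; random 10-mer: ~0)
    expect_gt(win_score, 5)
    expect_gte(scan_pwm(seqs[id], p)[[1]], win_score - 1e-9)
  }
  ## empty target set -> background only, deterministic under seed
  bg <- generate_sequences_with_motifs(cat_, p, character(), seed = 2)
  bg2 <- generate_sequences_with_motifs(cat_, p, character(), seed = 2)
  expect_identical(as.character(bg), as.character(bg2))
  expect_true(all(is.na(attr(bg, "offsets"))) || length(attr(bg, "offsets")) == 0)
  ## PWM longer than a region rejected
  tiny <- synthetic_catalog(spec, 50, 8)
  expect_error(generate_sequences_with_motifs(tiny, p, names(tiny$regions)[1]),
               "longer")
})

test_that("planted PWM separates targets from background (AUROC > 0.9)", {
  spec <- genome_spec(seed = 13)
  cat_ <- synthetic_catalog(spec, 2000, 300)
  p <- planted_pwm()
  targets <- sample(names(cat_$regions), 100)
  seqs <- generate_sequences_with_motifs(cat_, p, targets, seed = 3)
  sc <- scan_pwm(seqs, p)
  is_t <- names(sc) %in% targets
  ## Wilcoxon AUROC
  r <- rank(sc)
  auroc <- (sum(r[is_t]) - sum(is_t) * (sum(is_t) + 1) / 2) /
    (sum(is_t) * sum(!is_t))
  expect_gt(auroc, 0.9)
})

test_that("expression counts co-vary with linked region activity", {
  ds <- default_dataset()
  links <- ds$truth$region_gene_links
  act <- log_transform(ds$activity)
  expr <- log_transform(ds$expression)
  r_linked <- vapply(seq_len(nrow(links)), function(i)
    cor(act[links$region_id[i], ], expr[links$gene_id[i], ]), numeric(1))
  expect_gt(median(r_linked), 0.7)
  ## unlinked null pairs: no planted co-variation
  spec <- genome_spec(seed = 21)
  cat0 <- synthetic_catalog(spec, 200, 200)
  ann0 <- synthetic_annotation(spec, 200)
  cfg0 <- state_config(effect_log2fc = 0, n_regions_active_a = 1,
                       n_regions_active_b = 1)
  tr0 <- plant_truth(cat0, ann0, cfg0, n_loci = 1, regions_per_locus = 1,
                     n_de_genes_a = 1, n_de_genes_b = 1,
                     exclusion_bp = 1e4, seed = 2)
  a0 <- generate_activity_counts(cat0, cfg0, tr0, seed = 3)$counts
  e0 <- generate_expression_counts(ann0, cfg0, tr0, seed = 4)
  al <- log_transform(a0); el <- log_transform(e0)
  set.seed(8)
  rs <- vapply(1:500, function(i)
    cor(al[sample(nrow(al), 1), ], el[sample(nrow(el), 1), ]), numeric(1))
  ## null |r| at n = 11 has analytic median 0.674/sqrt(10) ~ 0.213
  expect_lt(median(abs(rs)), 0.3)
  expect_lt(abs(median(abs(rs)) - 0.674 / sqrt(10)), 0.05)
  ## determinism
  e0b <- generate_expression_counts(ann0, cfg0, tr0, seed = 4)
  expect_identical(e0$counts, e0b$counts)
})

test_that("planted truth is self-consistent and round-trips through JSON", {
  ds <- default_dataset()
  truth <- ds$truth
  ids <- names(ds$catalog$regions)
  expect_true(all(unlist(truth$active_regions_by_state) %in% ids))
  expect_true(all(unlist(truth$tf_target_regions) %in%
                    truth$active_regions_by_state$proliferative))
  expect_true(all(truth$region_gene_links$gene_id %in% ds$annotation$gene_id))
  tmp <- tempfile(fileext = ".json")
  write_truth(truth, tmp)
  back <- read_truth(tmp)
  expect_equal(back$active_regions_by_state, truth$active_regions_by_state)
  expect_equal(back$tf_target_regions, truth$tf_target_regions)
  expect_equal(back$region_gene_links, truth$region_gene_links)
  expect_equal(back$de_genes_by_state, truth$de_genes_by_state)
})
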