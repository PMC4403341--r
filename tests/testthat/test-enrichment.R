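test_that("PWM scanning matches the closed form, strand symmetry and brute force", {
  p <- planted_pwm()
  cons <- pwm_consensus(p)
  ## consensus of a degeneracy-free PWM under uniform background:
  ## score = sum log2(4 * p_max)
  expect_equal(unname(scan_pwm(setNames(cons, "x"), p)),
               sum(log2(4 * apply(p$mat, 2, max))), tolerance = 1e-9)
  ## reverse complement scores identically
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
  expect_equal(scan_pwm(setNames(cons, "a"), p)[[1]],
               scan_pwm(setNames(rc, "a"), p)[[1]], tolerance = 1e-9)
  ## random sequences vs an 8-mer PWM equal the per-window brute force
  set.seed(2)
  pw <- pwm_random(8, name = "r")
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:20)
  got <- scan_pwm(seqs, pw)
  want <- vapply(seqs, oracle_scan, numeric(1), mat = pw$mat)
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
  ## non-uniform background too
  bg <- c(0.3, 0.2, 0.2, 0.3)
  expect_equal(unname(scan_pwm(seqs, pw, background = bg)),
               unname(vapply(seqs, oracle_scan, numeric(1), mat = pw$mat,
                             background = bg)), tolerance = 1e-9)
  ## too-short / empty sequences get the -Inf sentinel
  expect_equal(unname(scan_pwm(c(a = "ACG", b = ""), pw)), c(-Inf, -Inf))
})

test_that("region ranking is a complete permutation with seeded tie-breaks", {
  sc <- setNames(c(5, 4, 3, 2, 1), paste0("r", 1:5))
  rk <- rank_regions(sc)
  expect_equal(unname(rk$ranks), 1:5)
  ## all-equal scores: different seeds give different valid permutations
  tied <- setNames(rep(1, 6), paste0("r", 1:6))
  r1 <- rank_regions(tied, tie_seed = 1)
  r2 <- rank_regions(tied, tie_seed = 2)
  expect_setequal(r1$ranks, 1:6)
  expect_setequal(r2$ranks, 1:6)
  expect_false(identical(r1$ranks, r2$ranks))
  ## tied block is uniformly shuffled across seeds
  sc2 <- setNames(c(9, rep(5, 4), 1), paste0("r", 1:6))
  pos <- replicate(400, rank_regions(sc2, tie_seed = sample.int(1e6, 1))$ranks["r3"])
  expect_setequal(unique(pos), 2:5)
  tab <- table(factor(pos, levels = 2:5))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("track ranking takes the maximum overlapping peak score", {
  spec <- genome_spec("chr1", 1e5, seed = 1)
  cat_ <- synthetic_catalog(spec, 10, 100)
  gr <- cat_$regions
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(GenomicRanges::start(gr)[1], GenomicRanges::start(gr)[1] + 10,
      GenomicRanges::end(gr)[2]), width = c(20, 30, 1)))
  peaks$score <- c(3, 7, 5)
  rk <- track_ranking(peaks, cat_)
  expect_equal(unname(rk$scores[names(gr)[1]]), 7)  # max of 3 and 7
  expect_equal(unname(rk$scores[names(gr)[2]]), 5)  # 1-bp overlap counts
  expect_equal(unname(rk$scores[names(gr)[3]]), 0)  # no overlap
  expect_equal(rk$kind, "track")
})

test_that("order-statistics Q matches the analytic cases and Monte Carlo", {
  expect_equal(combine_rankings_orderstat(0.3), 0.3)
  expect_equal(combine_rankings_orderstat(c(1, 1)), 1)
  expect_equal(combine_rankings_orderstat(c(0.1, 0.2)), 0.03, tolerance = 1e-12)
  expect_error(combine_rankings_orderstat(c(0, 0.5)), "\\(0, 1\\]")
  set.seed(17)
  n_draw <- 1e6
  for (N in 1:5) {
    U <- mc_orderstat_sample(n_draw, N)
    for (v in 1:20) {
      s <- sort(runif(N, 0.05, 1))
      q <- combine_rankings_orderstat(s)  # the joint probability itself
      p_hat <- mc_orderstat_prob(U, s)
      se <- sqrt(q * (1 - q) / n_draw)
      expect_lt(abs(q - p_hat), 3 * se + 1e-9)
    }
  }
})

test_that("recovery AUC equals the step-function oracle and the closed form", {
  M <- 10000
  ranks <- setNames(sample(M), paste0("r", 1:M))
  rk <- structure(list(feature = "f", kind = "motif", ranks = ranks),
                  class = "FeatureRanking")
  ## closed-form worked example: 5 foreground at ranks 1-5, T = 25
  ids_top <- names(ranks)[order(ranks)][1:5]
  expect_equal(recovery_auc(rk, ids_top), 0.92)
  ## no foreground inside the cutoff
  ids_bot <- names(ranks)[order(ranks)][(M - 4):M]
  expect_equal(recovery_auc(rk, ids_bot), 0)
  ## random foregrounds: exact agreement with the brute-force summation
  set.seed(4)
  for (i in 1:25) {
    fg <- sample(names(ranks), sample(c(5, 50, 400), 1))
    expect_equal(recovery_auc(rk, fg), oracle_auc(ranks, fg, M),
                 tolerance = 1e-12)
  }
  ## mean AUC over random rankings matches the uniform-placement expectation
  set.seed(9)
  fg <- paste0("r", 1:100)
  aucs <- replicate(400, {
    rr <- setNames(sample(M), paste0("r", 1:M))
    oracle_auc(rr, fg, M)
  })
  T_ <- 25
  expected <- (T_ + 1) / (2 * M)   # E[mean recovery] for uniform placement
  expect_lt(abs(mean(aucs) - expected), 3 * sd(aucs) / sqrt(length(aucs)))
  expect_error(recovery_auc(rk, character()), "non-empty")
})

test_that("NES standardizes AUCs as specified", {
  aucs <- setNames(c(0.1, 0.2, 0.3), c("a", "b", "c"))
  ## population sd of {0.1,0.2,0.3} is 0.0816...; hand-computed NES
  expect_equal(unname(nes_scores(aucs)),
               c(-0.1, 0, 0.1) / sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(unname(nes_scores(aucs, sd_type = "sample")), c(-1, 0, 1))
  expect_equal(unname(nes_scores(aucs))[2], 0)
  ## affine transform leaves NES unchanged
  expect_equal(nes_scores(2 * aucs + 0.05), nes_scores(aucs))
  expect_error(nes_scores(setNames(rep(0.2, 4), letters[1:4])), "degenerate")
  ## NES of a feature does not depend on relabeling of the others
  aucs2 <- aucs; names(aucs2) <- c("x", "y", "c")
  expect_equal(nes_scores(aucs)[["c"]], nes_scores(aucs2)[["c"]])
})

test_that("hypergeometric enrichment matches enumeration and is monotone in k", {
  M <- 20
  ranks <- setNames(1:M, paste0("r", 1:M))
  rk <- structure(list(feature = "f", kind = "motif", ranks = ranks),
                  class = "FeatureRanking")
  ## foreground = top 5, cutoff T = 5, k = 5 -> p = 1/choose(20,5)
  h <- hypergeom_enrichment(rk, paste0("r", 1:5), cutoff_frac = 0.25)
  expect_equal(h$k, 5)
  expect_equal(h$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  ## entire catalog as foreground -> p = 1
  h1 <- hypergeom_enrichment(rk, names(ranks), cutoff_frac = 0.25)
  expect_equal(h1$pvalue, 1)
  ## monotone decreasing in k for fixed margins
  ps <- vapply(0:5, function(k) {
    fg <- c(head(paste0("r", 1:5), k), head(paste0("r", 16:20), 5 - k))
    hypergeom_enrichment(rk, fg, cutoff_frac = 0.25)$pvalue
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  ## Bonferroni
  h2 <- hypergeom_enrichment(rk, paste0("r", 1:5), cutoff_frac = 0.25,
                             n_features = 100)
  expect_equal(h2$padj, min(1, h2$pvalue * 100))
})

test_that("leading targets and motif/track intersection behave as sets", {
  M <- 1000
  ranks <- setNames(1:M, paste0("r", 1:M))
  rk <- structure(list(feature = "f", kind = "motif", ranks = ranks),
                  class = "FeatureRanking")
  fg <- c("r5", "r2", "r900")
  lt <- leading_targets(rk, fg, cutoff_frac = 0.01)  # T = 10
  expect_equal(lt, c("r2", "r5"))                    # ordered by rank
  expect_true(all(lt %in% fg))
  expect_length(leading_targets(rk, "r900", cutoff_frac = 0.01), 0)
  expect_equal(intersect_motif_track(c("a", "b"), c("c")), character(0))
  expect_setequal(intersect_motif_track(c("a", "b"), c("b", "a")), c("a", "b"))
  expect_equal(intersect_motif_track(c("r5", "r2"), c("r2", "r5"), rk),
               c("r2", "r5"))
})

test_that("planted PWM wins the default synthetic enrichment screen", {
  ds <- default_dataset()
  enr <- default_enrichment()
  res <- enr$results
  expect_equal(res$feature[1], "TF_A")
  expect_gte(res$nes[1], 3)
  expect_lte(res$padj[1], 0.05)
  ## AUCs equal the brute-force oracle on every feature
  rankings <- default_rankings()
  fg <- ds$truth$active_regions_by_state$proliferative
  for (rk in rankings[c(1, 5, 20, 51)]) {
    expect_equal(recovery_auc(rk, fg),
                 oracle_auc(rk$ranks, fg, length(rk$ranks)),
                 tolerance = 1e-12)
  }
  ## leading targets of the planted PWM are planted target regions
  expect_true(all(enr$targets$TF_A %in% ds$truth$tf_target_regions$TF_A))
  ## a dedicated small screen recovers >= 80% of planted targets when the
  ## planted set fits inside the cutoff (T = 25, 10 planted); a sharp motif
  ## keeps sampled instances at consensus strength
  sharp <- planted_pwm(p_dominant = 0.997)
  cat_ <- synthetic_catalog(genome_spec(seed = 23), 10000, 300)
  few <- sample(names(cat_$regions), 10)
  seqs <- generate_sequences_with_motifs(cat_, sharp, few, seed = 3)
  rk1 <- rank_regions(scan_pwm(seqs, sharp), feature = "TF_A")
  fg2 <- unique(c(few, sample(names(cat_$regions), 990)))
  lt <- leading_targets(rk1, fg2)
  expect_gte(mean(few %in% lt), 0.8)
})
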