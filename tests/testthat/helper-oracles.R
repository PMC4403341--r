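## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (bit vectors and explicit loops instead
## of interval algebra; direct window enumeration instead of the compiled
## scanner; exponential-spacings Monte Carlo instead of the recursion).

## ---- per-bp region-catalog oracle -----------------------------------------
## Intervals are data.frames with chrom/start/end in 0-based half-open
## coordinates; chrom_len is a named vector. Each stage returns the interval
## list the corresponding catalog stage should produce.

bits_from_intervals <- function(df, len) {
  b <- logical(len)
  if (!is.null(df) && nrow(df)) {
    for (i in seq_len(nrow(df))) {
      s <- max(0L, df$start[i]); e <- min(len, df$end[i])
      if (e > s) b[(s + 1L):e] <- TRUE
    }
  }
  b
}

runs_from_bits <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

oracle_stages <- function(tracks, ins, exo, chrom_len,
                          min_len = 30L, target_len = 1000L,
                          ifrac = 0.2, efrac = 0.8) {
  out <- list(merged = NULL, cleaned = NULL, sized = NULL, extended = NULL)
  for (cc in names(chrom_len)) {
    len <- chrom_len[[cc]]
    sel <- function(df) df[df$chrom == cc, , drop = FALSE]
    cov <- Reduce(`|`, lapply(tracks, function(t) bits_from_intervals(sel(t), len)),
                  logical(len))
    ib <- bits_from_intervals(sel(ins), len)
    eb <- bits_from_intervals(sel(exo), len)
    merged <- runs_from_bits(cov)
    ## removal then per-bp subtraction
    keep <- logical(len)
    if (nrow(merged)) for (i in seq_len(nrow(merged))) {
      idx <- (merged$start[i] + 1L):merged$end[i]
      L <- length(idx)
      if (sum(ib[idx]) / L >= ifrac || sum(eb[idx]) / L >= efrac) next
      keep[idx] <- !(ib[idx] | eb[idx])
    }
    cleaned <- runs_from_bits(keep)
    sized <- cleaned[cleaned$end - cleaned$start >= min_len, , drop = FALSE]
    ## extension: left-to-right, symmetric first, spill to the open side,
    ## 1-bp gap to the next catalog region, blacklist/chrom ends may abut
    black <- ib | eb
    ext <- sized
    if (nrow(ext)) for (i in seq_len(nrow(ext))) {
      L <- ext$end[i] - ext$start[i]
      if (L >= target_len) next
      lb <- 0L
      if (ext$start[i] > 0L) {
        bl <- which(black[seq_len(ext$start[i])])
        if (length(bl)) lb <- max(bl)          # 1-based bit = 0-based coord
      }
      if (i > 1L) lb <- max(lb, ext$end[i - 1L] + 1L)
      rb <- len
      if (ext$end[i] < len) {
        br <- which(black[(ext$end[i] + 1L):len])
        if (length(br)) rb <- ext$end[i] + min(br) - 1L
      }
      if (i < nrow(ext)) rb <- min(rb, ext$start[i + 1L] - 1L)
      avail_l <- ext$start[i] - lb
      avail_r <- rb - ext$end[i]
      d <- target_len - L
      add_l <- min(avail_l, d %/% 2L)
      add_r <- min(avail_r, d - add_l)
      add_l <- min(avail_l, d - add_r)
      ext$start[i] <- ext$start[i] - add_l
      ext$end[i] <- ext$end[i] + add_r
    }
    wrap <- function(df) if (nrow(df)) cbind(chrom = cc, df) else NULL
    out$merged <- rbind(out$merged, wrap(merged))
    out$cleaned <- rbind(out$cleaned, wrap(cleaned))
    out$sized <- rbind(out$sized, wrap(sized))
    out$extended <- rbind(out$extended, wrap(ext))
  }
  lapply(out, function(df) {
    if (is.null(df)) data.frame(chrom = character(), start = integer(),
                                end = integer())
    else df
  })
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

df_to_gr <- function(df, chrom_len = NULL) {
  si <- if (is.null(chrom_len)) NULL
        else GenomeInfoDb::Seqinfo(names(chrom_len), unname(chrom_len))
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges(seqinfo = si))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(si)) GenomeInfoDb::seqinfo(gr) <- si
  gr
}

expect_same_intervals <- function(gr, df, info = NULL) {
  got <- gr_to_df(gr)
  got <- got[order(got$chrom, got$start), ]
  df <- df[order(df$chrom, df$start), ]
  rownames(got) <- rownames(df) <- NULL
  expect_equal(got$chrom, as.character(df$chrom), info = info)
  expect_equal(got$start, as.integer(df$start), info = info)
  expect_equal(got$end, as.integer(df$end), info = info)
}

rand_interval_df <- function(chrom_len, n_per_chrom, len_range) {
  do.call(rbind, lapply(names(chrom_len), function(cc) {
    n <- n_per_chrom
    w <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    s <- sapply(w, function(wi) sample.int(max(chrom_len[[cc]] - wi, 1), 1) - 1L)
    data.frame(chrom = cc, start = s, end = pmin(s + w, chrom_len[[cc]]),
               stringsAsFactors = FALSE)
  }))
}

## ---- PWM scan oracle -------------------------------------------------------
oracle_scan <- function(seq, mat, background = rep(0.25, 4)) {
  lom <- log2(sweep(mat, 1, background, "/"))
  lomN <- rbind(lom, colSums(background * lom))
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  L <- ncol(mat)
  if (length(code) < L) return(-Inf)
  rc_code <- rev(c(4L, 3L, 2L, 1L, 5L)[code])
  best <- -Inf
  for (p in 0:(length(code) - L)) {
    fw <- sum(lomN[cbind(code[p + 1:L], 1:L)])
    rv <- sum(lomN[cbind(rc_code[p + 1:L], 1:L)])
    best <- max(best, fw, rv)
  }
  best
}

## ---- recovery-curve step-function oracle ----------------------------------
oracle_auc <- function(ranks, foreground, M, cutoff_frac = 0.0025) {
  T_ <- ceiling(cutoff_frac * M)
  rec <- numeric(T_)
  fr <- ranks[foreground]
  for (x in seq_len(T_)) rec[x] <- sum(fr <= x) / length(foreground)
  mean(rec)
}

## ---- uniform order-statistics Monte Carlo ---------------------------------
## Sorted uniforms generated by the exponential-spacings construction, so no
## sorting of the package's kind is involved.
mc_orderstat_sample <- function(n_draw, N) {
  E <- matrix(stats::rexp(n_draw * (N + 1L)), n_draw, N + 1L)
  S <- E
  for (j in 2:(N + 1L)) S[, j] <- S[, j - 1L] + E[, j]
  S[, seq_len(N), drop = FALSE] / S[, N + 1L]
}

mc_orderstat_prob <- function(U, s) {
  ok <- rep(TRUE, nrow(U))
  for (j in seq_along(s)) ok <- ok & (U[, j] <= s[j])
  mean(ok)
}

## ---- GSEA running-sum oracle (explicit position loop) ----------------------
oracle_gsea_es <- function(scores, gene_set, p = 1) {
  scores <- sort(scores, decreasing = TRUE)
  hit <- names(scores) %in% gene_set
  NR <- sum(abs(scores[hit])^p)
  run <- 0; best <- 0
  n_miss <- sum(!hit)
  for (i in seq_along(scores)) {
    run <- run + if (hit[i]) abs(scores[[i]])^p / NR else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

## ---- shared expensive fixtures (computed once per session) -----------------
regland_cache <- local({
  if (!exists(".regland_test_cache", envir = globalenv()))
    assign(".regland_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".regland_test_cache", envir = globalenv())
})

default_dataset <- function() {
  if (is.null(regland_cache$ds))
    regland_cache$ds <- synthetic_dataset(genome_spec(seed = 7L))
  regland_cache$ds
}

default_rankings <- function() {
  if (is.null(regland_cache$rankings)) {
    ds <- default_dataset()
    regland_cache$rankings <- lapply(ds$pwms, function(pw)
      rank_regions(scan_pwm(ds$sequences, pw), feature = pw$name,
                   kind = "motif", tie_seed = stage_seed(7L, pw$name)))
  }
  regland_cache$rankings
}

default_enrichment <- function() {
  if (is.null(regland_cache$enr)) {
    ds <- default_dataset()
    fg <- ds$truth$active_regions_by_state[[1]]
    regland_cache$enr <- enrich_features(default_rankings(), fg)
  }
  regland_cache$enr
}

default_differential <- function() {
  if (is.null(regland_cache$dr))
    regland_cache$dr <- differential_regions(default_dataset()$activity)
  regland_cache$dr
}

default_links <- function(params = assignment_params(closest_only = TRUE)) {
  ds <- default_dataset()
  dr <- default_differential()
  if (is.null(regland_cache$gd))
    regland_cache$gd <- nb_differential(ds$expression)
  diff_ids <- c(dr[[1]], dr[[2]])
  assign_regions_to_genes(ds$catalog$regions[diff_ids], ds$annotation,
                          regland_cache$gd,
                          log_transform(ds$activity),
                          log_transform(ds$expression), params)
}
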