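## Candidate regulatory-region catalog construction.
##
## The catalog is the ranking universe for all downstream enrichment and
## differential-activity work: heterogeneous regulatory feature tracks are
## merged into a single non-overlapping set of intervals, intervals dominated
## by insulators or coding exons are removed, partially covered intervals are
## split at the blacklist boundaries, fragments < 30 bp are dropped, and the
## survivors are extended towards 1 kb where space permits.
##
## All coordinates are 0-based half-open (BED) at the interfaces; internally
## GRanges (1-based closed) is used and converted at the I/O boundary.

#' Validate a GRanges of intervals
#' @keywords internal
check_intervals <- function(gr, what = "intervals") {
  if (!is(gr, "GRanges")) stop(what, " must be a GRanges")
  if (length(gr) == 0L) return(invisible(gr))
  bad <- which(width(gr) < 1L)
  if (length(bad))
    stop(sprintf("%s: malformed interval (width < 1) at %s:%d-%d",
                 what, as.character(seqnames(gr))[bad[1]],
                 start(gr)[bad[1]], end(gr)[bad[1]]))
  sl <- seqlengths(gr)
  if (any(!is.na(sl))) {
    lim <- sl[as.character(seqnames(gr))]
    out <- which(!is.na(lim) & (end(gr) > lim | start(gr) < 1L))
    if (length(out))
      stop(sprintf("%s: interval outside chromosome bounds at %s:%d-%d",
                   what, as.character(seqnames(gr))[out[1]],
                   start(gr)[out[1]], end(gr)[out[1]]))
  }
  invisible(gr)
}

#' Merge feature tracks into a non-overlapping interval set
#'
#' Computes the union of all input tracks. Overlapping and abutting intervals
#' are joined (distance-0 join), so no two output intervals on the same
#' chromosome overlap or abut.
#'
#' @param tracks a `GRanges`, or a list / `GRangesList` of `GRanges`.
#' @return a sorted, reduced `GRanges`.
#' @export
#' @examples
#' library(GenomicRanges)
#' merge_tracks(GRanges("chr1", IRanges(c(1, 51), c(100, 200))))
merge_tracks <- function(tracks) {
  if (is(tracks, "GRangesList")) tracks <- as.list(tracks)
  if (!is.list(tracks)) tracks <- list(tracks)
  for (t in tracks) check_intervals(t, "track")
  if (length(tracks) == 0L) return(GRanges())
  all <- do.call(c, unname(lapply(tracks, granges)))
  sort(reduce(all, min.gapwidth = 1L))
}

## per-region overlap width with a (flattened) blacklist
overlap_bp <- function(regions, blacklist) {
  ov <- rep(0L, length(regions))
  if (length(blacklist) == 0L || length(regions) == 0L) return(ov)
  hits <- findOverlaps(regions, blacklist)
  if (length(hits) == 0L) return(ov)
  w <- width(pintersect(regions[queryHits(hits)], blacklist[subjectHits(hits)]))
  agg <- tapply(w, queryHits(hits), sum)
  ov[as.integer(names(agg))] <- as.integer(agg)
  ov
}

#' Remove or split regions by insulator and exon blacklists
#'
#' A region whose overlap with insulator elements is at least
#' `insulator_frac` (default 20%) of the region length, or with coding exons
#' at least `exon_frac` (default 80%), is removed outright. Regions with
#' smaller overlaps are split at the blacklist boundaries and the covered
#' pieces are discarded, so no output interval contains blacklist sequence.
#' Both blacklists are evaluated against the pre-split region, and removal is
#' checked before splitting. Overlap fractions are measured relative to the
#' candidate region's length.
#'
#' @param regions `GRanges` of candidate regions.
#' @param insulators,exons `GRanges` blacklists (may be empty).
#' @param insulator_frac,exon_frac removal thresholds on the
#'   overlap-fraction-of-region scale.
#' @return `GRanges` of surviving (possibly split) regions.
#' @export
remove_or_split_by_blacklist <- function(regions, insulators = GRanges(),
                                         exons = GRanges(),
                                         insulator_frac = 0.20,
                                         exon_frac = 0.80) {
  check_intervals(regions, "regions")
  check_intervals(insulators, "insulators")
  check_intervals(exons, "exons")
  if (length(regions) == 0L) return(regions)
  ins <- reduce(insulators)
  exo <- reduce(exons)
  keep <- overlap_bp(regions, ins) / width(regions) < insulator_frac &
          overlap_bp(regions, exo) / width(regions) < exon_frac
  survivors <- regions[keep]
  black <- reduce(c(granges(ins), granges(exo)))
  if (length(black) == 0L) return(sort(granges(survivors)))
  sort(setdiff(granges(survivors), black))
}

#' Drop regions below a minimum length
#'
#' @param regions `GRanges`.
#' @param min_len minimum retained length in bp (default 30).
#' @return `GRanges` with all widths `>= min_len`.
#' @export
filter_min_length <- function(regions, min_len = 30L) {
  check_intervals(regions, "regions")
  regions[width(regions) >= min_len]
}

#' Extend short regions towards a target length
#'
#' Regions shorter than `target_len` (default 1 kb) are extended, where
#' possible, without creating new overlap with blacklist intervals, other
#' catalog regions, or chromosome ends. The deficit is allocated
#' symmetrically first; any blocked remainder is taken from the other side.
#' Partial extension is allowed when the full target is unreachable
#' ("if possible"); a fully boxed-in region is left unchanged. Regions are
#' processed left-to-right per chromosome against the already-extended left
#' neighbour, and extension stops 1 bp short of the next catalog region so
#' that a rebuild of the catalog from its own output cannot re-merge
#' neighbours (idempotence).
#'
#' @param regions blacklist-clean `GRanges`, sorted.
#' @param target_len target length in bp (default 1000).
#' @param blacklist `GRanges` of obstacles (insulators + exons).
#' @return extended `GRanges`, same length and order as the input.
#' @export
extend_regions <- function(regions, target_len = 1000L, blacklist = GRanges()) {
  check_intervals(regions, "regions")
  check_intervals(blacklist, "blacklist")
  if (length(regions) == 0L) return(regions)
  regions <- sort(granges(regions))
  black <- reduce(blacklist)
  sl <- seqlengths(regions)
  out_start <- start(regions); out_end <- end(regions)
  chr <- as.character(seqnames(regions))
  bl_chr <- as.character(seqnames(black))
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    b_s <- start(black)[bl_chr == cc]; b_e <- end(black)[bl_chr == cc]
    lim <- if (!is.null(sl) && !is.na(sl[cc])) sl[cc] else Inf
    for (j in seq_along(idx)) {
      i <- idx[j]
      len <- out_end[i] - out_start[i] + 1L
      if (len >= target_len) next
      ## nearest obstacle boundaries (1-based closed coordinates):
      ## left_lim = smallest allowed start, right_lim = largest allowed end
      ## leave a 1-bp gap to the (already extended) previous catalog region
      left_edges <- c(0, b_e[b_e < out_start[i]],
                      if (j > 1L) out_end[idx[j - 1L]] + 1L)
      left_lim <- max(left_edges) + 1L
      right_edges <- c(lim + 1L, b_s[b_s > out_end[i]],
                       if (j < length(idx)) out_start[idx[j + 1L]])
      ## stop 1 bp short of the next catalog region; blacklist/chrom end may abut
      nxt <- if (j < length(idx)) out_start[idx[j + 1L]] - 1L else Inf
      right_lim <- min(min(right_edges) - 1L, nxt - 1L, lim)
      avail_l <- out_start[i] - left_lim
      avail_r <- right_lim - out_end[i]
      if (avail_l < 0) avail_l <- 0
      if (avail_r < 0) avail_r <- 0
      deficit <- target_len - len
      add_l <- min(avail_l, deficit %/% 2L)
      add_r <- min(avail_r, deficit - add_l)
      add_l <- min(avail_l, deficit - add_r)
      out_start[i] <- out_start[i] - add_l
      out_end[i] <- out_end[i] + add_r
    }
  }
  GRanges(chr, IRanges(out_start, out_end), seqinfo = seqinfo(regions))
}

#' Build the candidate regulatory-region catalog
#'
#' Composition of the full catalog-construction procedure:
#' [merge_tracks()] -> [remove_or_split_by_blacklist()] ->
#' [filter_min_length()] -> [extend_regions()], with stable region IDs of the
#' form `chrom:start-end` (0-based half-open) assigned at the end.
#'
#' @param tracks list of `GRanges` feature tracks (or one `GRanges`).
#' @param insulators,exons blacklist `GRanges`.
#' @param min_len minimum region length (default 30 bp).
#' @param target_len extension target (default 1000 bp).
#' @param insulator_frac,exon_frac removal thresholds (defaults 0.20 / 0.80).
#' @param provenance optional character vector of source-track names.
#' @return a `RegionCatalog`: list with `regions` (named `GRanges`),
#'   `provenance` and `build_params`.
#' @export
build_catalog <- function(tracks, insulators = GRanges(), exons = GRanges(),
                          min_len = 30L, target_len = 1000L,
                          insulator_frac = 0.20, exon_frac = 0.80,
                          provenance = NULL) {
  merged <- merge_tracks(tracks)
  cleaned <- remove_or_split_by_blacklist(merged, insulators, exons,
                                          insulator_frac, exon_frac)
  sized <- filter_min_length(cleaned, min_len)
  black <- reduce(c(granges(reduce(insulators)), granges(reduce(exons))))
  extended <- extend_regions(sized, target_len, black)
  regions <- sort(extended)
  names(regions) <- region_ids(regions)
  structure(list(
    regions = regions,
    provenance = provenance %||% paste0("track", seq_along(tracks)),
    build_params = list(min_len = min_len, target_len = target_len,
                        insulator_frac = insulator_frac,
                        exon_frac = exon_frac)
  ), class = "RegionCatalog")
}

#' Stable region IDs `chrom:start-end` in 0-based half-open coordinates
#' @param gr `GRanges`.
#' @return character vector of IDs.
#' @export
region_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' @export
print.RegionCatalog <- function(x, ...) {
  st <- catalog_stats(x)
  cat(sprintf("RegionCatalog: %d regions, mean length %.1f bp", st$n,
              st$mean_length))
  if (!is.na(st$genome_fraction))
    cat(sprintf(", %.1f%% of genome", 100 * st$genome_fraction))
  cat("\n")
  invisible(x)
}

#' Catalog summary statistics
#'
#' Region count, mean length and fraction of the genome covered (requires
#' chromosome lengths on the catalog's seqinfo; `NA` otherwise).
#'
#' @param catalog a `RegionCatalog` or `GRanges`.
#' @return list with `n`, `mean_length`, `total_bp`, `genome_fraction`.
#' @export
catalog_stats <- function(catalog) {
  gr <- if (is(catalog, "RegionCatalog")) catalog$regions else catalog
  sl <- seqlengths(gr)
  list(n = length(gr),
       mean_length = if (length(gr)) mean(width(gr)) else NA_real_,
       total_bp = sum(as.numeric(width(gr))),
       genome_fraction = if (length(sl) && !anyNA(sl))
         sum(as.numeric(width(reduce(gr)))) / sum(as.numeric(sl))
       else NA_real_)
}

#' Read / write catalogs and tracks as BED
#'
#' Thin wrappers over `rtracklayer` (BED is 0-based half-open on disk,
#' `GRanges` in memory).
#'
#' @param gr `GRanges` (or `RegionCatalog`) to write.
#' @param path BED file path.
#' @return `read_bed` returns a `GRanges`.
#' @export
write_bed <- function(gr, path) {
  if (is(gr, "RegionCatalog")) gr <- gr$regions
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
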