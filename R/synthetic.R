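## Synthetic data with planted ground truth.
##
## A toy genome carries feature/insulator/exon tracks, a tiled region
## catalog, a gene annotation, two-state negative-binomial activity and
## expression counts, region sequences with planted motif instances, and a
## planted TF -> enhancer -> gene network. Every generator is a pure
## function of its seed, and the planted truth object records exactly what
## downstream callers are expected to recover.
##
## Default scale mirrors the study design at desk scale: 2 chromosomes x
## 10 Mb, 10,000 candidate regions, 2,000 genes, 9 "proliferative" + 2
## "invasive" samples, planted effects of log2FC 2 on NB counts with
## dispersion 0.1.

#' Toy genome specification
#'
#' @param chrom_names unique chromosome labels.
#' @param chrom_lengths lengths in bp (> 0).
#' @param seed integer RNG seed; identical seeds give bit-identical outputs
#'   in every downstream generator.
#' @return a `GenomeSpec` list.
#' @export
genome_spec <- function(chrom_names = c("chr1", "chr2"),
                        chrom_lengths = c(1e7, 1e7), seed = 1L) {
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths))
    stop("names and lengths differ in length")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = setNames(as.numeric(chrom_lengths),
                                          chrom_names),
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

spec_seqinfo <- function(spec) {
  Seqinfo(seqnames = spec$chrom_names,
          seqlengths = as.integer(spec$chrom_lengths))
}

#' Two-state study configuration
#'
#' @param n_state_a,n_state_b sample counts per state (defaults 9
#'   proliferative-like vs 2 invasive-like).
#' @param n_regions_active_a,n_regions_active_b planted differential region
#'   counts per state (defaults 1000 each).
#' @param effect_log2fc planted mean log2 fold change (default 2).
#' @param nb_dispersion shared NB dispersion, Var = mu + alpha mu^2
#'   (default 0.1).
#' @param baseline_mean mean background count (default 100).
#' @param state_names labels for the two states.
#' @return a `StateConfig` list.
#' @export
state_config <- function(n_state_a = 9L, n_state_b = 2L,
                         n_regions_active_a = 1000L,
                         n_regions_active_b = 1000L,
                         effect_log2fc = 2, nb_dispersion = 0.1,
                         baseline_mean = 100,
                         state_names = c("proliferative", "invasive")) {
  stopifnot(n_state_a >= 1, n_state_b >= 1, nb_dispersion > 0,
            effect_log2fc >= 0, baseline_mean > 0,
            length(state_names) == 2L)
  structure(list(n_state_a = as.integer(n_state_a),
                 n_state_b = as.integer(n_state_b),
                 n_regions_active_a = as.integer(n_regions_active_a),
                 n_regions_active_b = as.integer(n_regions_active_b),
                 effect_log2fc = effect_log2fc,
                 nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean,
                 state_names = state_names),
            class = "StateConfig")
}

state_design <- function(cfg) {
  samples <- c(sprintf("%s_%02d", cfg$state_names[1], seq_len(cfg$n_state_a)),
               sprintf("%s_%02d", cfg$state_names[2], seq_len(cfg$n_state_b)))
  setNames(factor(rep(cfg$state_names, c(cfg$n_state_a, cfg$n_state_b)),
                  levels = cfg$state_names), samples)
}

rand_intervals <- function(spec, density, mean_len) {
  gr <- GRanges(seqinfo = spec_seqinfo(spec))
  for (cc in spec$chrom_names) {
    L <- spec$chrom_lengths[[cc]]
    n <- rpois(1L, density * L / 1e6)
    if (n == 0L) next
    len <- pmax(50L, as.integer(round(stats::rgamma(n, shape = 2,
                                                    scale = mean_len / 2))))
    st <- as.integer(floor(runif(n, 1, pmax(2, L - len))))
    en <- pmin(st + len - 1L, L)
    gr <- c(gr, GRanges(cc, IRanges(st, en), seqinfo = spec_seqinfo(spec)))
  }
  sort(gr)
}

#' Generate regulatory feature tracks plus insulator and exon tracks
#'
#' Interval counts per chromosome are Poisson with the given per-Mb density;
#' starts are uniform and lengths gamma-distributed. Insulator and exon
#' tracks are generated with their own densities and typical lengths.
#'
#' @param spec a [genome_spec()].
#' @param n_tracks number of regulatory feature tracks (default 3).
#' @param density intervals per Mb per track (default 100; 0 gives empty
#'   tracks).
#' @param mean_len mean feature length in bp (default 600).
#' @param insulator_density,exon_density per-Mb densities of the blacklist
#'   tracks.
#' @param seed RNG seed (default derived from the spec).
#' @return list with `tracks` (list of `GRanges`), `insulators`, `exons`.
#' @export
generate_feature_tracks <- function(spec, n_tracks = 3L, density = 100,
                                    mean_len = 600,
                                    insulator_density = 2,
                                    exon_density = 10,
                                    seed = stage_seed(spec$seed, "tracks")) {
  stopifnot(is(spec, "GenomeSpec"), density >= 0)
  with_seed(seed, {
    tracks <- lapply(seq_len(n_tracks), function(i)
      rand_intervals(spec, density, mean_len))
    names(tracks) <- sprintf("track%d", seq_len(n_tracks))
    list(tracks = tracks,
         insulators = rand_intervals(spec, insulator_density, 1000),
         exons = rand_intervals(spec, exon_density, 200))
  })
}

#' Tile a toy region catalog over a genome
#'
#' Regions of fixed length placed on a regular grid with uniform jitter, so
#' they never overlap; used as the ranking universe for the synthetic
#' pipeline (a catalog built from tracks with [build_catalog()] can be
#' substituted).
#'
#' @param spec a [genome_spec()].
#' @param n_regions total region count (default 10000).
#' @param region_len region length in bp (default 500).
#' @param seed RNG seed.
#' @return a `RegionCatalog`.
#' @export
synthetic_catalog <- function(spec, n_regions = 10000L, region_len = 500L,
                              seed = stage_seed(spec$seed, "catalog")) {
  stopifnot(is(spec, "GenomeSpec"))
  total <- sum(spec$chrom_lengths)
  per_chrom <- pmax(1L, round(n_regions * spec$chrom_lengths / total))
  per_chrom[length(per_chrom)] <- n_regions - sum(per_chrom[-length(per_chrom)])
  gr <- with_seed(seed, {
    parts <- lapply(seq_along(spec$chrom_names), function(ci) {
      cc <- spec$chrom_names[ci]
      n <- per_chrom[ci]
      spacing <- floor(spec$chrom_lengths[[cc]] / n)
      if (spacing <= region_len)
        stop("regions do not fit: reduce n_regions or region_len")
      jit <- floor(runif(n, 0, spacing - region_len))
      st <- as.integer((seq_len(n) - 1L) * spacing + jit + 1L)
      GRanges(cc, IRanges(st, width = region_len),
              seqinfo = spec_seqinfo(spec))
    })
    sort(do.call(c, parts))
  })
  names(gr) <- region_ids(gr)
  structure(list(regions = gr, provenance = "synthetic_tiling",
                 build_params = list(n_regions = n_regions,
                                     region_len = region_len, seed = seed)),
            class = "RegionCatalog")
}

#' Toy gene annotation with TSS coordinates
#'
#' @param spec a [genome_spec()].
#' @param n_genes gene count (default 2000).
#' @param seed RNG seed.
#' @return data.frame: `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
synthetic_annotation <- function(spec, n_genes = 2000L,
                                 seed = stage_seed(spec$seed, "annotation")) {
  total <- sum(spec$chrom_lengths)
  per_chrom <- pmax(1L, round(n_genes * spec$chrom_lengths / total))
  per_chrom[length(per_chrom)] <- n_genes - sum(per_chrom[-length(per_chrom)])
  with_seed(seed, {
    parts <- lapply(seq_along(spec$chrom_names), function(ci) {
      cc <- spec$chrom_names[ci]
      n <- per_chrom[ci]
      spacing <- floor(spec$chrom_lengths[[cc]] / n)
      tss <- as.integer((seq_len(n) - 1L) * spacing +
                          floor(runif(n, 0, spacing)))
      data.frame(chrom = cc, tss = tss,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, parts)
    ann <- ann[order(match(ann$chrom, spec$chrom_names), ann$tss), ]
    ann$gene_id <- sprintf("gene%04d", seq_len(nrow(ann)))
    rownames(ann) <- NULL
    ann[, c("gene_id", "chrom", "tss", "strand")]
  })
}

#' Plant the ground-truth regulatory program
#'
#' Chooses the planted differential region sets, the planted TF's target
#' regions, the enhancer -> gene links and the planted differential genes.
#' The TF's link-carrying target regions are clustered at `n_loci`
#' well-separated enhancer loci, one target gene per locus (the gene nearest
#' the locus centre), emulating enhancer clusters around state genes. All
#' other planted differential genes are kept at least `exclusion_bp` from
#' every TF target region, so the distance filter of the assignment step can
#' separate true from spurious enhancer-gene pairs: in a two-state design
#' every state-responsive region correlates with every state-responsive
#' gene, and geometry is the information that resolves the links.
#'
#' @param catalog a `RegionCatalog`.
#' @param annotation gene TSS table from [synthetic_annotation()].
#' @param cfg a [state_config()].
#' @param n_loci enhancer loci for the planted TF (default 4).
#' @param regions_per_locus TF target regions per locus (default 50).
#' @param n_de_genes_a,n_de_genes_b planted differential gene counts
#'   (defaults 50 each; state-A genes include the locus target genes).
#' @param exclusion_bp separation kept between non-locus differential genes
#'   and TF target regions (default 1.05e6, just beyond the 1 Mb assignment
#'   window).
#' @param tf_name planted TF label.
#' @param seed RNG seed.
#' @return a `PlantedTruth` list: `active_regions_by_state`,
#'   `tf_target_regions`, `region_gene_links`, `de_genes_by_state`, `loci`.
#' @export
plant_truth <- function(catalog, annotation, cfg,
                        n_loci = 4L, regions_per_locus = 50L,
                        n_de_genes_a = 50L, n_de_genes_b = 50L,
                        exclusion_bp = 1.05e6, tf_name = "TF_A",
                        seed = 1L) {
  gr <- catalog$regions
  if (length(gr) == 0L) stop("catalog is empty")
  n_tf <- n_loci * regions_per_locus
  if (cfg$n_regions_active_a > length(gr) ||
      cfg$n_regions_active_b > length(gr) ||
      cfg$n_regions_active_a + cfg$n_regions_active_b > length(gr))
    stop("planted active region counts exceed catalog size")
  if (n_tf > cfg$n_regions_active_a)
    stop("TF target regions must fit within state-A active regions")
  chroms <- unique(as.character(seqnames(gr)))
  sl <- seqlengths(gr)[chroms]
  ## locus centres: spread round-robin across chromosomes
  loci_chrom <- rep(chroms, length.out = n_loci)
  centers <- unlist(lapply(chroms, function(cc) {
    k <- sum(loci_chrom == cc)
    if (k == 0L) return(numeric())
    setNames((seq_len(k) - 0.5) / k * sl[[cc]], rep(cc, k))
  }))
  with_seed(seed, {
    mid <- (start(gr) + end(gr)) / 2
    gchr <- as.character(seqnames(gr))
    loci <- lapply(seq_len(n_loci), function(l) {
      cc <- names(centers)[l]
      on_c <- annotation$chrom == cc
      gene_i <- which(on_c)[which.min(abs(annotation$tss[on_c] - centers[l]))]
      gene <- annotation[gene_i, ]
      d <- ifelse(gchr == cc, abs(mid - gene$tss), Inf)
      regs <- names(gr)[order(d)[seq_len(regions_per_locus)]]
      list(gene_id = gene$gene_id, chrom = cc, tss = gene$tss, regions = regs)
    })
    tf_regions <- unlist(lapply(loci, `[[`, "regions"))
    locus_genes <- vapply(loci, `[[`, character(1), "gene_id")
    links <- do.call(rbind, lapply(loci, function(l)
      data.frame(region_id = l$regions, gene_id = l$gene_id,
                 stringsAsFactors = FALSE)))
    ## remaining active regions: anywhere outside the TF target set
    pool <- base::setdiff(names(gr), tf_regions)
    extra_a <- sample(pool, cfg$n_regions_active_a - n_tf)
    pool <- base::setdiff(pool, extra_a)
    active_b <- sample(pool, cfg$n_regions_active_b)
    ## differential genes away from every TF target region
    tf_gr <- gr[tf_regions]
    zone <- GRanges(seqnames(tf_gr),
                    IRanges(pmax(1, start(tf_gr) - exclusion_bp),
                            end(tf_gr) + exclusion_bp))
    gene_pt <- GRanges(annotation$chrom,
                       IRanges(annotation$tss + 1L, width = 1L))
    near_tf <- overlapsAny(gene_pt, zone)
    far_genes <- base::setdiff(annotation$gene_id[!near_tf], locus_genes)
    need <- (n_de_genes_a - length(locus_genes)) + n_de_genes_b
    if (need > length(far_genes))
      stop("not enough genes outside the exclusion zones")
    pick <- sample(far_genes, need)
    de_a <- c(locus_genes, pick[seq_len(n_de_genes_a - length(locus_genes))])
    de_b <- pick[(n_de_genes_a - length(locus_genes) + 1L):need]
    truth <- list(
      active_regions_by_state = setNames(
        list(c(tf_regions, extra_a), active_b), cfg$state_names),
      tf_target_regions = setNames(list(tf_regions), tf_name),
      region_gene_links = links,
      de_genes_by_state = setNames(list(de_a, de_b), cfg$state_names),
      loci = loci)
    class(truth) <- "PlantedTruth"
    validate_truth(truth, catalog, annotation)
    truth
  })
}

#' Check that a planted truth is self-consistent with catalog and annotation
#' @keywords internal
validate_truth <- function(truth, catalog, annotation) {
  ids <- names(catalog$regions)
  stopifnot(all(unlist(truth$active_regions_by_state) %in% ids),
            all(unlist(truth$tf_target_regions) %in% ids),
            all(truth$region_gene_links$region_id %in% ids),
            all(truth$region_gene_links$gene_id %in% annotation$gene_id),
            all(unlist(truth$de_genes_by_state) %in% annotation$gene_id))
  ## TF target regions must be active in some state
  act <- unlist(truth$active_regions_by_state)
  stopifnot(all(unlist(truth$tf_target_regions) %in% act))
  invisible(truth)
}

nb_matrix <- function(mu, disp) {
  m <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / disp),
              nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(m) <- "integer"
  m
}

#' Generate two-state NB activity counts over a catalog
#'
#' Background counts are NB(`baseline_mean`, `nb_dispersion`); planted
#' active regions have their mean multiplied by `2^effect_log2fc` in the
#' samples of their state. When no truth is supplied the active sets are
#' sampled here and returned.
#'
#' @param catalog a `RegionCatalog` (non-empty).
#' @param cfg a [state_config()].
#' @param truth optional `PlantedTruth` fixing the active sets.
#' @param seed RNG seed.
#' @return list with `counts` (a `CountMatrix`) and `truth`.
#' @export
generate_activity_counts <- function(catalog, cfg, truth = NULL, seed = 1L) {
  gr <- catalog$regions
  if (length(gr) == 0L) stop("catalog is empty")
  with_seed(seed, {
    if (is.null(truth)) {
      if (cfg$n_regions_active_a + cfg$n_regions_active_b > length(gr))
        stop("planted active region counts exceed catalog size")
      ids <- sample(names(gr), cfg$n_regions_active_a + cfg$n_regions_active_b)
      truth <- structure(list(
        active_regions_by_state = setNames(
          list(ids[seq_len(cfg$n_regions_active_a)],
               ids[cfg$n_regions_active_a + seq_len(cfg$n_regions_active_b)]),
          cfg$state_names),
        tf_target_regions = list(),
        region_gene_links = data.frame(region_id = character(),
                                       gene_id = character()),
        de_genes_by_state = setNames(list(character(), character()),
                                     cfg$state_names)),
        class = "PlantedTruth")
    }
    design <- state_design(cfg)
    mu <- matrix(cfg$baseline_mean, nrow = length(gr), ncol = length(design),
                 dimnames = list(names(gr), names(design)))
    eff <- 2^cfg$effect_log2fc
    for (s in cfg$state_names) {
      act <- truth$active_regions_by_state[[s]]
      mu[act, design == s] <- mu[act, design == s] * eff
    }
    list(counts = count_matrix(nb_matrix(mu, cfg$nb_dispersion), design),
         truth = truth)
  })
}

#' Generate per-region sequences with planted motif instances
#'
#' Background sequence is i.i.d. with the given GC content; each target
#' region receives one motif instance sampled from the PWM at a uniformly
#' chosen offset (recorded in the `offsets` attribute and metadata).
#'
#' @param catalog a `RegionCatalog`.
#' @param x a [pwm()] to plant.
#' @param target_ids region IDs receiving an instance (may be empty).
#' @param background_gc GC fraction in (0, 1) (default 0.41).
#' @param seed RNG seed.
#' @return named `DNAStringSet` with an `offsets` attribute (named integer
#'   vector of 0-based instance offsets for the targets).
#' @export
generate_sequences_with_motifs <- function(catalog, x, target_ids = character(),
                                           background_gc = 0.41, seed = 1L) {
  stopifnot(is(x, "PWM"), background_gc > 0, background_gc < 1)
  gr <- catalog$regions
  if (!all(target_ids %in% names(gr)))
    stop("target_ids must be catalog region IDs")
  L <- ncol(x$mat)
  if (any(width(gr[target_ids]) < L))
    stop("PWM longer than a target region")
  probs <- c((1 - background_gc) / 2, background_gc / 2,
             background_gc / 2, (1 - background_gc) / 2)
  with_seed(seed, {
    widths <- width(gr)
    chars <- sample(DNA, sum(widths), replace = TRUE, prob = probs)
    stops <- cumsum(widths)
    starts <- stops - widths + 1L
    big <- paste(chars, collapse = "")
    seqs <- substring(big, starts, stops)
    names(seqs) <- names(gr)
    offsets <- integer(0)
    if (length(target_ids)) {
      offsets <- vapply(target_ids, function(id) {
        w <- width(gr[id])
        off <- as.integer(floor(runif(1, 0, w - L + 1)))
        inst <- pwm_sample(x, 1L)
        s <- seqs[[id]]
        substr(s, off + 1L, off + L) <- inst
        seqs[[id]] <<- s
        off
      }, integer(1))
      names(offsets) <- target_ids
    }
    out <- DNAStringSet(seqs)
    mcols(out)$planted_offset <- NA_integer_
    if (length(target_ids))
      mcols(out)$planted_offset[match(target_ids, names(out))] <- offsets
    attr(out, "offsets") <- offsets
    out
  })
}

#' Generate two-state NB expression counts
#'
#' Planted differential genes have their mean multiplied by
#' `2^effect_log2fc` in the samples of their state, so genes linked to
#' planted active regions co-vary with their region's activity through the
#' shared state effect; all other genes are independent NB noise.
#'
#' @param annotation gene TSS table.
#' @param cfg a [state_config()].
#' @param truth a `PlantedTruth` (its `de_genes_by_state` drives the
#'   effects; genes referenced by links must exist in the annotation).
#' @param seed RNG seed.
#' @return a `CountMatrix` over genes.
#' @export
generate_expression_counts <- function(annotation, cfg, truth, seed = 1L) {
  stopifnot(all(truth$region_gene_links$gene_id %in% annotation$gene_id))
  design <- state_design(cfg)
  with_seed(seed, {
    mu <- matrix(cfg$baseline_mean, nrow = nrow(annotation),
                 ncol = length(design),
                 dimnames = list(annotation$gene_id, names(design)))
    eff <- 2^cfg$effect_log2fc
    for (s in cfg$state_names) {
      g <- truth$de_genes_by_state[[s]]
      mu[g, design == s] <- mu[g, design == s] * eff
    }
    count_matrix(nb_matrix(mu, cfg$nb_dispersion), design)
  })
}

#' Default planted transcription-factor motif
#'
#' A 10-bp high-information PWM (dominant base probability `p_dominant` per
#' position, default 0.97) used as the planted regulator in the synthetic
#' dataset.
#'
#' @param name feature name.
#' @param p_dominant probability of the consensus base per position.
#' @return a `PWM`.
#' @export
planted_pwm <- function(name = "TF_A", p_dominant = 0.97) {
  cons <- c("T", "G", "A", "C", "G", "T", "C", "A", "T", "C")
  mat <- vapply(cons, function(b) {
    p <- rep((1 - p_dominant) / 3, 4); p[match(b, DNA)] <- p_dominant; p
  }, numeric(4))
  pwm(mat, name = name, pseudo = 0)
}

#' Generate the full default synthetic dataset
#'
#' Ties the generators together: tiled catalog, gene annotation, planted
#' truth, activity and expression counts, region sequences with the planted
#' TF's motif embedded in its target regions, and a decoy motif collection.
#'
#' @param spec a [genome_spec()] (its seed drives every stage).
#' @param cfg a [state_config()].
#' @param n_regions,region_len,n_genes catalog / annotation scale.
#' @param n_decoys decoy PWM count (default 50).
#' @param ... passed to [plant_truth()].
#' @return list with `spec`, `cfg`, `catalog`, `annotation`, `truth`,
#'   `activity` (`CountMatrix`), `expression` (`CountMatrix`), `sequences`,
#'   `pwms` (planted first, then decoys), `design`.
#' @export
synthetic_dataset <- function(spec = genome_spec(), cfg = state_config(),
                              n_regions = 10000L, region_len = 500L,
                              n_genes = 2000L, n_decoys = 50L, ...) {
  catalog <- synthetic_catalog(spec, n_regions, region_len)
  annotation <- synthetic_annotation(spec, n_genes)
  truth <- plant_truth(catalog, annotation, cfg,
                       seed = stage_seed(spec$seed, "truth"), ...)
  act <- generate_activity_counts(catalog, cfg, truth,
                                  seed = stage_seed(spec$seed, "activity"))
  expr <- generate_expression_counts(annotation, cfg, truth,
                                     seed = stage_seed(spec$seed, "expression"))
  tf <- names(truth$tf_target_regions)[1]
  motif <- planted_pwm(tf)
  seqs <- generate_sequences_with_motifs(
    catalog, motif, truth$tf_target_regions[[tf]],
    seed = stage_seed(spec$seed, "sequences"))
  decoys <- with_seed(stage_seed(spec$seed, "decoys"),
                      lapply(seq_len(n_decoys), function(i)
                        pwm_random(8L, name = sprintf("decoy%02d", i))))
  list(spec = spec, cfg = cfg, catalog = catalog, annotation = annotation,
       truth = truth, activity = act$counts, expression = expr,
       sequences = seqs, pwms = c(list(motif), decoys),
       design = state_design(cfg))
}

#' Synthetic three-cluster expression matrix for state classification
#'
#' Two planted transcriptional states plus an immune-like confounder
#' cluster: each cluster has its own marker genes with a strong planted
#' fold change; all other genes are shared NB noise.
#'
#' @param n_per_cluster samples per cluster (default 12, 10, 8).
#' @param n_genes total genes (default 500).
#' @param n_markers marker genes per cluster (default 40).
#' @param marker_log2fc planted marker effect (default 3).
#' @param baseline_mean,nb_dispersion NB parameters.
#' @param seed RNG seed.
#' @return list with `counts` (`CountMatrix` with the cluster design),
#'   `log2` (log-transformed matrix), `labels`, `markers`.
#' @export
synthetic_state_expression <- function(n_per_cluster = c(12L, 10L, 8L),
                                       n_genes = 500L, n_markers = 40L,
                                       marker_log2fc = 3,
                                       baseline_mean = 100,
                                       nb_dispersion = 0.1, seed = 1L) {
  stopifnot(length(n_per_cluster) >= 2L, 3L * n_markers <= n_genes)
  k <- length(n_per_cluster)
  cl_names <- c("proliferative", "invasive", "immune")[seq_len(k)]
  labels <- factor(rep(cl_names, n_per_cluster), levels = cl_names)
  samples <- sprintf("s%02d", seq_along(labels))
  names(labels) <- samples
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    mu <- matrix(baseline_mean, n_genes, length(labels),
                 dimnames = list(genes, samples))
    markers <- lapply(seq_len(k), function(i)
      genes[(i - 1L) * n_markers + seq_len(n_markers)])
    names(markers) <- cl_names
    for (i in seq_len(k))
      mu[markers[[i]], labels == cl_names[i]] <-
        baseline_mean * 2^marker_log2fc
    cm <- count_matrix(nb_matrix(mu, nb_dispersion), labels)
    list(counts = cm, log2 = log_transform(cm), labels = labels,
         markers = markers)
  })
}

#' Write / read a planted-truth object as JSON
#'
#' Serialization round-trips losslessly so planted truth can accompany
#' exported synthetic datasets.
#'
#' @param truth a `PlantedTruth`.
#' @param path JSON file path.
#' @return `read_truth` returns the `PlantedTruth`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(active_regions_by_state = truth$active_regions_by_state,
              tf_target_regions = truth$tf_target_regions,
              region_gene_links = truth$region_gene_links,
              de_genes_by_state = truth$de_genes_by_state)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$region_gene_links <- as.data.frame(obj$region_gene_links,
                                         stringsAsFactors = FALSE)
  obj$active_regions_by_state <- lapply(obj$active_regions_by_state,
                                        as.character)
  obj$tf_target_regions <- lapply(obj$tf_target_regions, as.character)
  obj$de_genes_by_state <- lapply(obj$de_genes_by_state, as.character)
  class(obj) <- "PlantedTruth"
  obj
}
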