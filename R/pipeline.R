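## End-to-end orchestration with deterministic seeding and JSON manifests.
##
## The demo pipeline runs on synthetic data: feature tracks -> catalog ->
## planted truth, counts and sequences -> differential regions and genes ->
## motif enrichment -> region-to-gene assignment -> TF network -> report.
## Every stage writes its outputs plus a manifest (parameters, seed, input
## checksums, output checksums, package version, no timestamps), so a rerun
## with the same config is bit-identical and partial inputs can be audited.

#' Default pipeline configuration
#'
#' Thresholds default to the study values: signature cutoffs |log2FC| >= 1
#' and adjusted p <= 0.05, recovery cutoff 0.25%, assignment at 1 Mb /
#' ge 0.1 / corr 0.3 absolute. The demo scale keeps the run in seconds.
#'
#' @param seed global seed fanned out per stage via [stage_seed()].
#' @param ... overrides of the defaults (see the returned list).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
    n_tracks = 3L, track_density = 100, insulator_density = 2,
    exon_density = 8,
    n_regions = 2000L, region_len = 500L, n_genes = 400L,
    n_state_a = 9L, n_state_b = 2L,
    n_regions_active_a = 200L, n_regions_active_b = 200L,
    effect_log2fc = 2, nb_dispersion = 0.1, baseline_mean = 100,
    n_loci = 4L, regions_per_locus = 10L,
    n_de_genes_a = 12L, n_de_genes_b = 12L, exclusion_bp = 1.05e6,
    n_decoys = 15L,
    lfc_min = 1, padj_max = 0.05, support_q = 0.05,
    cutoff_frac = 0.0025,
    assign_max_dist = 1e6, assign_ge_alpha = 0.1, assign_corr_min = 0.3,
    assign_corr_mode = "absolute")
  over <- list(...)
  unknown <- base::setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

write_manifest <- function(dir, stage, params, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(packageVersion("regland")),
              params = params,
              input_checksums = as.list(file_checksums(inputs)),
              output_checksums = as.list(file_checksums(outputs)))
  jsonlite::write_json(man, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the demo pipeline end-to-end
#'
#' Stages run in dependency order (simulate -> catalog -> differential ->
#' enrichment -> assignment -> network -> report); outputs and JSON
#' manifests are written under `out_dir`. Reruns with the same config are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(is(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  ## --- simulate: toy genome, tracks, truth-bearing dataset -------------
  spec <- genome_spec(names(config$chrom_lengths), config$chrom_lengths,
                      seed = config$seed)
  trk <- generate_feature_tracks(spec, n_tracks = config$n_tracks,
                                 density = config$track_density,
                                 insulator_density = config$insulator_density,
                                 exon_density = config$exon_density)
  for (i in seq_along(trk$tracks))
    write_bed(trk$tracks[[i]], p(sprintf("track%d.bed", i)))
  write_bed(trk$insulators, p("insulators.bed"))
  write_bed(trk$exons, p("exons.bed"))

  ## --- catalog: merge/blacklist/split/filter/extend --------------------
  catalog <- build_catalog(trk$tracks, trk$insulators, trk$exons,
                           provenance = names(trk$tracks))
  write_bed(catalog, p("catalog.bed"))
  write_manifest(out_dir, "catalog", catalog$build_params,
                 p(sprintf("track%d.bed", seq_along(trk$tracks))),
                 p("catalog.bed"))

  ## --- simulate counts and sequences on the built catalog --------------
  cfg <- state_config(config$n_state_a, config$n_state_b,
                      min(config$n_regions_active_a, length(catalog$regions) %/% 4L),
                      min(config$n_regions_active_b, length(catalog$regions) %/% 4L),
                      config$effect_log2fc, config$nb_dispersion,
                      config$baseline_mean)
  annotation <- synthetic_annotation(spec, config$n_genes)
  truth <- plant_truth(catalog, annotation, cfg,
                       n_loci = config$n_loci,
                       regions_per_locus = config$regions_per_locus,
                       n_de_genes_a = config$n_de_genes_a,
                       n_de_genes_b = config$n_de_genes_b,
                       exclusion_bp = config$exclusion_bp,
                       seed = stage_seed(config$seed, "truth"))
  act <- generate_activity_counts(catalog, cfg, truth,
                                  seed = stage_seed(config$seed, "activity"))
  expr <- generate_expression_counts(annotation, cfg, truth,
                                     seed = stage_seed(config$seed, "expression"))
  tf <- names(truth$tf_target_regions)[1]
  motif <- planted_pwm(tf)
  seqs <- generate_sequences_with_motifs(catalog, motif,
                                         truth$tf_target_regions[[tf]],
                                         seed = stage_seed(config$seed, "sequences"))
  write_count_matrix(act$counts, p("region_counts.tsv"), p("design.tsv"))
  write_count_matrix(expr, p("gene_counts.tsv"))
  writeXStringSet(seqs, p("region_sequences.fa"))
  write_truth(truth, p("truth.json"))
  write_tss_bed(annotation, p("genes.bed"))
  write_manifest(out_dir, "simulate",
                 list(seed = config$seed, n_genes = config$n_genes),
                 p("catalog.bed"),
                 p(c("region_counts.tsv", "gene_counts.tsv", "design.tsv",
                     "region_sequences.fa", "truth.json", "genes.bed")))

  ## --- differential regions and genes ----------------------------------
  regions_diff <- differential_regions(act$counts,
                                       padj_max = config$padj_max,
                                       lfc_min = config$lfc_min,
                                       support_q = config$support_q)
  genes_diff <- nb_differential(expr)
  signatures <- define_signature(genes_diff, config$lfc_min,
                                 config$padj_max, cfg$state_names)
  write_tsv(regions_diff$table, p("regions_differential.tsv"))
  write_tsv(genes_diff, p("genes_differential.tsv"))
  write_manifest(out_dir, "differential",
                 list(padj_max = config$padj_max, lfc_min = config$lfc_min,
                      support_q = config$support_q),
                 p(c("region_counts.tsv", "gene_counts.tsv")),
                 p(c("regions_differential.tsv", "genes_differential.tsv")))

  ## --- enrichment over the state-A foreground ---------------------------
  foreground <- regions_diff[[cfg$state_names[1]]]
  pwms <- c(list(motif),
            with_seed(stage_seed(config$seed, "decoys"),
                      lapply(seq_len(config$n_decoys), function(i)
                        pwm_random(8L, name = sprintf("decoy%02d", i)))))
  rankings <- lapply(pwms, function(pw)
    rank_regions(scan_pwm(seqs, pw), feature = pw$name, kind = "motif",
                 tie_seed = stage_seed(config$seed, pw$name)))
  enr <- enrich_features(rankings, foreground,
                         cutoff_frac = config$cutoff_frac)
  write_tsv(enr$results, p("enrichment.tsv"))
  write_manifest(out_dir, "enrichment",
                 list(cutoff_frac = config$cutoff_frac,
                      n_features = length(pwms)),
                 p("region_sequences.fa"), p("enrichment.tsv"))

  ## --- assignment and TF network ----------------------------------------
  act_log <- log_transform(act$counts)
  expr_log <- log_transform(expr)
  diff_ids <- unlist(regions_diff[cfg$state_names], use.names = FALSE)
  params <- assignment_params(config$assign_max_dist, config$assign_ge_alpha,
                              config$lfc_min, config$assign_corr_min,
                              config$assign_corr_mode)
  links <- assign_regions_to_genes(catalog$regions[diff_ids], annotation,
                                   genes_diff, act_log, expr_log, params)
  top_feature <- enr$results$feature[1]
  net <- build_tf_network(top_feature, enr$targets[[top_feature]], links)
  write_tsv(links, p("links.tsv"))
  write_tsv(net$links, p("network_links.tsv"))
  write_manifest(out_dir, "assignment", unclass(params),
                 p(c("regions_differential.tsv", "genes_differential.tsv")),
                 p(c("links.tsv", "network_links.tsv")))

  ## --- report ------------------------------------------------------------
  rep <- pipeline_report(catalog, regions_diff, signatures, enr, links, net,
                         cfg)
  writeLines(rep$text, p("report.txt"))
  write_tsv(rep$table, p("report.tsv"))
  write_manifest(out_dir, "report", list(),
                 p(c("enrichment.tsv", "links.tsv")),
                 p(c("report.txt", "report.tsv")))
  invisible(list(catalog = catalog, truth = truth,
                 regions_diff = regions_diff, genes_diff = genes_diff,
                 signatures = signatures, enrichment = enr, links = links,
                 network = net, report = rep))
}

#' Summary report of a pipeline run
#'
#' Machine-readable table plus human-readable lines mirroring the headline
#' numbers: catalog size, differential region counts, top features by NES,
#' assignment coverage and network size. Percentages are printed to the
#' nearest integer, with one decimal when below 10% (where integer
#' rounding would lose most of the signal).
#'
#' @param catalog,regions_diff,signatures,enr,links,net,cfg stage outputs.
#' @return list with `table` (data.frame metric/value) and `text`.
#' @export
pipeline_report <- function(catalog, regions_diff, signatures, enr, links,
                            net, cfg) {
  st <- catalog_stats(catalog)
  nA <- length(regions_diff[[cfg$state_names[1]]])
  nB <- length(regions_diff[[cfg$state_names[2]]])
  n_diff <- nA + nB
  cov_pct <- if (n_diff > 0) {
    raw <- 100 * length(unique(links$region_id)) / n_diff
    assignment_coverage(links, n_diff, digits = if (raw < 10) 1 else 0)
  } else 0
  tab <- data.frame(
    metric = c("catalog_regions", "catalog_mean_length",
               paste0("regions_", cfg$state_names[1]),
               paste0("regions_", cfg$state_names[2]),
               paste0("signature_", cfg$state_names[1]),
               paste0("signature_", cfg$state_names[2]),
               "top_feature_nes", "assigned_region_pct",
               "network_links", "network_genes"),
    value = c(st$n, round(st$mean_length, 1), nA, nB,
              length(signatures[[1]]), length(signatures[[2]]),
              round(enr$results$nes[1], 2), cov_pct,
              nrow(net$links), length(net$target_genes)),
    stringsAsFactors = FALSE)
  text <- c(
    sprintf("Catalog: %d regions, mean length %.1f bp", st$n,
            st$mean_length),
    sprintf("Differential regions: %d %s / %d %s", nA, cfg$state_names[1],
            nB, cfg$state_names[2]),
    sprintf("Signatures: %d / %d genes", length(signatures[[1]]),
            length(signatures[[2]])),
    sprintf("Top feature: %s (NES %.2f)", enr$results$feature[1],
            enr$results$nes[1]),
    sprintf("Assigned regions: %s%%", format(cov_pct)),
    sprintf("Network '%s': %d links to %d genes", net$tf_name,
            nrow(net$links), length(net$target_genes)))
  list(table = tab, text = text)
}
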