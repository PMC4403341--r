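## Plain-text I/O: TSV count matrices, design tables, result tables and
## gene TSS tables. Matrices are written with an `id` first column; design
## tables are two columns (sample, state). All readers return the package's
## native containers.

#' Write / read a count matrix as TSV
#'
#' @param cm a `CountMatrix` (or plain matrix for `write_matrix_tsv`).
#' @param path file path.
#' @param design_path design-table path (written/read alongside for a
#'   `CountMatrix`).
#' @return `read_count_matrix` returns a `CountMatrix`.
#' @export
write_count_matrix <- function(cm, path, design_path = NULL) {
  m <- if (is(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is(cm, "CountMatrix") && !is.null(design_path))
    write_design(cm$design, design_path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, design_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  count_matrix(m, read_design(design_path))
}

#' Write / read a sample design table (columns: sample, state)
#' @param design named factor/character.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  write.table(data.frame(sample = names(design),
                         state = as.character(design)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(factor(df$state, levels = unique(df$state)), df$sample)
}

#' Write a result data.frame as TSV
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a gene TSS table as BED6 (0-based)
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param path file path.
#' @export
write_tss_bed <- function(tss_table, path) {
  df <- data.frame(tss_table$chrom, tss_table$tss, tss_table$tss + 1L,
                   tss_table$gene_id, 0L,
                   tss_table$strand %||% "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = df$V4, chrom = df$V1, tss = df$V2, strand = df$V6,
             stringsAsFactors = FALSE)
}
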