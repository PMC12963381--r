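#' Write a cohort dataset to the MTX + TSV sidecar layout
#'
#' Writes `matrix.mtx` (Matrix Market), `features.tsv`, `barcodes.tsv`,
#' `cell_metadata.tsv` and `donor_metadata.tsv` into `dir`.
#'
#' @param ds a `cohort_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ds, dir) {
  stopifnot(inherits(ds, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "barcodes.tsv"))
  write.table(ds$cell_meta, file.path(dir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$donor_meta, file.path(dir, "donor_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort dataset from the MTX + TSV sidecar layout
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  gene_ids <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  cell_meta <- read.delim(file.path(dir, "cell_metadata.tsv"),
                          stringsAsFactors = FALSE)
  donor_meta <- read.delim(file.path(dir, "donor_metadata.tsv"),
                           stringsAsFactors = FALSE)
  donor_meta$pathology_group <- factor(donor_meta$pathology_group,
                                       levels = c("low", "intermediate",
                                                  "high"))
  structure(list(counts = counts, gene_ids = gene_ids,
                 cell_meta = cell_meta, donor_meta = donor_meta),
            class = "cohort_dataset")
}

#' Write a spatial dataset as cells.csv + counts.mtx
#' @param sd a `spatial_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spatial <- function(sd, dir) {
  stopifnot(inherits(sd, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sd$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  Matrix::writeMM(sd$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(sd$counts), file.path(dir, "panel_genes.tsv"))
  invisible(dir)
}

#' Read a spatial dataset written by [write_spatial()]
#' @param dir input directory.
#' @return a `spatial_dataset`.
#' @export
read_spatial <- function(dir) {
  cells <- read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "panel_genes.tsv"))
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells), class = "spatial_dataset")
}

#' Write calcium traces as long-format CSV (trace_id, t_s, F)
#' @param cts a `calcium_trace_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_calcium <- function(cts, dir) {
  stopifnot(inherits(cts, "calcium_trace_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(names(cts$traces), function(id) {
    f <- cts$traces[[id]]
    data.frame(trace_id = id,
               t_s = (seq_along(f) - 1) / cts$rate_hz,
               F = f, stringsAsFactors = FALSE)
  }))
  write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(cts$meta, file.path(dir, "trace_metadata.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read calcium traces written by [write_calcium()]
#' @param dir input directory.
#' @param rate_hz sampling rate; inferred from time stamps when `NULL`.
#' @return a `calcium_trace_set` (without ground truth).
#' @export
read_calcium <- function(dir, rate_hz = NULL) {
  long <- read.csv(file.path(dir, "traces.csv"), stringsAsFactors = FALSE)
  meta <- read.csv(file.path(dir, "trace_metadata.csv"),
                   stringsAsFactors = FALSE)
  ids <- unique(long$trace_id)
  traces <- lapply(ids, function(id) long$F[long$trace_id == id])
  names(traces) <- ids
  if (is.null(rate_hz)) {
    ts <- long$t_s[long$trace_id == ids[1]]
    rate_hz <- 1 / stats::median(diff(ts))
  }
  structure(list(traces = traces, rate_hz = rate_hz, meta = meta,
                 truth = NULL),
            class = "calcium_trace_set")
}

#' Write ground truth to JSON
#' @param truth a `ground_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
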