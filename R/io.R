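# Readers/writers: MTX count bundles, events CSV, plain-text stacks + YAML
# sidecar, trend CSV. Coordinates are um with a 0-based pixel origin; times
# are hours from experiment start; gene ids are case-sensitive strings.

#' Write an expression bundle to a directory (MTX + TSV)
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv`,
#' `cells.tsv` (cell metadata), and `spliced.mtx` / `unspliced.mtx` when the
#' layers are present.
#'
#' @param bundle An `expression_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(bundle, dir) {
  stopifnot(inherits(bundle, "expression_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f)
    Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(m, sparse = TRUE)),
                                "CsparseMatrix"),
                    file.path(dir, f))
  wr(bundle$counts, "matrix.mtx")
  if (!is.null(bundle$spliced)) wr(bundle$spliced, "spliced.mtx")
  if (!is.null(bundle$unspliced)) wr(bundle$unspliced, "unspliced.mtx")
  utils::write.table(bundle$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression bundle from a directory
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv` and
#'   optionally `spliced.mtx` / `unspliced.mtx`.
#' @return An `expression_bundle` (counts as integer sparse matrices,
#'   cells x genes).
#' @export
read_counts <- function(dir) {
  need <- c("matrix.mtx", "genes.tsv", "cells.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("missing required file: %s", f))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  rd <- function(f) {
    m <- Matrix::t(Matrix::readMM(file.path(dir, f)))  # -> cells x genes
    if (nrow(m) != nrow(cells) || ncol(m) != nrow(genes))
      stop(sprintf("shape mismatch between %s (%d x %d) and annotations (%d cells, %d genes)",
                   f, nrow(m), ncol(m), nrow(cells), nrow(genes)))
    dimnames(m) <- list(cells$cell_id, genes$gene)
    methods::as(m, "CsparseMatrix")
  }
  counts <- rd("matrix.mtx")
  spl <- if (file.exists(file.path(dir, "spliced.mtx"))) rd("spliced.mtx") else NULL
  uns <- if (file.exists(file.path(dir, "unspliced.mtx"))) rd("unspliced.mtx") else NULL
  structure(list(counts = counts, spliced = spl, unspliced = uns,
                 cell_meta = cells, gene_meta = genes, norm = NULL),
            class = "expression_bundle")
}

#' Write an event table to CSV
#'
#' @param events Event `data.frame` (from a `basal_sim` or compatible).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an event table
#'
#' Schema: `event_id, type, time_h, x_um, y_um, cell_id, daughter1,
#' daughter2, cause_event_id`. Division rows must carry exactly two
#' daughters; delaminations none.
#'
#' @param path CSV path.
#' @return Validated event `data.frame`.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "type", "time_h", "x_um", "y_um", "cell_id",
            "daughter1", "daughter2", "cause_event_id")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events CSV lacks columns: ", paste(miss, collapse = ", "))
  if (!all(ev$type %in% c("division", "delamination")))
    stop("unknown event type(s)")
  if (!is.numeric(ev$time_h) || !is.numeric(ev$x_um) || !is.numeric(ev$y_um))
    stop("time/position columns must be numeric")
  div <- ev$type == "division"
  if (any(div & (is.na(ev$daughter1) | is.na(ev$daughter2))))
    stop("schema error: division rows must list exactly two daughters")
  if (any(!div & (!is.na(ev$daughter1) | !is.na(ev$daughter2))))
    stop("schema error: delamination rows must not list daughters")
  ev
}

#' Write a list of image stacks as plain-text volumes with a YAML sidecar
#'
#' Each frame becomes `frame_###.json` (dims plus flattened channel
#' intensities); `stack.yaml` records channel names, voxel size and frame
#' times. A plain-text stand-in for multi-page TIFF, which has no reader in
#' this R stack.
#'
#' @param stacks List of [image_stack()] objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_stack_dir <- function(stacks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    jsonlite::write_json(
      list(dim = st$dim,
           channels = lapply(st$channels, function(a) as.vector(a))),
      file.path(dir, sprintf("frame_%03d.json", i)),
      auto_unbox = FALSE, digits = 8)
  }
  yaml::write_yaml(
    list(channels = names(stacks[[1]]$channels),
         voxel_size_um = as.numeric(stacks[[1]]$voxel_size_um),
         frame_times_h = vapply(stacks, `[[`, numeric(1), "frame_time_h")),
    file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' Read a stack directory written by [write_stack_dir()]
#'
#' Validates the sidecar (channel names present, frame times strictly
#' increasing) and rebuilds the [image_stack()] list.
#'
#' @param dir Stack directory.
#' @return List of `image_stack` objects.
#' @export
read_stack_dir <- function(dir) {
  side <- file.path(dir, "stack.yaml")
  if (!file.exists(side)) stop("missing sidecar stack.yaml")
  meta <- yaml::read_yaml(side)
  if (is.null(meta$channels) || !length(meta$channels))
    stop("sidecar lists no channels")
  times <- as.numeric(meta$frame_times_h)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times are not strictly increasing")
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.json$",
                           full.names = TRUE))
  if (length(files) != length(times))
    stop("frame count differs from sidecar frame_times_h")
  lapply(seq_along(files), function(i) {
    fr <- jsonlite::read_json(files[i], simplifyVector = TRUE)
    dims <- as.integer(fr$dim)
    chans <- lapply(fr$channels, function(v) array(as.numeric(v), dim = dims))
    if (!identical(sort(names(chans)), sort(unlist(meta$channels))))
      stop("channel names differ between frames and sidecar")
    image_stack(chans[unlist(meta$channels)],
                voxel_size_um = as.numeric(meta$voxel_size_um),
                frame_time_h = times[i])
  })
}

#' Read a genotype trend table
#'
#' @param path CSV with columns `Y`, `X`, `G` (and optionally `region_id`).
#' @return Validated `data.frame`.
#' @export
read_trend <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("Y", "X", "G"), names(tb))
  if (length(miss)) stop("trend CSV lacks columns: ", paste(miss, collapse = ", "))
  if (any(tb$Y < 0) || any(tb$X < 0)) stop("Y and X must be non-negative")
  tb
}
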