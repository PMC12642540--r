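#' Load a spatial perturbation dataset from disk
#'
#' Supported formats:
#' \describe{
#'   \item{csv_triplet}{a directory with `counts.csv` (spots x genes,
#'     first column spot_id, header row gene names), `coords.csv`
#'     (spot_id,x,y\[,z\]) and `attrs.csv` (spot_id,perturbation
#'     \[,disease,slide,time...\]).}
#'   \item{mtx_triplet}{a directory with `matrix.mtx` (genes x spots or
#'     spots x genes, auto-oriented via the sidecars), `barcodes.tsv`,
#'     `features.tsv`, plus the same `coords.csv`/`attrs.csv` sidecars.}
#'   \item{h5ad}{an AnnData file; counts in `X` (or `layers/counts`),
#'     coordinates under `obsm/spatial`, attributes as `obs` columns.
#'     Read through the bundled Python helper (requires `python` with
#'     `anndata` on the PATH).}
#' }
#'
#' @param path file (h5ad) or directory (triplets).
#' @param format one of `"csv_triplet"`, `"mtx_triplet"`, `"h5ad"`.
#' @return a validated [spatial_dataset()].
#' @export
load_dataset <- function(path, format = c("csv_triplet", "mtx_triplet", "h5ad")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  switch(format,
    csv_triplet = load_csv_triplet(path),
    mtx_triplet = load_mtx_triplet(path),
    h5ad = load_h5ad(path)
  )
}

read_sidecars <- function(dir, spot_ids) {
  cpath <- file.path(dir, "coords.csv")
  apath <- file.path(dir, "attrs.csv")
  if (!file.exists(cpath)) stop("missing coords.csv: coordinates are required")
  coords_df <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  attrs_df <- if (file.exists(apath)) {
    utils::read.csv(apath, stringsAsFactors = FALSE)
  } else stop("missing attrs.csv: perturbation labels are required")

  m <- match(spot_ids, coords_df$spot_id)
  if (anyNA(m)) {
    stop(sprintf("spot(s) lacking coordinates: %s",
                 paste(spot_ids[is.na(m)], collapse = ", ")))
  }
  coords <- as.matrix(coords_df[m, setdiff(names(coords_df), "spot_id"), drop = FALSE])
  ma <- match(spot_ids, attrs_df$spot_id)
  if (anyNA(ma)) {
    stop(sprintf("spot(s) lacking attributes: %s",
                 paste(spot_ids[is.na(ma)], collapse = ", ")))
  }
  attrs <- attrs_df[ma, , drop = FALSE]
  if (!"perturbation" %in% names(attrs)) stop("attrs.csv must have a 'perturbation' column")
  cat_cols <- intersect(c("disease", "slide"), names(attrs))
  num_cols <- setdiff(names(attrs), c("spot_id", "perturbation", cat_cols))
  continuous <- if (length(num_cols) > 0) {
    stats::setNames(lapply(num_cols, function(nm) as.numeric(attrs[[nm]])), num_cols)
  } else NULL
  list(coords = coords,
       perturbation = attrs$perturbation,
       disease = if ("disease" %in% cat_cols) attrs$disease else NULL,
       slide = if ("slide" %in% cat_cols) attrs$slide else NULL,
       continuous = continuous)
}

load_csv_triplet <- function(dir) {
  cpath <- file.path(dir, "counts.csv")
  if (!file.exists(cpath)) stop("missing counts.csv")
  df <- utils::read.csv(cpath, stringsAsFactors = FALSE, check.names = FALSE)
  spot_ids <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- spot_ids
  side <- read_sidecars(dir, spot_ids)
  spatial_dataset(counts, side$coords, side$perturbation,
                  disease = side$disease, slide = side$slide,
                  continuous = side$continuous,
                  gene_names = colnames(counts), spot_ids = spot_ids)
}

load_mtx_triplet <- function(dir) {
  mpath <- file.path(dir, "matrix.mtx")
  if (!file.exists(mpath)) stop("missing matrix.mtx")
  m <- as.matrix(Matrix::readMM(mpath))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  features <- vapply(strsplit(features, "\t"), `[[`, character(1), 1)
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- t(m)  # CellRanger orientation: genes x spots
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop("matrix.mtx dimensions match neither barcodes x features nor features x barcodes")
  }
  rownames(m) <- barcodes
  colnames(m) <- features
  side <- read_sidecars(dir, barcodes)
  spatial_dataset(m, side$coords, side$perturbation,
                  disease = side$disease, slide = side$slide,
                  continuous = side$continuous,
                  gene_names = features, spot_ids = barcodes)
}

#' Save a spatial_dataset to disk
#'
#' @param ds a `spatial_dataset`.
#' @param path output directory (triplets) or file (h5ad).
#' @param format as in [load_dataset()].
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, format = c("csv_triplet", "mtx_triplet", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad") return(save_h5ad(ds, path))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  coords_df <- data.frame(spot_id = ds$spot_ids, ds$coords)
  names(coords_df) <- c("spot_id", c("x", "y", "z")[seq_len(ncol(ds$coords))])
  utils::write.csv(coords_df, file.path(path, "coords.csv"), row.names = FALSE)
  attrs_df <- data.frame(spot_id = ds$spot_ids,
                         perturbation = as.character(ds$perturbation),
                         disease = as.character(ds$disease),
                         slide = as.character(ds$slide),
                         stringsAsFactors = FALSE)
  if (!is.null(ds$continuous))
    for (nm in names(ds$continuous)) attrs_df[[nm]] <- ds$continuous[[nm]]
  utils::write.csv(attrs_df, file.path(path, "attrs.csv"), row.names = FALSE)
  if (format == "csv_triplet") {
    cdf <- data.frame(spot_id = ds$spot_ids, ds$counts, check.names = FALSE)
    names(cdf) <- c("spot_id", ds$gene_names)
    utils::write.csv(cdf, file.path(path, "counts.csv"), row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(ds$counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(ds$spot_ids, file.path(path, "barcodes.tsv"))
    writeLines(ds$gene_names, file.path(path, "features.tsv"))
  }
  invisible(path)
}

h5ad_helper <- function() {
  system.file("python", "h5ad_io.py", package = "nichegp", mustWork = TRUE)
}

run_h5ad_helper <- function(args) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("h5ad I/O requires a `python` with the anndata package on the PATH")
  out <- suppressWarnings(system2(py, c(h5ad_helper(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(sprintf("h5ad helper failed:\n%s", paste(out, collapse = "\n")))
  }
  invisible(out)
}

load_h5ad <- function(path) {
  tmp <- tempfile("h5ad_io_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_h5ad_helper(c("export", shQuote(path), shQuote(tmp)))
  load_csv_triplet(tmp)
}

save_h5ad <- function(ds, path) {
  tmp <- tempfile("h5ad_io_")
  save_dataset(ds, tmp, format = "csv_triplet")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_h5ad_helper(c("import", shQuote(tmp), shQuote(path)))
  invisible(path)
}
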