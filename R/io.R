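# Readers and writers: NIfTI-1 volumes and masks, realignment-parameter
# text files, plain-text time series, estimate tables.

#' Construct a 4-D volume dataset
#'
#' Carrier for all voxelwise operations: the 4-D data array, the
#' repetition time, named 3-D logical masks on the same grid, and an
#' optional nuisance-design source.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param tr_seconds repetition time in seconds.
#' @param masks named list of 3-D logical arrays (conventionally `brain`,
#'   `gm`, `wm`, `csf`) matching the spatial grid.
#' @param motion optional n_volumes x 6 motion-parameter matrix.
#' @return object of class `volume_dataset`.
#' @export
volume_dataset <- function(data, tr_seconds, masks = list(), motion = NULL) {
  if (length(dim(data)) != 4) stop("data must be a 4-D array (x, y, z, t)")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  grid <- dim(data)[1:3]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(as.integer(dim(m)), as.integer(grid)))
      stop(sprintf("mask '%s' grid (%s) does not match data grid (%s)",
                   nm, paste(dim(m), collapse = "x"),
                   paste(grid, collapse = "x")))
    masks[[nm]] <- array(as.logical(m), dim = grid)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != dim(data)[4])
      stop("motion rows must equal the number of volumes")
  }
  structure(list(data = data, tr_seconds = tr_seconds, masks = masks,
                 motion = motion),
            class = "volume_dataset")
}

#' @export
print.volume_dataset <- function(x, ...) {
  cat(sprintf("<volume_dataset> %s, TR = %g s, masks: %s\n",
              paste(dim(x$data), collapse = " x "), x$tr_seconds,
              if (length(x$masks)) paste(names(x$masks), collapse = ", ")
              else "(none)"))
  invisible(x)
}

# Series of one voxel as a numeric vector.
voxel_series <- function(vol, i, j, k) as.numeric(vol$data[i, j, k, ])

#' Read a 4-D NIfTI volume with companion masks
#'
#' The repetition time is taken from the NIfTI header (`pixdim[4]`)
#' unless overridden; masks are loaded from companion paths and checked
#' against the data grid.
#'
#' @param path NIfTI-1 file containing a 4-D image.
#' @param mask_paths named character vector of mask NIfTI paths (e.g.
#'   `c(brain = "...", gm = "...")`).
#' @param tr_seconds optional TR override in seconds (takes precedence
#'   over the header and is recorded in the `tr_source` attribute).
#' @param motion optional motion-parameter file path, read with
#'   [read_motion()].
#' @return a [volume_dataset()].
#' @export
read_volume <- function(path, mask_paths = NULL, tr_seconds = NULL,
                        motion = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3)
    stop("expected a 4-D image but '", path, "' is 3-D")
  if (length(dim(arr)) != 4) stop("expected a 4-D image in ", path)
  hdr_tr <- RNifti::pixdim(img)[4]
  tr_source <- "header"
  if (!is.null(tr_seconds)) {
    tr_source <- "override"
  } else {
    tr_seconds <- hdr_tr
  }
  if (!is.numeric(tr_seconds) || is.na(tr_seconds) || tr_seconds <= 0)
    stop("no usable TR in header; pass tr_seconds explicitly")
  masks <- list()
  for (nm in names(mask_paths)) {
    marr <- as.array(RNifti::readNifti(mask_paths[[nm]]))
    if (!identical(as.integer(dim(marr)[1:3]), as.integer(dim(arr)[1:3])))
      stop(sprintf("mask '%s' grid (%s) does not match data grid (%s)",
                   nm, paste(dim(marr), collapse = "x"),
                   paste(dim(arr)[1:3], collapse = "x")))
    masks[[nm]] <- array(marr != 0, dim = dim(arr)[1:3])
  }
  mot <- if (!is.null(motion)) read_motion(motion, n_volumes = dim(arr)[4])
  vol <- volume_dataset(arr, tr_seconds, masks, mot)
  attr(vol, "tr_source") <- tr_source
  attr(vol, "affine") <- RNifti::xform(img)
  vol
}

#' Write a volume dataset (and masks) as NIfTI
#'
#' @param vol a [volume_dataset()].
#' @param path output path for the 4-D data.
#' @param mask_dir optional directory to write each mask as
#'   `mask_<name>.nii.gz`.
#' @return invisibly, the paths written.
#' @export
write_volume <- function(vol, path, mask_dir = NULL) {
  img <- RNifti::asNifti(vol$data)
  pd <- RNifti::pixdim(img)
  pd[4] <- vol$tr_seconds
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  written <- path
  if (!is.null(mask_dir)) {
    dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(vol$masks)) {
      p <- file.path(mask_dir, paste0("mask_", nm, ".nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(vol$masks[[nm]] * 1L), p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Read realignment parameters
#'
#' Whitespace-delimited text with six numeric columns (translations in
#' mm, rotations in radians), one row per volume; blank lines and lines
#' starting with `#` are tolerated and skipped.
#'
#' @param path text file path.
#' @param n_volumes expected row count (checked when given).
#' @return numeric matrix n x 6.
#' @export
read_motion <- function(path, n_volumes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1 || ncols != 6)
    stop(sprintf("motion file must have exactly 6 numeric columns, found %s",
                 paste(ncols, collapse = "/")))
  m <- matrix(as.numeric(unlist(parts)), ncol = 6, byrow = TRUE)
  if (anyNA(m)) stop("motion file contains non-numeric entries")
  if (!is.null(n_volumes) && nrow(m) != n_volumes)
    stop(sprintf("motion file has %d rows but %d volumes expected",
                 nrow(m), n_volumes))
  colnames(m) <- paste0("mot", 1:6)
  m
}

#' Write realignment parameters in the rp_*.txt dialect
#'
#' @param motion n x 6 numeric matrix.
#' @param path output path.
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  write.table(format(motion, digits = 10, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time series from plain text or CSV
#'
#' Accepts a single column of decimal text or a CSV with one series per
#' column (header optional). Missing values are rejected.
#'
#' @param path file path.
#' @return numeric matrix, one series per column.
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^[-+0-9.eE,[:space:]]+$", first)
  df <- read.table(path, sep = sep, header = header,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("time series input contains missing or non-numeric values")
  m
}

#' Write a table of Hurst estimates as CSV
#'
#' @param batch a `hurst_batch` from [hurst_all()] (or a data.frame
#'   already in table form).
#' @param path output path.
#' @return invisibly, the data frame written (columns `estimator_id`,
#'   `H`, `slope`, `r2`, `n_scales`).
#' @export
write_estimates <- function(batch, path) {
  df <- if (is.data.frame(batch)) batch else as.data.frame(batch)
  out <- df[, intersect(c("series", "estimator_id", "H", "slope", "r2",
                          "n_scales"), names(df))]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}
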