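#' Read and write multi-page TIFF stacks
#'
#' Movies are stored T x Y x X and z-stacks Z x Y x X as 16-bit multi-page
#' TIFF. The leading-axis meaning (T or Z) is declared in a YAML sidecar or
#' by the caller, never inferred from TIFF tags. Values are stored as
#' unsigned 16-bit integers; writing rounds and clamps to [0, 65535].
#'
#' @param path TIFF file path.
#' @param axes Declared leading axis, `"T"` or `"Z"`; overrides the sidecar.
#' @param sidecar Optional YAML sidecar path (default `<path>.yaml` if it
#'   exists) with fields `axes` and voxel sizes.
#' @return For readers, a numeric array with attributes `axes` and any
#'   sidecar metadata in `attr(, "meta")`.
#' @export
load_stack <- function(path, axes = NULL, sidecar = NULL) {
  if (!file.exists(path))
    rlang::abort(sprintf("TIFF file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0) rlang::abort("TIFF file has no pages.")
  meta <- NULL
  if (is.null(sidecar)) {
    cand <- paste0(path, ".yaml")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar) && file.exists(sidecar))
    meta <- yaml::read_yaml(sidecar)
  if (is.null(axes)) axes <- meta$axes
  if (is.null(axes))
    rlang::abort("Leading axis is ambiguous: declare `axes` (\"T\" or \"Z\") or provide a sidecar.")
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1:2]))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[k, , ] <- pg
  }
  attr(arr, "axes") <- axes
  attr(arr, "meta") <- meta
  arr
}

#' @rdname load_stack
#' @export
load_movie <- function(path, sidecar = NULL) {
  load_stack(path, axes = "T", sidecar = sidecar)
}

#' @rdname load_stack
#' @param stack Numeric array (T|Z x Y x X) to write.
#' @param meta Optional list written to the YAML sidecar alongside `axes`.
#' @export
write_stack <- function(stack, path, axes = "Z", meta = list()) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  vals <- pmin(pmax(round(stack), 0), 65535)
  pages <- purrr::map(seq_len(dim(stack)[1]),
                      function(k) vals[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta$axes <- axes
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Load ROI masks
#'
#' Reads either a label image TIFF (0 = background, k = ROI k) or a JSON
#' polygon list (`[{"id": 1, "vertices": [[x, y], ...]}, ...]`, pixel
#' units). Polygons are rasterised with the even-odd rule at pixel centers
#' (pixel (i, j), 0-based, has center (j + 0.5, i + 0.5)), a half-open
#' inclusion so abutting polygons never double-claim a pixel; overlapping
#' polygons are rejected.
#'
#' @param path `.tif`/`.tiff` label image or `.json` polygon file.
#' @param frame_shape (rows, cols); required for polygon input.
#' @return Named list of logical Y x X masks (`roi_1`, `roi_2`, ...).
#' @export
load_rois <- function(path, frame_shape = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("ROI file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    polys <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(frame_shape))
      rlang::abort("`frame_shape` is required for polygon ROIs.")
    masks <- purrr::map(polys, function(p) {
      v <- do.call(rbind, purrr::map(p$vertices, unlist))
      rasterize_polygon(v, frame_shape)
    })
    ids <- purrr::map_chr(seq_along(polys), function(i) {
      id <- polys[[i]]$id
      if (is.null(id)) paste0("roi_", i) else paste0("roi_", id)
    })
    names(masks) <- ids
    overlap <- Reduce(`+`, purrr::map(masks, as.numeric))
    if (any(overlap > 1)) rlang::abort("Polygon ROIs overlap.")
    masks
  } else {
    lab <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(lab)) == 3) lab <- lab[, , 1]
    ids <- sort(setdiff(unique(as.vector(lab)), 0))
    if (length(ids) == 0) return(stats::setNames(list(), character(0)))
    masks <- purrr::map(ids, function(k) lab == k)
    names(masks) <- paste0("roi_", ids)
    masks
  }
}

# Even-odd rasterisation at pixel centers. vertices: n x 2 matrix of (x, y)
# in pixel units; frame_shape = (rows, cols).
rasterize_polygon <- function(vertices, frame_shape) {
  ny <- frame_shape[1]; nx <- frame_shape[2]
  cx <- rep(seq_len(nx) - 0.5, each = ny)
  cy <- rep(seq_len(ny) - 0.5, times = nx)
  n <- nrow(vertices)
  inside <- rep(FALSE, length(cx))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > cy) != (yj > cy)) &
      (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = ny, ncol = nx)
}

#' Read and write synchronisation traces as CSV
#'
#' Three columns mirroring a voltage recording: `time_s`, `frame_clock`,
#' `stim_gate` (binary channel values).
#'
#' @param sync A [sync_record()].
#' @param path CSV path.
#' @return `read_sync()` returns a [sync_record()].
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync_record"))
  utils::write.csv(
    data.frame(time_s = sync$time_s, frame_clock = sync$frame_clock,
               stim_gate = sync$stim_gate),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sync
#' @export
read_sync <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Sync file not found: %s", path))
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "frame_clock", "stim_gate") %in% names(df)))
  sr <- 1 / stats::median(diff(df$time_s))
  sync_record(df$time_s, df$frame_clock, df$stim_gate, sample_rate = sr)
}
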