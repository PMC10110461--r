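#' Spatially resolved photon-count record
#'
#' Raw data from the two detectors as 3-D photon-count arrays with two
#' spatial dimensions and one temporal: `counts[y, x, t]`, row-major,
#' 0-based pixel centers, time bins half-open `[t_i, t_{i+1})`.
#'
#' @param counts_parallel,counts_perpendicular nonnegative integer 3-D
#'   arrays of identical shape `(y, x, t)`.
#' @param pixel_size pixel pitch in metres.
#' @param bin_edges time-bin edges, seconds, length `dim[3] + 1`,
#'   strictly increasing.
#' @param scheme,detector metadata lists.
#' @param seed seed recorded for provenance.
#' @return An object of class `starss_record`.
#' @export
starss_record <- function(counts_parallel, counts_perpendicular, pixel_size,
                          bin_edges, scheme = list(), detector = list(),
                          seed = NULL) {
  stopifnot(length(dim(counts_parallel)) == 3,
            identical(dim(counts_parallel), dim(counts_perpendicular)),
            all(counts_parallel >= 0), all(counts_perpendicular >= 0),
            is.numeric(pixel_size), pixel_size > 0)
  nt <- dim(counts_parallel)[3]
  if (length(bin_edges) != nt + 1 || any(diff(bin_edges) <= 0))
    stop(sprintf("bin_edges must have %d strictly increasing values (%d time pages)",
                 nt + 1, nt))
  structure(list(counts_parallel = counts_parallel,
                 counts_perpendicular = counts_perpendicular,
                 pixel_size = pixel_size, bin_edges = bin_edges,
                 scheme = scheme, detector = detector, seed = seed),
            class = "starss_record")
}

#' @export
print.starss_record <- function(x, ...) {
  d <- dim(x$counts_parallel)
  cat(sprintf("<starss_record> %d x %d pixels, %d time bins, %.4g photons total\n",
              d[1], d[2], d[3],
              sum(x$counts_parallel) + sum(x$counts_perpendicular)))
  invisible(x)
}

#' Time-integrated intensity image of a record
#'
#' @param record a [starss_record()].
#' @return a `(y, x)` matrix: both channels summed over all time bins.
#' @export
intensity_image <- function(record) {
  stopifnot(inherits(record, "starss_record"))
  rowSums(record$counts_parallel, dims = 2) +
    rowSums(record$counts_perpendicular, dims = 2)
}

#' Intensity bands used for cytosol/cluster segmentation
#'
#' The default bands assign normalized intensities in `(0.05, 0.30]` to
#' the diffuse cytosolic class and `> 0.5` to micrometric clusters;
#' anything else is background.
#'
#' @return a named list of `(lo, hi]` normalized-intensity bands.
#' @export
bands_cytosol_cluster <- function() {
  list(cytosol = c(0.05, 0.30), cluster = c(0.5, 1.0))
}

#' Segment a record by normalized fluorescence intensity
#'
#' The time-integrated intensity image is normalized by the maximum signal
#' of the brightest structure in the field of view (the image maximum
#' after a small median filter, which guards against single hot pixels)
#' and pixels are labelled by half-open intensity bands `(lo, hi]`.
#' Pixels in no band are background. Alternatively `method = "otsu"`
#' performs a generic two-class (e.g. nucleus versus background)
#' segmentation with Otsu's threshold. The returned provenance is
#' sufficient to reproduce the map bit-exactly, and the labelling is
#' invariant under rescaling the image by any positive constant.
#'
#' @param record a [starss_record()] or a 2-D intensity matrix.
#' @param bands named list of `c(lo, hi)` normalized bands; default
#'   [bands_cytosol_cluster()].
#' @param method `"bands"` (default) or `"otsu"`.
#' @param median_radius radius of the median filter used for the
#'   normalizer (1 = 3x3). Set 0 to disable.
#' @return An object of class `segmentation_map`: integer `labels` matrix
#'   (0 = background), a `legend`, and `provenance`.
#' @examples
#' img <- matrix(c(3, 20, 60, 100), 2, 2)
#' segment_by_intensity(img, median_radius = 0)$labels
#' @export
segment_by_intensity <- function(record, bands = bands_cytosol_cluster(),
                                 method = c("bands", "otsu"),
                                 median_radius = 1) {
  method <- match.arg(method)
  img <- if (inherits(record, "starss_record")) intensity_image(record)
         else as.matrix(record)
  if (all(img == 0)) stop("all-zero intensity image; nothing to segment")
  mx <- max(img)
  filt <- if (median_radius >= 1 && min(dim(img)) > 2 * median_radius)
    EBImage::medianFilter(img / mx, median_radius) * mx
  else img
  normalizer <- max(filt)
  norm <- img / normalizer
  labels <- matrix(0L, nrow(img), ncol(img))
  if (method == "bands") {
    stopifnot(length(bands) >= 1, !is.null(names(bands)))
    for (i in seq_along(bands)) {
      b <- bands[[i]]
      labels[norm > b[1] & norm <= b[2]] <- i
    }
    legend <- c(background = 0L, setNames(seq_along(bands), names(bands)))
    prov <- list(method = "bands", normalizer = normalizer,
                 bands = bands, median_radius = median_radius)
  } else {
    th <- EBImage::otsu(EBImage::Image(pmin(norm, 1)), range = c(0, 1))
    labels[norm > th] <- 1L
    legend <- c(background = 0L, foreground = 1L)
    prov <- list(method = "otsu", normalizer = normalizer, threshold = th,
                 median_radius = median_radius)
  }
  structure(list(labels = labels, legend = legend, provenance = prov),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$legend,
                      labels = names(x$legend)))
  cat("<segmentation_map>", paste(sprintf("%s: %d px", names(tab), tab),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate per-region decay curves from an image record
#'
#' Per label, photons of member pixels are summed per time bin and
#' channel. The integer sums conserve photons exactly: summing the
#' returned curves over all labels (including background) reproduces the
#' whole-frame totals.
#'
#' @param record a [starss_record()].
#' @param map a [segment_by_intensity()] map of matching shape.
#' @param include_background include the background label? Default `TRUE`.
#' @return A named list of [decay_curve()]s; empty labels are omitted
#'   with a warning.
#' @export
aggregate_region_decays <- function(record, map, include_background = TRUE) {
  stopifnot(inherits(record, "starss_record"),
            inherits(map, "segmentation_map"))
  if (!identical(dim(record$counts_parallel)[1:2], dim(map$labels)))
    stop("segmentation map shape does not match the record")
  centers <- (head(record$bin_edges, -1) + tail(record$bin_edges, -1)) / 2
  bw <- diff(record$bin_edges)
  nt <- length(centers)
  seg <- record$scheme$segments %||% rep("detect", nt)
  out <- list()
  labs <- map$legend
  if (!include_background) labs <- labs[names(labs) != "background"]
  for (nm in names(labs)) {
    sel <- map$labels == labs[[nm]]
    if (!any(sel)) {
      warning(sprintf("label '%s' contains no pixels; omitted", nm))
      next
    }
    cp <- vapply(seq_len(nt), function(k)
      sum(record$counts_parallel[, , k][sel]), 0)
    cq <- vapply(seq_len(nt), function(k)
      sum(record$counts_perpendicular[, , k][sel]), 0)
    out[[nm]] <- decay_curve(centers, cp, cq, bw, segment = seg,
                             metadata = c(record$scheme,
                                          list(label = nm,
                                               n_pixels = sum(sel),
                                               detector = record$detector)))
  }
  out
}

#' Per-pixel anisotropy map
#'
#' Counts are summed over a time window per pixel and channel and turned
#' into anisotropy with the standard corrected estimator. Pixels below a
#' minimum total count, or with a non-positive corrected denominator, are
#' masked rather than reported.
#'
#' @param record a [starss_record()].
#' @param time_window `c(from, to)` in seconds (intersected with the bin
#'   grid); default the full record.
#' @param G gain ratio.
#' @param background per-(pixel, bin) background counts per channel
#'   (length 1 or 2).
#' @param min_counts mask pixels with fewer total (both-channel) counts in
#'   the window. Default 0.
#' @return An object of class `anisotropy_map`: matrix `r`, logical
#'   `valid`, plus window bookkeeping.
#' @export
anisotropy_map <- function(record, time_window = NULL, G = 1,
                           background = c(0, 0), min_counts = 0) {
  stopifnot(inherits(record, "starss_record"), G > 0)
  background <- rep_len(background, 2)
  edges <- record$bin_edges
  if (is.null(time_window)) time_window <- range(edges)
  kidx <- which(head(edges, -1) >= time_window[1] - 1e-15 &
                  tail(edges, -1) <= time_window[2] + 1e-15)
  if (!length(kidx)) stop("time window contains no complete bins")
  Ipar <- rowSums(record$counts_parallel[, , kidx, drop = FALSE], dims = 2)
  Iperp <- rowSums(record$counts_perpendicular[, , kidx, drop = FALSE], dims = 2)
  P <- Ipar - background[1] * length(kidx)
  Q <- Iperp - background[2] * length(kidx)
  den <- P + 2 * G * Q
  valid <- den > 0 & (Ipar + Iperp) >= min_counts
  r <- ifelse(valid, (P - G * Q) / den, NA_real_)
  structure(list(r = r, valid = valid, bins_used = kidx,
                 time_window = time_window,
                 corrections = list(G = G, background = background,
                                    min_counts = min_counts)),
            class = "anisotropy_map")
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat(sprintf("<anisotropy_map> %d x %d, %d valid px, mean r = %.4g\n",
              nrow(x$r), ncol(x$r), sum(x$valid),
              mean(x$r[x$valid])))
  invisible(x)
}

#' Write / read an image record (two 16-bit TIFF stacks + JSON sidecar)
#'
#' `write_record()` stores the two channels as multi-page 16-bit TIFFs
#' (`<stem>_parallel.tif`, `<stem>_perpendicular.tif`, one page per time
#' bin) plus a `<stem>.json` sidecar holding pixel size, bin edges and
#' metadata. `read_record()` restores the record; the round trip is
#' bit-exact for counts up to 65535.
#'
#' @param record a [starss_record()].
#' @param stem path stem (no extension).
#' @return `write_record()` returns the stem invisibly; `read_record()`
#'   the restored [starss_record()].
#' @export
write_record <- function(record, stem) {
  stopifnot(inherits(record, "starss_record"))
  mx <- max(record$counts_parallel, record$counts_perpendicular)
  if (mx > 65535)
    stop("counts exceed the 16-bit TIFF range (max 65535)")
  pages <- function(a) lapply(seq_len(dim(a)[3]), function(k)
    a[, , k, drop = TRUE] / 65535)
  tiff::writeTIFF(pages(record$counts_parallel),
                  paste0(stem, "_parallel.tif"), bits.per.sample = 16,
                  compression = "none")
  tiff::writeTIFF(pages(record$counts_perpendicular),
                  paste0(stem, "_perpendicular.tif"), bits.per.sample = 16,
                  compression = "none")
  side <- list(shape = dim(record$counts_parallel),
               pixel_size = record$pixel_size,
               bin_edges = record$bin_edges, scheme = record$scheme,
               detector = record$detector, seed = record$seed,
               channels = c(parallel = paste0(basename(stem), "_parallel.tif"),
                            perpendicular = paste0(basename(stem),
                                                   "_perpendicular.tif")))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(stem)
}

#' @rdname write_record
#' @export
read_record <- function(stem) {
  side_path <- paste0(stem, ".json")
  if (!file.exists(side_path))
    stop(sprintf("missing sidecar: expected '%s'", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  read_stack <- function(suffix) {
    path <- paste0(stem, "_", suffix, ".tif")
    if (!file.exists(path)) stop(sprintf("missing channel file '%s'", path))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != side$shape[3])
      stop(sprintf("sidecar declares %d time bins but '%s' has %d pages",
                   side$shape[3], path, length(pages)))
    arr <- array(0, dim = side$shape)
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  }
  starss_record(read_stack("parallel"), read_stack("perpendicular"),
                pixel_size = side$pixel_size, bin_edges = side$bin_edges,
                scheme = as.list(side$scheme),
                detector = as.list(side$detector), seed = side$seed)
}
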