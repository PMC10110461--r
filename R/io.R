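# CSV + JSON-sidecar input/output for curves and fit reports

#' Write a decay curve as CSV with a JSON metadata sidecar
#'
#' Columns: `time_s, counts_par, counts_perp, r, r_lo95, r_hi95` (the
#' anisotropy columns are computed with the supplied corrections and are
#' `NA` on invalid bins). Metadata is written next to the CSV as
#' `<path>.json`.
#'
#' @param curve a [decay_curve()].
#' @param path output CSV path.
#' @param G,background corrections passed to [compute_anisotropy()].
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(curve, path, G = 1, background = c(0, 0)) {
  stopifnot(inherits(curve, "decay_curve"))
  an <- compute_anisotropy(curve, G = G, background = background,
                           use_segments = unique(curve$segment))
  df <- data.frame(time_s = curve$bin_centers,
                   counts_par = curve$counts_parallel,
                   counts_perp = curve$counts_perpendicular,
                   bin_width_s = curve$bin_width, segment = curve$segment,
                   r = an$r, r_lo95 = an$ci95_lo, r_hi95 = an$ci95_hi)
  write.csv(df, path, row.names = FALSE)
  meta <- curve$metadata
  meta$corrections <- list(G = G, background = background)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a decay curve written by [write_decay_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar is read if present).
#' @return a [decay_curve()].
#' @export
read_decay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  decay_curve(df$time_s, df$counts_par, df$counts_perp,
              bin_width = df$bin_width_s,
              segment = df$segment %||% rep("detect", nrow(df)),
              metadata = meta)
}

#' Write / read a modulation curve as CSV (+ JSON sidecar)
#'
#' Columns: `delay_s, total_counts, reference_counts, norm_counts`.
#'
#' @param mod a [modulation_curve()].
#' @param path CSV path.
#' @return `path` (write) or a [modulation_curve()] (read).
#' @export
write_modulation_csv <- function(mod, path) {
  stopifnot(inherits(mod, "modulation_curve"))
  write.csv(as.data.frame(mod), path, row.names = FALSE)
  jsonlite::write_json(mod$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_modulation_csv
#' @export
read_modulation_csv <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  modulation_curve(df$delay_s, df$total_counts, df$reference_counts[1],
                   metadata = meta)
}

#' Serialize a fit result as JSON
#'
#' @param fit a `starss_fit` (or the list returned by
#'   [analyze_method3()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$cov <- if (!is.null(x$cov)) unname(apply(x$cov, 1, as.numeric,
                                             simplify = FALSE))
  x$fit <- NULL
  x$calibration <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
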