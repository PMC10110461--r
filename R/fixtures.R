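# Synthetic datasets: every scenario produces curve-mode CSVs, an
# image-mode record and a ground-truth JSON, so all downstream analysis is
# testable without instrument data.

fixture_scenarios <- c("beads", "vlp_like", "arc_like", "static_reference")

# region templates: list(label = list(rotor-args, rel_intensity, blob spec))
fixture_regions <- function(scenario, env) {
  switch(scenario,
    arc_like = list(
      cluster = list(rotor = list(tau = 22.2e-6), intensity = 1.0),
      cytosol = list(rotor = list(tau = 8.1e-6), intensity = 0.15)),
    vlp_like = list(
      immature = list(rotor = list(tau = tau_from_diameter(100e-9, env),
                                   static_fraction = 0.7), intensity = 1.0),
      mature = list(rotor = list(tau = 2e-6), intensity = 0.8)),
    beads = list(
      bead030 = list(rotor = list(diameter = 30e-9), intensity = 0.8),
      bead060 = list(rotor = list(diameter = 60e-9), intensity = 0.9),
      bead100 = list(rotor = list(diameter = 100e-9), intensity = 1.0)),
    static_reference = list(
      static = list(rotor = list(D_r = 0), intensity = 1.0)))
}

# disjoint square blobs on an ny x nx frame, one per region, on a dim
# (0.02 relative) background
fixture_intensity_map <- function(region_names, ny = 24, nx = 24,
                                  rel_intensity) {
  img <- matrix(0.02, ny, nx)
  lab <- matrix(0L, ny, nx)
  n <- length(region_names)
  w <- max(4L, floor(nx / (2 * n + 1)))
  for (i in seq_len(n)) {
    x0 <- floor((2 * i - 1) * nx / (2 * n + 1)) + 1
    rows <- seq(floor(ny / 3), floor(2 * ny / 3))
    cols <- x0:min(nx, x0 + w - 1)
    img[rows, cols] <- rel_intensity[i]
    lab[rows, cols] <- i
  }
  list(intensity = img, labels = lab)
}

#' Generate a self-contained synthetic dataset
#'
#' Each scenario emulates a class of specimens measured with the
#' ON-switching photoselection scheme: `"beads"` (rigid spheres of 30, 60
#' and 100 nm), `"vlp_like"` (a constrained slow rotor with a large
#' static fraction versus a fast freely tumbling one, mimicking immature
#' and mature virus-like particles), `"arc_like"` (bright clusters with a
#' 22.2-us correlation time over a dimmer cytosol-like region at 8.1 us)
#' and `"static_reference"` (no rotation). The generator writes, per
#' region, a Poisson-sampled decay curve (CSV + JSON sidecar), one
#' image-mode record (two TIFF stacks + sidecar) whose pixels share the
#' photon budget according to the intensity template, and a ground-truth
#' JSON with the generating parameters.
#'
#' @param scenario one of `"beads"`, `"vlp_like"`, `"arc_like"`,
#'   `"static_reference"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed; drives photon sampling deterministically.
#' @param photons expected signal-photon budget per region. Default 2e6.
#' @param fluor fluorophore; default the rsEGFP2 preset.
#' @param env environment; default 293 K, 1 cP.
#' @param grid sphere grid for the forward model; default 32 x 64.
#' @param bin_width,probe_duration probe binning. Defaults 10 us / 0.8 ms.
#' @param image_size `c(ny, nx)` of the record. Default 24 x 24.
#' @return Invisibly, a list with the output `paths` and the ground
#'   `truth`.
#' @export
generate_fixture <- function(scenario = fixture_scenarios, dir, seed = 1,
                             photons = 2e6, fluor = NULL, env = NULL,
                             grid = NULL, bin_width = 1e-5,
                             probe_duration = 8e-4, image_size = c(24, 24)) {
  scenario <- match.arg(scenario)
  fluor <- fluor %||% fluorophore_preset("rsEGFP2")
  env <- env %||% environment_params()
  grid <- grid %||% sphere_grid(32, 64)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- fixture_regions(scenario, env)
  probe <- illumination("probe_488", "circular", 1e3, probe_duration)
  rel <- vapply(regions, `[[`, 0, "intensity")
  tmpl <- fixture_intensity_map(names(regions), image_size[1], image_size[2],
                                rel)
  paths <- character()
  truth <- list(scenario = scenario, seed = seed, photons = photons,
                regions = list())
  # one noiseless forward curve per region, then shared Poisson sampling
  expect <- list()
  for (i in seq_along(regions)) {
    nm <- names(regions)[i]
    rotor <- do.call(rotor_model, c(regions[[i]]$rotor, list(env = env)))
    cur <- simulate_method1(fluor, rotor, probe_488 = probe,
                            bin_width = bin_width, grid = grid,
                            target_photons = photons)
    expect[[nm]] <- cur
    samp <- cur
    s2 <- stage_seed(seed, "poisson") + i
    samp$counts_parallel <- .with_seed(s2,
      rpois(length(cur$counts_parallel), cur$counts_parallel))
    samp$counts_perpendicular <- .with_seed(s2 + 1L,
      rpois(length(cur$counts_perpendicular), cur$counts_perpendicular))
    samp$metadata$sampled <- TRUE
    samp$metadata$seed <- seed
    p <- file.path(dir, sprintf("%s_%s_curve.csv", scenario, nm))
    write_decay_csv(samp, p)
    paths <- c(paths, p)
    truth$regions[[nm]] <- c(regions[[i]]$rotor,
                             list(D_r = rotor$D_r,
                                  tau = if (is.finite(rotor$tau)) rotor$tau else NULL,
                                  static_fraction = rotor$static_fraction,
                                  intensity = regions[[i]]$intensity))
  }
  # image-mode record: distribute each region's expected curve over its
  # blob pixels plus a uniform dim background borrowed from region 1
  nb <- length(expect[[1]]$bin_centers)
  ny <- image_size[1]; nx <- image_size[2]
  epar <- eperp <- array(0, dim = c(ny, nx, nb))
  for (i in seq_along(regions)) {
    sel <- tmpl$labels == i
    npx <- sum(sel)
    sc <- regions[[i]]$intensity / max(rel)   # per-pixel brightness contrast
    for (k in seq_len(nb)) {
      epar[, , k][sel] <- sc * expect[[i]]$counts_parallel[k] / npx
      eperp[, , k][sel] <- sc * expect[[i]]$counts_perpendicular[k] / npx
    }
  }
  bgsel <- tmpl$labels == 0
  bg_scale <- 0.02 / max(rel)
  for (k in seq_len(nb)) {
    epar[, , k][bgsel] <- bg_scale * expect[[1]]$counts_parallel[k] / sum(bgsel)
    eperp[, , k][bgsel] <- bg_scale * expect[[1]]$counts_perpendicular[k] / sum(bgsel)
  }
  counts <- with_stage_seed(seed, "pixel", {
    list(array(rpois(length(epar), epar), dim = dim(epar)),
         array(rpois(length(eperp), eperp), dim = dim(eperp)))
  })
  edges <- c(expect[[1]]$bin_centers - expect[[1]]$bin_width / 2,
             tail(expect[[1]]$bin_centers, 1) + tail(expect[[1]]$bin_width, 1) / 2)
  record <- starss_record(counts[[1]], counts[[2]], pixel_size = 50e-9,
                          bin_edges = edges,
                          scheme = list(method = "method1",
                                        scenario = scenario,
                                        fluorophore = fluor$name,
                                        segments = expect[[1]]$segment),
                          detector = unclass(detector_pair()), seed = seed)
  stem <- file.path(dir, paste0(scenario, "_record"))
  write_record(record, stem)
  paths <- c(paths, paste0(stem, c("_parallel.tif", "_perpendicular.tif",
                                   ".json")))
  tp <- file.path(dir, paste0(scenario, "_truth.json"))
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, tp)
  invisible(list(paths = paths, truth = truth, record = record))
}

# ---- run configuration -----------------------------------------------------

run_config_keys <- c("scheme", "fluorophore", "tau_us", "diameter_nm",
                     "static_fraction", "temperature_K", "viscosity_cP",
                     "g_factor", "background_rate", "dark_rate",
                     "photons", "cycles", "seed", "bin_us", "probe_ms",
                     "delays_us", "on_fraction", "grid", "out", "verbosity")

#' Validated run configuration
#'
#' A flat, fully serializable description of one simulation/analysis run
#' in user-facing units (nm, us, ms, cP); unknown keys are rejected so
#' that typos fail before any computation. The config is embedded in
#' every output sidecar.
#'
#' @param ... key-value pairs; see `starss:::run_config_keys`.
#' @return a classed list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg$scheme <- cfg$scheme %||% "method1"
  if (!cfg$scheme %in% c("method1", "method2", "method3"))
    stop("scheme must be method1, method2 or method3")
  if (!is.null(cfg$tau_us) && cfg$tau_us <= 0) stop("tau_us must be positive")
  if (!is.null(cfg$diameter_nm) && cfg$diameter_nm <= 0)
    stop("diameter_nm must be positive")
  if (!is.null(cfg$g_factor) && cfg$g_factor <= 0)
    stop("g_factor must be positive")
  structure(cfg, class = "starss_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  run_config(cfg)
}
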