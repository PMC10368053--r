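#' Resolved run configuration
#'
#' Builds the fully resolved parameter set for a pipeline run: every
#' effective parameter is materialized (no silent defaulting), the
#' result round-trips through JSON, and unknown keys in any block are
#' rejected.
#'
#' @param optical Named list of \code{\link{optical_config}} arguments.
#' @param roi Named list \code{(x, y, radius, ring_width)}, or
#'   \code{NULL} when ROIs come per specimen.
#' @param demodulate Named list: \code{half_size} (NULL = automatic),
#'   \code{taper}, \code{dc_exclusion_radius}.
#' @param ri Named list: \code{h_min_frac}, \code{bounds}.
#' @param stats Named list: \code{alpha}.
#' @param out_dir Output directory or \code{NULL}.
#' @param log_level One of \code{"quiet"}, \code{"info"}.
#' @return Object of class \code{run_config} (a named list).
#' @export
run_config <- function(optical = list(), roi = NULL,
                       demodulate = list(), ri = list(), stats = list(),
                       out_dir = NULL, log_level = "info") {
  check_keys <- function(x, allowed, block) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in %s block: %s", block,
                   paste(bad, collapse = ", ")))
  }
  check_keys(optical, c("wavelength", "pixel_pitch", "n_medium",
                        "image_shape", "bit_depth", "carrier_frac",
                        "tilt_alpha", "tilt_beta"), "optical")
  oc <- do.call(optical_config, optical)
  if (!is.null(roi)) check_keys(roi, c("x", "y", "radius", "ring_width"), "roi")
  check_keys(demodulate, c("half_size", "taper", "dc_exclusion_radius"),
             "demodulate")
  check_keys(ri, c("h_min_frac", "bounds"), "ri")
  check_keys(stats, c("alpha"), "stats")
  # half_size 0 means "automatic" (JSON-stable sentinel for NULL)
  dm <- utils::modifyList(list(half_size = 0, taper = FALSE,
                               dc_exclusion_radius = 8), demodulate)
  if (is.null(dm$half_size)) dm$half_size <- 0
  ri <- utils::modifyList(list(h_min_frac = 0.1, bounds = c(-0.05, 0.1)), ri)
  st <- utils::modifyList(list(alpha = 0.05), stats)
  stopifnot(log_level %in% c("quiet", "info"))
  structure(list(optical = unclass(oc), roi = roi, demodulate = dm,
                 ri = ri, stats = st, out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Serialize / deserialize a run configuration as JSON
#'
#' @param config A \code{\link{run_config}}.
#' @param path File path.
#' @return \code{write_run_config}: \code{path} invisibly;
#'   \code{read_run_config}: a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(optical = as.list(x$optical),
             roi = if (is.null(x$roi)) NULL else as.list(x$roi),
             demodulate = as.list(x$demodulate),
             ri = as.list(x$ri), stats = as.list(x$stats),
             out_dir = x$out_dir,
             log_level = if (is.null(x$log_level)) "info" else x$log_level)
}

#' Stable hash of a run configuration
#'
#' MD5 digest of the canonical JSON serialization of the scientific
#' parameters, stamped into every artifact for provenance.  The output
#' location and log level are excluded, so moving a run does not change
#' its stamp.
#'
#' @param config A \code{\link{run_config}}.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$out_dir <- NULL
  x$log_level <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  unname(tools::md5sum(tmp))
}

as_optical <- function(config) do.call(optical_config, config$optical)

#' Reconstruct one hologram end to end
#'
#' Runs the full inverse chain on one interferogram: centred Fourier
#' transform, sidelobe location, demodulation, reliability-sorted
#' unwrapping, annular background subtraction and chord-model index
#' mapping.
#'
#' @param holo An \code{\link{interferogram}}.
#' @param roi A \code{\link{circular_roi}}.
#' @param config A \code{\link{run_config}} (or \code{NULL} for
#'   defaults).
#' @return List with \code{wrapped}, \code{unwrapped},
#'   \code{phase} (background-subtracted), \code{amplitude},
#'   \code{rimap}, \code{window} and \code{qc} (sidelobe SNR,
#'   valid-pixel fraction).
#' @export
reconstruct_hologram <- function(holo, roi, config = NULL) {
  if (is.null(config)) config <- run_config()
  stopifnot(inherits(config, "run_config"))
  oc <- holo$config
  hs <- config$demodulate$half_size
  dm <- demodulate(holo, taper = config$demodulate$taper,
                   dc_exclusion_radius = config$demodulate$dc_exclusion_radius,
                   half_size = if (is.null(hs) || hs == 0) NULL else hs)
  unwrapped <- unwrap_phase(dm$phase)
  ph <- background_subtract(unwrapped, roi, oc)
  rimap <- compute_ri(ph, roi, oc, h_min_frac = config$ri$h_min_frac,
                      bounds = config$ri$bounds)
  list(wrapped = dm$phase, unwrapped = unwrapped, phase = ph,
       amplitude = dm$amplitude, rimap = rimap, window = dm$window,
       qc = list(sidelobe_snr = dm$window$snr,
                 valid_fraction = mean(rimap$mask[
                   roi_radius_grid(roi, oc) < roi$radius])))
}

#' Run the pipeline over a cohort of specimens
#'
#' Reconstructs every specimen, collects per-specimen summary rows, and
#' runs the cohort statistics on the survivors: the normality-gated
#' two-group comparison between lipid levels within each stage, and the
#' one-way ANOVA with Tukey HSD across stages within each lipid level
#' (when at least three stages are present).  A failing specimen aborts
#' only itself and is recorded in the failures table.
#'
#' @param config A \code{\link{run_config}}.
#' @param specimens Data frame with columns \code{id}, \code{stage},
#'   \code{lipid}, \code{path} (hologram TIFF), \code{roi_x},
#'   \code{roi_y}, \code{roi_radius}; zero rows allowed.  Instead of
#'   \code{path}, a list column \code{holo} of
#'   \code{\link{interferogram}} objects may be supplied.
#' @return List with \code{summaries} (data frame), \code{failures}
#'   (data frame), \code{tests} (list), \code{config_hash} and
#'   \code{resolved_config}.  When \code{config$out_dir} is set, the
#'   tables and resolved configuration are also written there as
#'   CSV/JSON.
#' @export
run_pipeline <- function(config, specimens) {
  stopifnot(inherits(config, "run_config"))
  specimens <- as.data.frame(specimens)
  hash <- config_hash(config)
  oc <- as_optical(config)
  summaries <- data.frame()
  failures <- data.frame()
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens[i, ]
    res <- tryCatch({
      holo <- if (!is.null(specimens$holo)) sp$holo[[1]]
        else read_interferogram(sp$path, oc)
      roi <- circular_roi(sp$roi_x, sp$roi_y, sp$roi_radius)
      rec <- reconstruct_hologram(holo, roi, config)
      data.frame(id = sp$id, stage = sp$stage, lipid = sp$lipid,
                 mean_ri = rec$rimap$summary$mean,
                 median_ri = rec$rimap$summary$median,
                 n_valid = rec$rimap$summary$n_valid,
                 sidelobe_snr = rec$qc$sidelobe_snr,
                 valid_fraction = rec$qc$valid_fraction,
                 config_hash = hash)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(id = sp$id, error = conditionMessage(res)))
    } else summaries <- rbind(summaries, res)
  }

  alpha <- config$stats$alpha
  tests <- list(within_stage = list(), across_stage = list())
  if (nrow(summaries)) {
    for (st in unique(summaries$stage)) {
      lo <- summaries$mean_ri[summaries$stage == st & summaries$lipid == "low"]
      hi <- summaries$mean_ri[summaries$stage == st & summaries$lipid == "high"]
      if (length(lo) >= 2 && length(hi) >= 2)
        tests$within_stage[[st]] <- choose_and_compare(lo, hi, alpha)
    }
    for (lp in unique(summaries$lipid)) {
      sub <- summaries[summaries$lipid == lp, ]
      grp <- split(sub$mean_ri, sub$stage)
      grp <- grp[vapply(grp, length, 1L) >= 2]
      if (length(grp) >= 3)
        tests$across_stage[[lp]] <- compare_across_stages(grp, alpha)
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries,
                     file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(failures,
                     file.path(config$out_dir, "failures.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(config$out_dir, "resolved_config.json"))
  }
  list(summaries = summaries, failures = failures, tests = tests,
       config_hash = hash, resolved_config = config)
}

#' Representative phantom for sensitivity analyses
#'
#' The shipped reference scene for the radius and background sensitivity
#' checks: a uniform sphere of radius 50 um and index excess 0.004 over
#' medium 1.336, centred in a 512 x 512 field at 0.3 um/px, 0.532 um
#' illumination, carrier at 1/8 of the diagonal Nyquist limit.
#'
#' @param config Optional \code{\link{optical_config}} override.
#' @param delta_n Index excess of the sphere (default 0.004).
#' @param radius Sphere radius in micrometres (default 50).
#' @return List with \code{spec}, \code{roi} and \code{config}.
#' @export
representative_phantom <- function(config = optical_config(),
                                   delta_n = 0.004, radius = 50) {
  cx <- config$image_shape[2] * config$pixel_pitch / 2
  cy <- config$image_shape[1] * config$pixel_pitch / 2
  list(spec = phantom_spec(spheres = data.frame(x = cx, y = cy,
                                                radius = radius,
                                                delta_n = delta_n)),
       roi = circular_roi(cx, cy, radius),
       config = config)
}
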