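#' Normality-gated two-group comparison
#'
#' Compares two groups of per-specimen summary values the way the
#' analysis protocol prescribes: each group is checked for normality
#' with a Shapiro-Wilk test at \code{alpha}; if both pass, a two-sided
#' unpaired Student t-test (equal variances, the classical "unpaired
#' t-test") is used, otherwise a two-sided Mann-Whitney U test (exact
#' when sample sizes permit and there are no ties).  Groups too small
#' for Shapiro-Wilk (n < 3) and degenerate zero-variance inputs fall
#' back to Mann-Whitney, the latter with a warning flag.  Either branch
#' can be forced for audit via \code{force}.
#'
#' @param a,b Numeric vectors of per-specimen values (n >= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param force \code{"auto"} (default), \code{"ttest"} or
#'   \code{"mannwhitney"}.
#' @return Object of class \code{dhm_test_result}: list with
#'   \code{test}, \code{statistic}, \code{p_value}, \code{significant},
#'   \code{alpha}, \code{path} (which branch ran and why),
#'   \code{normal} (named logical) and \code{degenerate} flag.
#' @examples
#' choose_and_compare(rnorm(8, 1.340, 0.001), rnorm(8, 1.345, 0.001))
#' choose_and_compare(c(1, 2, 3), c(4, 5, 6), force = "mannwhitney")
#' @export
choose_and_compare <- function(a, b, alpha = 0.05,
                               force = c("auto", "ttest", "mannwhitney")) {
  force <- match.arg(force)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 specimens")
  stopifnot(alpha > 0, alpha < 1)
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  shapiro_ok <- function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(NA)
    stats::shapiro.test(x)$p.value >= alpha
  }
  normal <- c(a = shapiro_ok(a), b = shapiro_ok(b))
  use_t <- switch(force,
    ttest = TRUE,
    mannwhitney = FALSE,
    auto = !degenerate && isTRUE(normal[["a"]]) && isTRUE(normal[["b"]]))
  if (degenerate && force == "auto")
    warning("zero-variance groups: falling back to Mann-Whitney")
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"; statistic <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    test <- "mannwhitney"; statistic <- unname(ht$statistic)
  }
  p <- if (degenerate && !use_t && identical(sort(a), sort(b)) &&
           stats::sd(c(a, b)) == 0) 1 else unname(ht$p.value)
  structure(
    list(test = test, statistic = statistic, p_value = p,
         significant = p < alpha, alpha = alpha,
         path = if (force != "auto") paste0("forced:", force)
                else if (degenerate) "degenerate->mannwhitney"
                else if (use_t) "normal->ttest" else "nonnormal->mannwhitney",
         normal = normal, degenerate = degenerate),
    class = "dhm_test_result")
}

#' @export
print.dhm_test_result <- function(x, ...) {
  cat(sprintf("<%s test> statistic = %.4g, p = %.4g (%s at alpha %.3g) [%s]\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha, x$path))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD across developmental stages
#'
#' Fixed-effects one-way ANOVA over three or more groups of per-specimen
#' values, followed by Tukey honest-significant-difference pairwise
#' comparisons and a compact letter display (groups sharing no letter
#' differ significantly), the standard rendering of the superscripts
#' used in stage-comparison figures.
#'
#' @param groups Named list of numeric vectors, one per group
#'   (>= 3 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with \code{anova} (data frame: F, df1, df2, p_value),
#'   \code{tukey} (data frame of pairwise diff, bounds, adjusted p),
#'   \code{letters} (named character vector) and \code{significant}.
#' @export
compare_across_stages <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need at least 3 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 specimens")
  ow <- oneway_f(groups)
  fit <- ow$fit
  anova_tab <- ow$table
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey_tab <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL)
  letters_vec <- cld_letters(names(groups), tukey_tab, alpha,
                             vapply(groups, mean, 1))
  list(anova = anova_tab, tukey = tukey_tab, letters = letters_vec,
       significant = anova_tab$p_value < alpha)
}

# fixed-effects one-way ANOVA over >= 2 named groups (the k = 2 case
# reduces to the squared equal-variance t statistic)
oneway_f <- function(groups) {
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  list(fit = fit,
       table = data.frame(F = an[1, "F value"],
                          df1 = an[1, "Df"], df2 = an[2, "Df"],
                          p_value = an[1, "Pr(>F)"]))
}

# compact letter display by insert-and-absorb: start from one set holding
# every group, split sets on each significant pair, drop subsets, letter
# the survivors in order of group mean
cld_letters <- function(group_names, tukey_tab, alpha, means) {
  sets <- list(group_names)
  sig <- tukey_tab[tukey_tab$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    pr <- strsplit(sig$pair[i], "-", fixed = TRUE)[[1]]
    new_sets <- list()
    for (s in sets) {
      if (all(pr %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, pr[1])), list(setdiff(s, pr[2])))
      } else new_sets <- c(new_sets, list(s))
    }
    keep <- rep(TRUE, length(new_sets))
    for (p in seq_along(new_sets))
      for (q in seq_along(new_sets))
        if (p != q && keep[q] &&
            all(new_sets[[p]] %in% new_sets[[q]]) &&
            (length(new_sets[[p]]) < length(new_sets[[q]]) || p > q))
          keep[p] <- FALSE
    sets <- unique(new_sets[keep])
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, names(sort(means)))), 1))]
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Sensitivity of the mean index to the analysis radius
#'
#' Re-runs the annular background subtraction and the chord-model index
#' mapping with the ROI radius perturbed by each fraction in
#' \code{perturb_fracs}, and reports the mean valid-pixel index and its
#' relative change against the nominal radius.  For a well-posed
#' reconstruction a +/-15 percent radius error changes the mean index by
#' well under half a percent.
#'
#' @param phase Unwrapped \code{\link{phase_map}} before background
#'   subtraction.
#' @param roi Nominal \code{\link{circular_roi}}.
#' @param config An \code{\link{optical_config}}.
#' @param perturb_fracs Radius perturbations as fractions
#'   (default \code{c(-0.15, 0, 0.15)}).
#' @param h_min_frac Passed to \code{\link{compute_ri}}.
#' @return Data frame with \code{fraction}, \code{radius},
#'   \code{mean_ri}, \code{rel_change} and \code{rel_change_pct}.
#' @export
radius_sensitivity <- function(phase, roi, config,
                               perturb_fracs = c(-0.15, 0, 0.15),
                               h_min_frac = 0.1) {
  mean_at <- function(f) {
    roi_f <- circular_roi(roi$x, roi$y, roi$radius * (1 + f), roi$ring_width)
    ph <- background_subtract(phase, roi_f, config)
    compute_ri(ph, roi_f, config, h_min_frac)$summary$mean
  }
  nominal <- mean_at(0)
  means <- vapply(perturb_fracs, mean_at, 1)
  data.frame(fraction = perturb_fracs,
             radius = roi$radius * (1 + perturb_fracs),
             mean_ri = means,
             rel_change = (means - nominal) / nominal,
             rel_change_pct = 100 * (means - nominal) / nominal)
}

#' Sensitivity of the mean index to smooth background distortion
#'
#' Adds a first-order (tilt) plus second-order (curvature) polynomial
#' phase of given peak-to-peak amplitude across the ROI to the unwrapped
#' phase, re-runs the annular subtraction and index mapping, and reports
#' the relative change of the mean valid-pixel index.  In normalized ROI
#' coordinates \code{u = (x - x_c)/R}, \code{v = (y - y_c)/R} the
#' distortion is \code{A (u/2 + (u^2 + v^2 - 1)/4)}, whose range over
#' the ROI disk is exactly \code{A}.
#'
#' @param phase Unwrapped \code{\link{phase_map}} before background
#'   subtraction.
#' @param roi A \code{\link{circular_roi}}.
#' @param config An \code{\link{optical_config}}.
#' @param distortion_amplitude_rad Peak-to-peak amplitude A in radians
#'   (default 0.2).
#' @param h_min_frac Passed to \code{\link{compute_ri}}.
#' @return List with \code{baseline_mean}, \code{distorted_mean},
#'   \code{rel_change} and \code{rel_change_pct}.
#' @export
background_sensitivity <- function(phase, roi, config,
                                   distortion_amplitude_rad = 0.2,
                                   h_min_frac = 0.1) {
  stopifnot(distortion_amplitude_rad >= 0)
  run <- function(ph) {
    compute_ri(background_subtract(ph, roi, config), roi, config,
               h_min_frac)$summary$mean
  }
  base <- run(phase)
  g <- pixel_grids(config)
  u <- (g$x - roi$x) / roi$radius
  v <- (g$y - roi$y) / roi$radius
  dist <- distortion_amplitude_rad * (u / 2 + (u^2 + v^2 - 1) / 4)
  pert <- run(phase_map(phase$values + dist, wrapped = FALSE))
  list(baseline_mean = base, distorted_mean = pert,
       rel_change = (pert - base) / base,
       rel_change_pct = 100 * abs(pert - base) / base)
}

#' Illumination energy density
#'
#' Total optical energy delivered per unit area:
#' \code{power * exposure / (pi (d/2)^2)}, converted to J/cm^2.  A 30 uW
#' beam over one minute on a 780 um spot delivers 0.4 J/cm^2.
#'
#' @param power_W Incident power in watts.
#' @param exposure_s Exposure time in seconds.
#' @param spot_diameter_m Beam spot diameter (2 w0) in metres.
#' @return Energy density in J/cm^2.
#' @examples
#' energy_density(30e-6, 60, 780e-6)  # ~0.4
#' @export
energy_density <- function(power_W, exposure_s, spot_diameter_m) {
  if (power_W <= 0 || exposure_s <= 0 || spot_diameter_m <= 0)
    stop("all inputs must be positive")
  area_cm2 <- pi * (spot_diameter_m / 2)^2 * 1e4
  power_W * exposure_s / area_cm2
}
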