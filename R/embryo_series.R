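#' Seeded embryo-stage phantom generator
#'
#' Builds a deterministic \code{\link{phantom_spec}} for one of five
#' preimplantation stages.  Cleavage stages (2-cell through morula) pack
#' 2/4/8/16 cytoplasm spheres inside a zona-pellucida shell; the per-cell
#' radii are chosen so total cytoplasm volume is conserved across
#' cleavage divisions, as in real embryos.  The blastocyst is an expanded
#' shell with a thin cytoplasm layer and a large fluid cavity whose
#' negative \code{delta_n} cancels the cytoplasm, leaving the blastocoel
#' at the medium index; its mean effective index over the (larger) ROI is
#' therefore below the cleavage stages.  The \code{high} lipid level
#' multiplies the cytoplasm index excess by \code{lipid_factor} while
#' leaving geometry and the zona untouched.
#'
#' The seed drives only small positional jitter (embryo centre and
#' blastomere placement), so two calls with identical arguments return
#' identical specs.
#'
#' @param stage One of \code{"2cell"}, \code{"4cell"}, \code{"8cell"},
#'   \code{"morula"}, \code{"blastocyst"}.
#' @param lipid_level \code{"low"} or \code{"high"}.
#' @param seed Integer seed for the positional jitter.
#' @param config \code{\link{optical_config}} giving the field of view.
#' @param delta_n_cytoplasm Index excess of cytoplasm at low lipid
#'   (default 0.004).
#' @param delta_n_zona Index excess of the zona shell (default 0.002).
#' @param lipid_factor Multiplier applied to the cytoplasm excess for the
#'   high-lipid group (default 1.5, i.e. 0.006).
#' @param noise \code{noise} list passed through to the spec.
#' @return A \code{\link{phantom_spec}} with \code{stage}/\code{lipid}
#'   labels and an \code{roi} attribute holding the matching
#'   \code{\link{circular_roi}}.
#' @examples
#' sp <- make_embryo_series("2cell", "low", seed = 1)
#' attr(sp, "roi")$radius
#' @export
make_embryo_series <- function(stage,
                               lipid_level = c("low", "high"),
                               seed = 1L,
                               config = optical_config(),
                               delta_n_cytoplasm = 0.004,
                               delta_n_zona = 0.002,
                               lipid_factor = 1.5,
                               noise = list(photon_scale = NULL, seed = NULL)) {
  stages <- c("2cell", "4cell", "8cell", "morula", "blastocyst")
  if (!is.character(stage) || length(stage) != 1 || !(stage %in% stages))
    stop("unknown stage label: ", paste(stage, collapse = ", "),
         " (expected one of ", paste(stages, collapse = ", "), ")")
  lipid_level <- match.arg(lipid_level)
  stopifnot(lipid_factor > 1)
  dn <- delta_n_cytoplasm * if (lipid_level == "high") lipid_factor else 1

  fw <- config$image_shape[2] * config$pixel_pitch
  fh <- config$image_shape[1] * config$pixel_pitch

  with_seed(seed, {
    cx <- fw / 2 + stats::runif(1, -2, 2)
    cy <- fh / 2 + stats::runif(1, -2, 2)

    if (stage == "blastocyst") {
      # expanded embryo: thin trophectoderm layer around a large cavity
      zona_outer <- 52; zona_inner <- 47
      layer_outer <- 44.8           # cytoplasm sphere
      cavity_r <- 42.6              # conserves ~57e3 um^3 of cytoplasm
      spheres <- data.frame(x = cx, y = cy, radius = layer_outer, delta_n = dn)
      cavity <- list(x = cx, y = cy, radius = cavity_r, delta_n = -dn)
    } else {
      zona_outer <- 45; zona_inner <- 40
      cavity <- NULL
      geom <- switch(stage,
        "2cell" = list(n = 2, r = 19, rings = list(c(n = 2, d = 19))),
        "4cell" = list(n = 4, r = 15.1, rings = list(c(n = 4, d = 21))),
        "8cell" = list(n = 8, r = 12, rings = list(c(n = 8, d = 25))),
        "morula" = list(n = 16, r = 9.55,
                        rings = list(c(n = 11, d = 28), c(n = 5, d = 13))))
      theta0 <- stats::runif(1, 0, 2 * pi)
      xs <- ys <- numeric(0)
      for (ring in geom$rings) {
        ang <- theta0 + 2 * pi * seq_len(ring[["n"]]) / ring[["n"]] +
          stats::runif(ring[["n"]], -0.08, 0.08)
        d <- ring[["d"]] + stats::runif(ring[["n"]], -1, 1)
        # keep every blastomere inside the zona cavity
        d <- pmin(d, zona_inner - geom$r)
        xs <- c(xs, cx + d * cos(ang))
        ys <- c(ys, cy + d * sin(ang))
        theta0 <- theta0 + pi / ring[["n"]]
      }
      spheres <- data.frame(x = xs, y = ys, radius = geom$r, delta_n = dn)
    }

    spec <- phantom_spec(
      spheres = spheres,
      shell = list(x = cx, y = cy, inner_radius = zona_inner,
                   outer_radius = zona_outer, delta_n = delta_n_zona),
      cavity = cavity,
      noise = noise,
      stage = stage, lipid = lipid_level)
    attr(spec, "roi") <- circular_roi(cx, cy, zona_outer)
    spec
  })
}
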