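#' Geometric specification of a synthetic blastocyst frame
#'
#' Two nested circles carry the labeled regions: the outer circle is the
#' zona-inclusive contour (the zp-A edge), the inner circle the embryo
#' proper. The inner center may be offset along +x by `d` micrometres, which
#' is how maximum zona thickness values exceeding the mean annulus width are
#' realized. An angular sector of the inner disc is labeled as ICM.
#'
#' @param R_out Outer (zona) radius in um.
#' @param R_in Inner (embryo proper) radius in um.
#' @param d Offset of the inner center from the outer center, um. Nesting
#'   requires `d + R_in <= R_out`.
#' @param icm_frac Fraction of the embryo-proper area labeled ICM, in
#'   `[0, 1)`.
#' @param icm_angle Starting angle (radians) of the ICM sector.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(R_out, R_in, d = 0, icm_frac = 0, icm_angle = pi / 2) {
  stopifnot(is.numeric(R_out), is.numeric(R_in), is.numeric(d))
  if (R_in < 0 || R_out < R_in) stop("need R_out >= R_in >= 0")
  if (d < 0 || d + R_in > R_out + 1e-9)
    stop("contours not nested: need d + R_in <= R_out")
  if (icm_frac < 0 || icm_frac >= 1) stop("icm_frac must be in [0, 1)")
  structure(list(R_out = R_out, R_in = R_in, d = d,
                 icm_frac = icm_frac, icm_angle = icm_angle),
            class = "frame_spec")
}

#' Frame geometry realizing a set of drawn morphometric anchors
#'
#' Converts one embryo's drawn anchors into a renderable [frame_spec()]. The
#' outer radius reproduces the zona-inclusive area exactly. The maximum
#' thickness zp-T is realized exactly by offsetting the inner contour
#' (`d = zp_T - (R_out - R_in)`); when the drawn thickness exceeds twice the
#' concentric annulus width the inner radius is shrunk to
#' `R_out - zp_T / 2` first, the largest inner circle for which the nesting
#' constraint still permits that thickness. Thickness and the area pair are
#' therefore treated as separately calibrated observables: when they are
#' geometrically incompatible the outer area and the thickness win and the
#' rendered embryo-proper area departs from its drawn anchor. A minimum
#' zona clearance (`margin`) keeps the inner contour strictly inside the
#' outer one, so the rendered zona encloses the embryo everywhere.
#'
#' @param zp_A Zona-inclusive area, um^2.
#' @param emb_A Embryo-proper area, um^2.
#' @param zp_T Maximum zona thickness, um.
#' @param icm_frac ICM fraction of the embryo-proper area.
#' @param margin Minimum zona width in um (default 2, about two pixels at
#'   the default rendering scale).
#' @return A [frame_spec()].
#' @export
embryo_frame_spec <- function(zp_A, emb_A, zp_T, icm_frac = 0, margin = 2) {
  stopifnot(zp_A > 0, emb_A > 0, emb_A <= zp_A, zp_T >= 0)
  R_out <- sqrt(zp_A / pi)
  R_in <- min(sqrt(emb_A / pi), R_out - (zp_T + margin) / 2)
  R_in <- max(R_in, 0)
  d <- min(max(zp_T - (R_out - R_in), 0), R_out - R_in)
  frame_spec(R_out, R_in, d, icm_frac = icm_frac)
}

#' A labeled single-plane mask frame
#'
#' @param labels Integer matrix with values 0 (background), 1 (zona),
#'   2 (embryo proper), 3 (ICM).
#' @param scale Micrometres per pixel, > 0.
#' @param time Acquisition time in hpi (optional).
#' @return An object of class `mask_frame`.
#' @export
mask_frame <- function(labels, scale, time = NA_real_) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3)) stop("labels must be in {0, 1, 2, 3}")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  structure(list(labels = labels, scale = scale, time = time),
            class = "mask_frame")
}

#' Rasterize a frame specification into a labeled mask
#'
#' Pixels are labeled by their centers: inside the inner circle they are
#' embryo proper (or ICM within the configured sector), inside the outer
#' circle only they are zona, elsewhere background. Pixel counts times
#' `scale^2` approximate the analytic circle areas to within the
#' discretization error of the contour.
#'
#' @param spec A [frame_spec()].
#' @param scale Micrometres per pixel.
#' @param side Frame side length in pixels; `NA` auto-sizes to the outer
#'   contour plus a margin.
#' @param time Acquisition time (hpi) recorded on the frame.
#' @return A [mask_frame()].
#' @export
#' @examples
#' m <- render_mask(frame_spec(80, 60), scale = 1)
#' sum(m$labels >= 2)  # ~ pi * 60^2 pixels
render_mask <- function(spec, scale = 1, side = NA, time = NA_real_) {
  stopifnot(inherits(spec, "frame_spec"), scale > 0)
  if (is.na(side)) side <- 2L * ceiling(spec$R_out / scale) + 9L
  side <- as.integer(side)
  cx <- (side + 1) / 2
  if (spec$R_out / scale > (side - 1) / 2)
    stop("contour exceeds frame: increase side or scale")
  xs <- (seq_len(side) - cx) * scale
  X <- matrix(xs, side, side, byrow = TRUE)   # column -> x
  Y <- matrix(xs, side, side)                 # row -> y
  r2_out <- X^2 + Y^2
  lab <- matrix(0L, side, side)
  lab[r2_out <= spec$R_out^2] <- 1L
  if (spec$R_in > 0) {
    Xi <- X - spec$d
    inner <- (Xi^2 + Y^2) <= spec$R_in^2
    lab[inner] <- 2L
    if (spec$icm_frac > 0) {
      ang <- (atan2(Y, Xi) - spec$icm_angle) %% (2 * pi)
      lab[inner & ang < 2 * pi * spec$icm_frac] <- 3L
    }
  }
  mask_frame(lab, scale, time)
}

#' Write and read labeled mask stacks
#'
#' Masks are stored as multi-page 8-bit grayscale TIFF with pixel value equal
#' to the integer label, plus a JSON sidecar (`<path>.json`) declaring the
#' label map, the spatial scale and the per-frame acquisition times. The
#' label map is always read from the sidecar, never assumed.
#'
#' @param frames List of [mask_frame()] objects sharing one scale.
#' @param path Output TIFF path.
#' @return `write_mask_stack()` returns `path` invisibly; `read_mask_stack()`
#'   returns a list of [mask_frame()] objects.
#' @export
write_mask_stack <- function(frames, path) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "mask_frame")))
  scale <- frames[[1]]$scale
  pages <- lapply(frames, function(f) f$labels / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- list(scale_um_per_px = scale,
                  label_map = list(background = 0L, zona = 1L,
                                   embryo_proper = 2L, ICM = 3L),
                  times_hpi = vapply(frames, function(f) f$time, numeric(1)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$label_map) || is.null(sc$scale_um_per_px))
    stop("sidecar must declare label_map and scale_um_per_px")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  times <- sc$times_hpi
  if (is.null(times)) times <- rep(NA_real_, length(pages))
  lapply(seq_along(pages), function(i) {
    lab <- round(pages[[i]] * 255)
    mask_frame(lab, sc$scale_um_per_px, times[i])
  })
}
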