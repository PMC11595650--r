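# 8-connected outer contour of a logical region: pixels of the region with
# at least one 8-neighbour (or the image edge) outside it. Returns an n x 2
# matrix of (row, col) indices.
.region_boundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  which(m & !interior, arr.ind = TRUE)
}

# subpixel edge point set of a logical region: midpoints of every
# 4-neighbour in/out pixel pair (the marching-squares crossing points at
# level one half). Unbiased to first order in the pixel phase, unlike
# boundary pixel centers which sit up to one pixel inside the region.
# Returns an n x 2 matrix of (row, col) coordinates in pixel units.
.region_edges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  h <- pad[, -1L] != pad[, -ncol(pad)]   # vertical edges between col j, j+1
  v <- pad[-1L, ] != pad[-nrow(pad), ]   # horizontal edges between row i, i+1
  hi <- which(h, arr.ind = TRUE)
  vi <- which(v, arr.ind = TRUE)
  rbind(cbind(hi[, 1L] - 1L, hi[, 2L] - 0.5),
        cbind(vi[, 1L] - 0.5, vi[, 2L] - 1L))
}

# for each point of `from` (n x 2), index of the nearest point of `to`
.nearest_idx <- function(from, to, chunk = 2048L) {
  n <- nrow(from)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(from[s:e, 1L], to[, 1L], `-`)
    dy <- outer(from[s:e, 2L], to[, 2L], `-`)
    out[s:e] <- max.col(-(dx * dx + dy * dy), ties.method = "first")
  }
  out
}

# distance from points p (n x 2) to segments a->b (n x 2 each), elementwise
.pt_seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- rowSums(ab * ab)
  t <- rowSums((p - a) * ab) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  sqrt(rowSums((p - proj)^2))
}

# directed distance profile from each inner edge point to the outer contour,
# treating the outer edge points (ordered by angle around their centroid) as
# a closed polyline; refined over segments near the nearest vertex
.dist_to_contour <- function(inner, outer) {
  ctr <- colMeans(outer)
  ord <- order(atan2(outer[, 1L] - ctr[1L], outer[, 2L] - ctr[2L]))
  poly <- outer[ord, , drop = FALSE]
  np <- nrow(poly)
  ni <- nrow(inner)
  near <- .nearest_idx(inner, poly)
  best <- rep(Inf, ni)
  for (off in -4:4) {
    i1 <- ((near - 1L + off) %% np) + 1L
    i2 <- (i1 %% np) + 1L
    d <- .pt_seg_dist(inner, poly[i1, , drop = FALSE],
                      poly[i2, , drop = FALSE])
    best <- pmin(best, d)
  }
  best
}

# circular moving average over a profile ordered along the contour
.circ_smooth <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  if (w <= 1L) return(x)
  xx <- c(x, x[seq_len(w)])
  cs <- cumsum(c(0, xx))
  (cs[(w + 1):(n + w)] - cs[seq_len(n)]) / w
}

#' Cross-sectional areas from a labeled mask
#'
#' Areas are pixel counts times the squared spatial scale: the embryo-proper
#' area `emb_A` covers labels 2 and 3 (the blastocoel, trophectoderm and ICM
#' enclosed by the inner zona surface), the ICM area label 3 only, and the
#' zona-inclusive area `zp_A` everything non-background.
#'
#' @param mask A [mask_frame()].
#' @return Named numeric vector `c(zp_A, emb_A, ICM_A)` in um^2.
#' @export
measure_areas <- function(mask) {
  stopifnot(inherits(mask, "mask_frame"))
  lab <- mask$labels
  n_emb <- sum(lab == 2L | lab == 3L)
  if (n_emb == 0L) stop("empty embryo: no embryo-proper or ICM pixels")
  s2 <- mask$scale^2
  c(zp_A = sum(lab != 0L) * s2,
    emb_A = n_emb * s2,
    ICM_A = sum(lab == 3L) * s2)
}

#' Maximum zona pellucida thickness from a labeled mask
#'
#' Zona thickness is the largest distance between the embryo-proper edge and
#' the outer zona edge. The default estimator is the directed Hausdorff
#' distance from the embryo-region edge to the outer edge of the full
#' (zona-inclusive) region: for every embryo edge point the distance to the
#' nearest point of the outer contour is taken and the maximum over the
#' embryo edge is returned, times the scale. For nested circles with inner
#' offset `d` this equals `R_out - R_in + d` up to pixelation.
#'
#' Edges are localized at subpixel precision (midpoints of in/out pixel
#' pairs, i.e. the half-level contour) and the outer contour is treated as
#' a closed polyline, so neither edge carries the half-pixel inset of raw
#' boundary pixel centers. Because the maximum of a jittered, near-flat
#' distance profile is biased upward by the rasterization noise, the
#' profile is smoothed along the contour (circular moving average over
#' `smooth` points) before the maximum is taken; `smooth = 1` disables
#' this and reproduces the raw pointwise maximum.
#'
#' The `"radial"` variant instead measures, along the ray from the embryo
#' centroid through each embryo edge point, the radial gap to the outer
#' edge; both variants coincide for near-circular nested contours.
#'
#' @param mask A [mask_frame()].
#' @param method `"hausdorff"` (default) or `"radial"`.
#' @param smooth Contour smoothing window (points) for the distance
#'   profile.
#' @return Thickness in um.
#' @export
measure_zp_thickness <- function(mask, method = c("hausdorff", "radial"),
                                 smooth = 15L) {
  stopifnot(inherits(mask, "mask_frame"))
  method <- match.arg(method)
  lab <- mask$labels
  emb <- lab == 2L | lab == 3L
  if (!any(emb)) stop("empty embryo: no embryo-proper or ICM pixels")
  full <- lab != 0L
  has_zona <- any(lab == 1L)
  if (!has_zona)
    warning("no zona pixels: zona treated as zero-width")
  if (has_zona) {
    # enclosure check: an embryo boundary pixel touching background means
    # the zona does not wrap the embryo at that point
    emb_b <- .region_boundary(emb)
    nr <- nrow(lab); nc <- ncol(lab)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
    exposed <- FALSE
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nb <- pad[cbind(emb_b[, 1L] + 1L + dr, emb_b[, 2L] + 1L + dc)]
        if (any(nb == 0L)) { exposed <- TRUE; break }
      }
      if (exposed) break
    }
    if (exposed)
      warning("embryo region not fully enclosed by zona; ",
              "thickness computed anyway")
  }
  inner <- .region_edges(emb)
  outer <- .region_edges(full)
  ctr <- colMeans(which(emb, arr.ind = TRUE))
  if (method == "hausdorff") {
    d <- .dist_to_contour(inner, outer)
    ord <- order(atan2(inner[, 1L] - ctr[1L], inner[, 2L] - ctr[2L]))
    max(.circ_smooth(d[ord], as.integer(smooth))) * mask$scale
  } else {
    ang_i <- atan2(inner[, 1L] - ctr[1L], inner[, 2L] - ctr[2L])
    ang_o <- atan2(outer[, 1L] - ctr[1L], outer[, 2L] - ctr[2L])
    r_i <- sqrt((inner[, 1L] - ctr[1L])^2 + (inner[, 2L] - ctr[2L])^2)
    r_o <- sqrt((outer[, 1L] - ctr[1L])^2 + (outer[, 2L] - ctr[2L])^2)
    gap <- vapply(seq_along(ang_i), function(i) {
      dd <- abs(((ang_o - ang_i[i] + pi) %% (2 * pi)) - pi)
      r_o[which.min(dd)] - r_i[i]
    }, numeric(1))
    ord <- order(ang_i)
    max(.circ_smooth(gap[ord], as.integer(smooth))) * mask$scale
  }
}

#' All morphometric features of one labeled frame
#'
#' Combines [measure_areas()] and [measure_zp_thickness()] and derives the
#' ICM/TE ratio as `ICM_A / (emb_A - ICM_A)`: both areas are taken in the
#' same focal plane, so the trophectoderm denominator is the embryo-proper
#' area minus the ICM. A frame whose embryo is all ICM has an undefined
#' ratio (`NA`); a frame without ICM has ratio 0.
#'
#' @param mask A [mask_frame()].
#' @param zp_method Thickness estimator, see [measure_zp_thickness()].
#' @return One-row data frame: `time`, `zp_A`, `emb_A`, `zp_T`, `ICM_A`,
#'   `ICM_TE_ratio`.
#' @export
measure_frame <- function(mask, zp_method = "hausdorff") {
  ar <- measure_areas(mask)
  zp_t <- measure_zp_thickness(mask, method = zp_method)
  te <- ar[["emb_A"]] - ar[["ICM_A"]]
  ratio <- if (ar[["ICM_A"]] == 0) 0 else if (te == 0) NA_real_
           else ar[["ICM_A"]] / te
  data.frame(time = mask$time,
             zp_A = ar[["zp_A"]], emb_A = ar[["emb_A"]], zp_T = zp_t,
             ICM_A = ar[["ICM_A"]], ICM_TE_ratio = ratio)
}
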