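## ROI segmentation from a mean image via polar intensity profiles.

#' Segment somatic ROIs around seed points
#'
#' For each seed, intensity profiles are computed along polar rays; the
#' boundary along each ray is placed at the maximal intensity (somata appear
#' as bright disks or rings), taking the outer edge of the first maximal run
#' so adjacent bright cells do not capture each other's pixels. Pixels whose
#' radius is below the (angle-interpolated) boundary form the ROI. Seeds on
#' background -- where the boundary intensity does not rise above the image
#' background, or the boundary hits the search limit -- are flagged
#' unsegmentable.
#'
#' @param mean_image 2-D numeric intensity matrix (rows = y, cols = x).
#' @param seeds list of \code{c(x, y)} seed points (1-based pixel
#'   coordinates), or a 2-column matrix.
#' @param max_radius_px radial search limit (pixels).
#' @param n_angles number of polar rays.
#' @return data frame with one row per seed: \code{x}, \code{y},
#'   \code{area_px}, \code{radius_px} (mean boundary radius) and
#'   \code{segmentable}; pixel masks (logical matrices) are attached as the
#'   \code{masks} attribute.
#' @export
segment_rois <- function(mean_image, seeds, max_radius_px = 15,
                         n_angles = 36) {
  if (is.matrix(seeds)) seeds <- asplit(seeds, 1)
  bgl <- median(mean_image)
  bright <- bgl + 0.25 * (max(mean_image) - bgl)
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  rr <- seq(0.5, max_radius_px, by = 0.5)
  out <- data.frame(x = numeric(0), y = numeric(0), area_px = numeric(0),
                    radius_px = numeric(0), segmentable = logical(0))
  masks <- list()
  for (s in seeds) {
    sx <- s[1]; sy <- s[2]
    if (sx < 1 || sy < 1 || sx > ncol(mean_image) || sy > nrow(mean_image))
      stopf("seed (%g, %g) outside image", sx, sy)
    bound <- numeric(length(ang))
    bval <- numeric(length(ang))
    for (a in seq_along(ang)) {
      px <- sx + rr * cos(ang[a])
      py <- sy + rr * sin(ang[a])
      prof <- bilinear(mean_image, px, py)
      mx <- max(prof, na.rm = TRUE)
      tol <- 1e-9 * max(abs(mx), 1)
      is_max <- !is.na(prof) & prof >= mx - tol
      ## outer edge of the first maximal run
      first <- which(is_max)[1]
      run_end <- first
      while (run_end < length(rr) && is_max[run_end + 1]) run_end <- run_end + 1
      bound[a] <- rr[run_end]
      bval[a] <- mx
    }
    seg <- median(bval) > bright && median(bound) < max_radius_px - 0.5
    mask <- matrix(FALSE, nrow(mean_image), ncol(mean_image))
    area <- 0
    if (seg) {
      r0 <- ceiling(max(bound))
      xs <- max(1, floor(sx - r0)):min(ncol(mean_image), ceiling(sx + r0))
      ys <- max(1, floor(sy - r0)):min(nrow(mean_image), ceiling(sy + r0))
      for (yy in ys) for (xx in xs) {
        dx <- xx - sx; dy <- yy - sy
        r <- sqrt(dx^2 + dy^2)
        th <- atan2(dy, dx) %% (2 * pi)
        blim <- stats::approx(c(ang, 2 * pi), c(bound, bound[1]),
                              xout = th)$y
        if (r <= blim + 0.5) mask[yy, xx] <- TRUE
      }
      area <- sum(mask)
    }
    out <- rbind(out, data.frame(x = sx, y = sy, area_px = area,
                                 radius_px = mean(bound),
                                 segmentable = seg))
    masks[[length(masks) + 1]] <- mask
  }
  attr(out, "masks") <- masks
  out
}

bilinear <- function(img, x, y) {
  nx <- ncol(img); ny <- nrow(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  x0 <- pmin(floor(x[ok]), nx - 1); y0 <- pmin(floor(y[ok]), ny - 1)
  fx <- x[ok] - x0; fy <- y[ok] - y0
  out[ok] <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
  out
}
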