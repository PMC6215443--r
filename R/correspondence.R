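# Quantitative stress-fabric comparison: axial mean directions within
# anatomical spheres, angular deviations, field downsampling, equal-angle
# stereonet projection, and the scalar correspondence score that drives
# the posture search.  All directional quantities are axial (sign-free).

#' Mean axis of a set of unit axes
#'
#' Principal eigenvector of the orientation tensor (mean of outer
#' products), the canonical mean for axial data: it is invariant to sign
#' flips of any subset of axes.  Ties between the top two eigenvalues are
#' broken by the lexicographically smallest axis representative and
#' flagged via the `tie` attribute.  The returned axis is canonicalized
#' so its largest-magnitude component is positive.
#'
#' @param axes n x 3 matrix of unit axes (rows)
#' @return unit 3-vector with attributes `eigenvalues` and `tie`
#' @export
mean_axis <- function(axes) {
  if (is.null(dim(axes))) axes <- matrix(axes, 1)
  axes <- as.matrix(axes)
  if (nrow(axes) < 1) stop("empty axis set")
  Tm <- crossprod(axes) / nrow(axes)
  ei <- eigen(Tm, symmetric = TRUE)
  v <- ei$vectors[, 1]
  tie <- (ei$values[1] - ei$values[2]) < 1e-12
  if (tie) {
    # deterministic tie-break: smallest canonical representative,
    # comparing the two leading eigenvectors lexicographically
    cand <- lapply(1:2, function(i) canonical_axis(ei$vectors[, i]))
    ord <- order(vapply(cand, function(u)
      u[1] * 4 + u[2] * 2 + u[3], 0))
    v <- cand[[ord[1]]]
  }
  v <- canonical_axis(v)
  attr(v, "eigenvalues") <- ei$values
  attr(v, "tie") <- tie
  v
}

canonical_axis <- function(u) {
  u <- unit3(u)
  if (u[which.max(abs(u))] < 0) u <- -u
  u
}

#' Angular deviation between two axes
#'
#' acos(|a . b|) in degrees: axial (sign-free), in [0, 90].
#'
#' @param a,b unit 3-vectors (normalized internally; zero vectors error)
#' @return degrees
#' @export
angular_deviation <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  rad2deg(acos(min(abs(sum(a * b)), 1)))
}

#' Percent reduction from a worst to a best angular deviation
#'
#' @param worst worst-posture deviation (degrees, > 0)
#' @param best best-posture deviation (degrees)
#' @return integer percent: round(100 (worst - best) / worst)
#' @export
#' @examples
#' percent_reduction(15.6, 7.3)  # 53
percent_reduction <- function(worst, best) {
  if (worst <= 0) stop("worst deviation must be positive")
  round(100 * (worst - best) / worst)
}

#' Angular deviation within one ROI
#'
#' Mean stress axis (sigma_3 for compressive-mode, sigma_1 for
#' tensile-mode ROIs) versus mean fabric axis over the lattice points
#' inside the ROI sphere.
#'
#' @param stress a stress field from [stress_trajectory_field()]
#' @param fabric a `fabric_field`
#' @param roi a [spherical_roi()]
#' @param min_points minimum lattice points required inside the sphere
#' @return deviation in degrees, with attributes `n_points`,
#'   `mean_stress_axis`, `mean_fabric_axis`
#' @export
roi_deviation <- function(stress, fabric, roi, min_points = 10) {
  inside <- function(df) {
    df$bone == roi$bone &
      (df$x - roi$centre[1])^2 + (df$y - roi$centre[2])^2 +
      (df$z - roi$centre[3])^2 <= roi$radius^2
  }
  fs <- fabric[inside(fabric), , drop = FALSE]
  ss <- stress[inside(stress), , drop = FALSE]
  if (nrow(fs) < min_points || nrow(ss) < min_points)
    stop("too few lattice points inside ROI '", roi$label, "' (",
         nrow(fs), " fabric, ", nrow(ss), " stress)")
  cols <- if (roi$mode == "tensile") c("s1x", "s1y", "s1z")
          else c("s3x", "s3y", "s3z")
  ms <- mean_axis(as.matrix(ss[, cols]))
  mf <- mean_axis(as.matrix(fs[, c("ux", "uy", "uz")]))
  dev <- angular_deviation(ms, mf)
  attr(dev, "n_points") <- nrow(fs)
  attr(dev, "mean_stress_axis") <- as.vector(ms)
  attr(dev, "mean_fabric_axis") <- as.vector(mf)
  dev
}

#' Downsample an axis field to a regular grid
#'
#' At each node of a regular grid with the requested spacing, the mean
#' axis (orientation-tensor mean, so no spurious vector cancellation) of
#' all field axes within one spacing radius; nodes with no neighbours are
#' dropped.  Applied per bone.
#'
#' @param field a `fabric_field`-like data.frame (`bone,x,y,z,ux,uy,uz`)
#' @param grid_spacing grid step (m)
#' @return data.frame in the same format on the grid nodes
#' @export
downsample_field <- function(field, grid_spacing) {
  stopifnot(nrow(field) > 0, grid_spacing > 0)
  ext <- max(apply(field[, c("x", "y", "z")], 2,
                   function(v) diff(range(v))))
  if (grid_spacing > ext)
    stop("grid spacing (", grid_spacing, ") exceeds field extent (",
         signif(ext, 4), ")")
  out <- list()
  for (bone in unique(field$bone)) {
    fb <- field[field$bone == bone, , drop = FALSE]
    gx <- seq(min(fb$x), max(fb$x) + grid_spacing / 2, by = grid_spacing)
    gy <- seq(min(fb$y), max(fb$y) + grid_spacing / 2, by = grid_spacing)
    gz <- seq(min(fb$z), max(fb$z) + grid_spacing / 2, by = grid_spacing)
    g <- expand.grid(x = gx, y = gy, z = gz)
    U <- as.matrix(fb[, c("ux", "uy", "uz")])
    rows <- lapply(seq_len(nrow(g)), function(i) {
      d2 <- (fb$x - g$x[i])^2 + (fb$y - g$y[i])^2 + (fb$z - g$z[i])^2
      sel <- d2 <= grid_spacing^2
      if (!any(sel)) return(NULL)
      m <- mean_axis(U[sel, , drop = FALSE])
      data.frame(bone = bone, x = g$x[i], y = g$y[i], z = g$z[i],
                 ux = m[1], uy = m[2], uz = m[3])
    })
    out[[bone]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equal-angle stereonet projection of an axis
#'
#' Folds the axis into the requested hemisphere, then projects with
#' r = tan((90 - plunge)/2), azimuth preserved; north is +y on the plot.
#'
#' @param axis unit 3-vector
#' @param hemisphere `"northern"` or `"southern"`
#' @return plot coordinates `c(x, y)` in the unit disc
#' @export
#' @examples
#' stereonet_equal_angle(c(0, 0, 1))       # centre
#' stereonet_equal_angle(c(0, 1, 0))       # primitive circle, north
stereonet_equal_angle <- function(axis,
                                  hemisphere = c("northern", "southern")) {
  hemisphere <- match.arg(hemisphere)
  u <- unit3(axis)
  if ((hemisphere == "northern" && u[3] < 0) ||
      (hemisphere == "southern" && u[3] > 0)) u <- -u
  plunge <- asin(min(abs(u[3]), 1))            # radians, from horizontal
  r <- tan((pi / 2 - plunge) / 2)
  trend <- atan2(u[1], u[2])                   # clockwise from north (+y)
  c(x = r * sin(trend), y = r * cos(trend))
}

#' Invert an equal-angle stereonet projection
#'
#' @param xy plot coordinates `c(x, y)`
#' @param hemisphere hemisphere used in the projection
#' @return the folded unit axis
#' @export
stereonet_invert <- function(xy, hemisphere = c("northern", "southern")) {
  hemisphere <- match.arg(hemisphere)
  r <- sqrt(sum(xy^2))
  plunge <- pi / 2 - 2 * atan(r)
  trend <- atan2(xy[1], xy[2])
  z <- sin(plunge) * if (hemisphere == "northern") 1 else -1
  c(cos(plunge) * sin(trend), cos(plunge) * cos(trend), z)
}

#' Correspondence score between a stress field and a fabric field
#'
#' Per-ROI angular deviations and their unweighted mean, the scalar that
#' drives the posture search.
#'
#' @param stress stress field ([stress_trajectory_field()])
#' @param fabric `fabric_field`
#' @param rois list of [spherical_roi()]
#' @param weights optional per-ROI weights (default equal)
#' @param min_points minimum points per ROI
#' @return a `correspondence_report`: data.frame `per_roi` (label, mode,
#'   deviation, n_points) plus `overall_score` (degrees) and `failed`
#'   labels
#' @export
correspondence_score <- function(stress, fabric, rois, weights = NULL,
                                 min_points = 10) {
  labs <- vapply(rois, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("ROI labels must be unique")
  if (is.null(weights)) weights <- rep(1, length(rois))
  devs <- rep(NA_real_, length(rois))
  npts <- rep(NA_integer_, length(rois))
  failed <- character()
  for (i in seq_along(rois)) {
    d <- tryCatch(roi_deviation(stress, fabric, rois[[i]], min_points),
                  error = function(e) e)
    if (inherits(d, "error")) {
      failed <- c(failed, labs[i])
    } else {
      devs[i] <- as.numeric(d)
      npts[i] <- attr(d, "n_points")
    }
  }
  ok <- !is.na(devs)
  score <- if (all(ok)) sum(weights[ok] * devs[ok]) / sum(weights[ok])
           else NA_real_
  structure(list(
    per_roi = data.frame(label = labs,
                         mode = vapply(rois, `[[`, "", "mode"),
                         deviation = devs, n_points = npts),
    overall_score = score, failed = failed),
    class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat("<correspondence_report> overall score:",
      if (is.na(x$overall_score)) "undefined"
      else paste0(signif(x$overall_score, 4), " deg"), "\n")
  print(x$per_roi, row.names = FALSE)
  if (length(x$failed))
    cat("failed ROIs:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
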