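# Quantitative evaluation: morphological similarity (surface deviation) and
# edge fitness (curve deviation), plus descriptive statistics.

new_deviation_report <- function(per_point, max_location = NULL,
                                 max_label = "n/a", kind = "surface") {
  rmsd <- sqrt(mean(per_point^2))
  structure(list(rmsd = rmsd, max_deviation = max(per_point),
                 max_location = max_location, max_label = max_label,
                 per_point = per_point, kind = kind),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("%s deviation: RMSD %.3f mm, max %.3f mm%s (%d points)\n",
              x$kind, x$rmsd, x$max_deviation,
              if (!identical(x$max_label, "n/a"))
                sprintf(" at %s", x$max_label) else "",
              length(x$per_point)))
  invisible(x)
}

#' Surface deviation between two meshes (3D compare)
#'
#' Unsigned point-to-surface distance from every vertex of `test` to the
#' `reference` surface (exact closest point on any reference triangle, not
#' vertex-to-vertex).  RMSD of these distances is the "3D surface
#' deviation"; their maximum is the "max surface deviation".  The metric is
#' directional: `test` is the reconstructed nose, `reference` the original
#' nose.
#'
#' @param test A [face_mesh()] whose vertices are measured.
#' @param reference A [face_mesh()] whose surface is measured against.
#' @param subunits Optional character vector of subunit labels, one per
#'   `reference` vertex; the maximum deviation is localized to the label of
#'   the reference vertex nearest to the worst test point.
#' @return A `deviation_report`: `rmsd`, `max_deviation`, `max_location`
#'   (3-vector, the worst test vertex), `max_label`, `per_point` (mm).
#' @export
surface_deviation <- function(test, reference, subunits = NULL) {
  if (nrow(test$vertices) == 0L || nrow(reference$vertices) == 0L)
    stopf("empty mesh")
  cp <- closest_point_on_mesh(test$vertices, reference)
  imax <- which.max(cp$dist)
  label <- "n/a"
  if (!is.null(subunits)) {
    if (length(subunits) != nrow(reference$vertices))
      stopf("need one subunit label per reference vertex")
    nn <- nearest_neighbor(test$vertices[imax, , drop = FALSE],
                           reference$vertices)
    label <- as.character(subunits[nn$index])
  }
  new_deviation_report(cp$dist, max_location = test$vertices[imax, ],
                       max_label = label, kind = "surface")
}

# Resample a closed polyline to n points uniformly by arc length.
resample_closed_curve <- function(points, n) {
  pts <- rbind(points, points[1, ])
  seg <- row_norms(diff(pts))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- (seq_len(n) - 1) / n * total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / seg[idx]
  pts[idx, , drop = FALSE] +
    frac * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
}

# Min distance from each row of p to a closed polyline (continuous: closest
# point on any segment, not vertex-snapped).
dist_to_polyline <- function(p, points, closed = TRUE) {
  a <- points
  b <- if (closed) rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
       else points[-1, , drop = FALSE]
  if (!closed) a <- a[-nrow(a), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab * ab)
  vapply(seq_len(nrow(p)), function(i) {
    ap <- matrix(p[i, ], nrow(a), 3, byrow = TRUE) - a
    t_ <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
    d <- ap - t_ * ab
    sqrt(min(rowSums(d * d)))
  }, numeric(1))
}

#' Curve deviation between two boundary curves (edge fitness)
#'
#' Both closed curves are resampled to `n_samples` points uniformly by arc
#' length; each resampled point of `nose_edge` is paired with its closest
#' point anywhere on the `defect_edge` polyline.  RMSD of the pair distances
#' is the "curve deviation", their maximum the "max curve deviation".
#'
#' @param nose_edge Edge [boundary_curve()] of the reconstructed nose.
#' @param defect_edge Defect edge [boundary_curve()] of the defective face.
#' @param n_samples Number of arc-length samples (default 200, >= 8).
#' @return A `deviation_report` (subunit label `"n/a"`).
#' @export
curve_deviation <- function(nose_edge, defect_edge, n_samples = 200) {
  if (!isTRUE(nose_edge$closed) || !isTRUE(defect_edge$closed))
    stopf("curve_deviation needs closed curves")
  if (n_samples < 8) stopf("n_samples must be >= 8")
  a <- resample_closed_curve(nose_edge$points, n_samples)
  bpts <- resample_closed_curve(defect_edge$points, n_samples)
  d <- dist_to_polyline(a, bpts, closed = TRUE)
  imax <- which.max(d)
  new_deviation_report(d, max_location = a[imax, ], max_label = "n/a",
                       kind = "curve")
}

#' Summarize deviation reports (mean +/- SD, subunit tally)
#'
#' @param reports List of `deviation_report` objects (>= 2).
#' @return List of class `deviation_summary`: `n`, `rmsd_mean`, `rmsd_sd`,
#'   `max_mean`, `max_sd` (sample SD, n-1 denominator), and
#'   `subunit_tally` (named counts of max-deviation locations).
#' @export
summarize_deviations <- function(reports) {
  if (length(reports) < 2L) stopf("need at least 2 reports")
  rmsd <- vapply(reports, `[[`, numeric(1), "rmsd")
  mx <- vapply(reports, `[[`, numeric(1), "max_deviation")
  labels <- vapply(reports, `[[`, character(1), "max_label")
  tally <- table(factor(labels[labels != "n/a"], levels = NASAL_SUBUNITS))
  structure(list(n = length(reports),
                 rmsd_mean = mean(rmsd), rmsd_sd = stats::sd(rmsd),
                 max_mean = mean(mx), max_sd = stats::sd(mx),
                 subunit_tally = tally),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("deviation over %d cases: RMSD %.2f +/- %.2f mm, max %.2f +/- %.2f mm\n",
              x$n, x$rmsd_mean, x$rmsd_sd, x$max_mean, x$max_sd))
  if (sum(x$subunit_tally) > 0) {
    cat("  max-deviation subunit tally:\n")
    t <- x$subunit_tally[x$subunit_tally > 0]
    for (nm in names(t)) cat(sprintf("    %-18s %d\n", nm, t[[nm]]))
  }
  invisible(x)
}
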