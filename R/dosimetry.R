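# Dose metrics: volume-weighted quantiles of the field strength |E| within
# regions of interest, pairwise montage/model comparisons, signed difference
# maps and hot-spot extraction.

#' Volume-weighted quantiles
#'
#' Quantiles of per-element values weighted by element volume, by linear
#' interpolation on the cumulative-volume curve. Values are sorted and knot
#' positions are `p_i = (C_i - u) / (C_n - u)` with `C` the cumulative
#' volume and `u = min(w)`; below the first knot the curve is flat. With
#' equal weights this reduces exactly to `stats::quantile(type = 7)`, and it
#' is invariant to rescaling all volumes.
#'
#' @param x numeric values (e.g. per-element |E|).
#' @param w positive weights (e.g. element volumes); `NULL` for equal
#'   weights.
#' @param probs quantile probabilities between 0 and 1.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(length(x) > 0, all(probs >= 0 & probs <= 1))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w > 0))
  if (length(x) == 1) return(rep(x, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  C <- cumsum(w)
  u <- min(w)
  p <- (C - u) / (C[length(C)] - u)
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Volume-weighted dose statistics in a region of interest
#'
#' The field "dose" of a region is summarized as the volume-weighted median
#' of the element field strengths |E|, and the homogeneity of the field as
#' the interquartile range (IQR = Q3 - Q1): a low IQR means a uniformly
#' distributed field in the tissue.
#'
#' @param solution a `tt_solution`.
#' @param mesh the `tet_mesh` the solution was computed on.
#' @param roi_labels character vector of tissue labels defining the region
#'   (default: the tumor compartments present in the mesh).
#' @param weighted volume-weighted statistics (default) or plain per-element
#'   quantiles.
#' @return object of class `dose_stats` with `median_Vpm`, `q1_Vpm`,
#'   `q3_Vpm`, `iqr_Vpm`, `n_elements` and `volume_mm3`.
#' @export
roi_statistics <- function(solution, mesh,
                           roi_labels = c("tumor_shell", "tumor_core"),
                           weighted = TRUE) {
  sel <- mesh$label %in% roi_labels
  if (!any(sel)) {
    stop("region of interest is empty for label(s): ",
         paste(roi_labels, collapse = ", "))
  }
  x <- solution$normE[sel]
  w <- if (weighted) mesh$element_volume[sel] else NULL
  q <- weighted_quantile(x, w, probs = c(0.25, 0.5, 0.75))
  structure(list(roi_labels = roi_labels,
                 median_Vpm = q[2], q1_Vpm = q[1], q3_Vpm = q[3],
                 iqr_Vpm = q[3] - q[1],
                 n_elements = sum(sel),
                 volume_mm3 = sum(mesh$element_volume[sel]),
                 weighted = weighted),
            class = "dose_stats")
}

#' @export
print.dose_stats <- function(x, ...) {
  cat("dose_stats [", paste(x$roi_labels, collapse = "+"), "]: ",
      x$n_elements, " elements, ", format(x$volume_mm3), " mm^3\n", sep = "")
  cat(sprintf("  median %.2f V/m  (Q1 %.2f, Q3 %.2f, IQR %.2f)\n",
              x$median_Vpm, x$q1_Vpm, x$q3_Vpm, x$iqr_Vpm))
  invisible(x)
}

#' Volume fraction where one solution's field is at least the other's
#'
#' Ties count towards the "greater or equal" fraction, matching the clinical
#' comparison "equal or higher field strength".
#'
#' @param solA,solB two `tt_solution`s on the same mesh.
#' @param mesh the common `tet_mesh`.
#' @param roi_labels tissue labels defining the region of interest.
#' @return the volume fraction of the region where `|E_A| >= |E_B|`.
#' @export
pairwise_fraction_ge <- function(solA, solB, mesh,
                                 roi_labels = c("tumor_shell",
                                                "tumor_core")) {
  sel <- mesh$label %in% roi_labels
  if (!any(sel)) {
    stop("region of interest is empty for label(s): ",
         paste(roi_labels, collapse = ", "))
  }
  w <- mesh$element_volume[sel]
  sum(w[solA$normE[sel] >= solB$normE[sel]]) / sum(w)
}

#' Signed per-element field-strength difference between two solutions
#'
#' @param solA,solB two `tt_solution`s on the same mesh.
#' @param mesh the common `tet_mesh`.
#' @return object of class `field_difference` with the per-element signed
#'   `delta_Vpm = |E_A| - |E_B|` and its volume-weighted median; swapping
#'   the arguments flips the sign of both.
#' @export
difference_map <- function(solA, solB, mesh) {
  stopifnot(length(solA$normE) == length(solB$normE),
            length(solA$normE) == nrow(mesh$tets))
  delta <- solA$normE - solB$normE
  structure(list(delta_Vpm = delta,
                 median_delta_Vpm = weighted_quantile(
                   delta, mesh$element_volume, 0.5),
                 ids = c(solA$montage_id, solB$montage_id)),
            class = "field_difference")
}

#' Extract hot-spot elements above a volume-weighted percentile
#'
#' Elements whose field strength lies strictly above the volume-weighted
#' `percentile` of |E| in the region; `percentile = 0` returns the whole
#' region, and a uniform field yields no hot spots for any positive
#' percentile.
#'
#' @param solution a `tt_solution`.
#' @param mesh the `tet_mesh`.
#' @param percentile threshold percentile, at least 0 and below 100.
#' @param roi_labels optional tissue labels restricting the search
#'   (default: all elements).
#' @return integer element indices (into the full mesh) of the hot-spot set.
#' @export
hotspot_extract <- function(solution, mesh, percentile,
                            roi_labels = NULL) {
  stopifnot(percentile >= 0, percentile < 100)
  sel <- if (is.null(roi_labels)) {
    seq_len(nrow(mesh$tets))
  } else {
    which(mesh$label %in% roi_labels)
  }
  if (!length(sel)) stop("region of interest is empty")
  if (percentile == 0) return(sel)
  thr <- weighted_quantile(solution$normE[sel], mesh$element_volume[sel],
                           percentile / 100)
  sel[solution$normE[sel] > thr]
}

#' Write a dose-statistics table as CSV
#'
#' @param table a data.frame of sweep rows (see [run_position_sweep()]).
#' @param file output path.
#' @export
write_dose_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
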