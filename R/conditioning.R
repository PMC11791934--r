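## Digitization conditioning: fiducial-plane filter, robust outlier
## rejection, sagittal-mirror densification, density cap, inward shift.

#' Conditioning configuration
#'
#' Parameters for preparing digitized head-shape points before warping.
#' Defaults follow standard MEG digitization practice: keep points down to
#' ~1 cm below the fiducial plane, always discard 2% (at most 10%) of
#' points as scalp-distance outliers, mirror-densify sparse clouds
#' (< 50 points), cap density at 300 points, and compensate 1.5 mm of
#' stylus standoff.
#'
#' @param plane_margin_mm keep points above the plane this far below the
#'   fiducial plane (mm).
#' @param min_reject_frac,max_reject_frac outlier-rejection floor/ceiling
#'   as fractions of the point count.
#' @param densify_threshold point count below which sagittal mirroring
#'   triggers.
#' @param n_max density cap applied by farthest-point downsampling.
#' @param inward_shift_mm stylus-standoff compensation (mm, toward the
#'   head-frame origin).
#' @param dedupe_tol_mm mirrored points closer than this to an existing
#'   point are dropped.
#' @return an object of class `"conditioning_config"`.
#' @export
conditioning_config <- function(plane_margin_mm = 10, min_reject_frac = 0.02,
                                max_reject_frac = 0.10, densify_threshold = 50,
                                n_max = 300, inward_shift_mm = 1.5,
                                dedupe_tol_mm = 1.0) {
  if (min_reject_frac < 0 || min_reject_frac > max_reject_frac ||
      max_reject_frac > 0.5)
    pmri_stop("invalid_config", "need 0 <= min_reject_frac <= max_reject_frac <= 0.5")
  if (plane_margin_mm < 0) pmri_stop("invalid_config", "plane_margin_mm must be >= 0")
  if (n_max < 4) pmri_stop("invalid_config", "n_max must be >= 4")
  structure(list(plane_margin_mm = plane_margin_mm,
                 min_reject_frac = min_reject_frac,
                 max_reject_frac = max_reject_frac,
                 densify_threshold = densify_threshold,
                 n_max = n_max, inward_shift_mm = inward_shift_mm,
                 dedupe_tol_mm = dedupe_tol_mm),
            class = "conditioning_config")
}

#' Keep points above a plane below the fiducial plane
#'
#' Retains exactly the points with signed distance `> -margin_mm` from the
#' fiducial plane; the plane normal is oriented toward the centroid of the
#' point cloud (the top of the head). Points below the neck/face margin
#' carry no scalp information and destabilize the warp.
#'
#' @param points n x 3 matrix (mm), same frame as `fids`.
#' @param fids a [fiducials()] object.
#' @param margin_mm margin below the fiducial plane (mm).
#' @return list `(points, kept, dropped)` with kept row indices in input
#'   order.
#' @export
filter_below_fiducial_plane <- function(points, fids, margin_mm = 10) {
  points <- as_point_matrix(points)
  d <- fiducial_plane_distances(fids, points, toward = colMeans(points))
  keep <- d > -margin_mm
  list(points = points[keep, , drop = FALSE],
       kept = which(keep), dropped = which(!keep))
}

#' Reject head points far from the template scalp
#'
#' Distances to the template scalp are computed for every point; the
#' `ceiling(min_reject_frac * N)` most distant points are always removed,
#' and additionally any point beyond `median + 3 * 1.4826 * MAD` of the
#' distance distribution, up to `floor(max_reject_frac * N)` removals in
#' total. The removal fraction therefore always lies in
#' `[min_reject_frac, max_reject_frac]`.
#'
#' @param points n x 3 matrix rigidly co-registered to the template frame.
#' @param scalp template scalp [trimesh()].
#' @param cfg a [conditioning_config()].
#' @return list `(points, kept, dropped, distances)`.
#' @export
reject_scalp_outliers <- function(points, scalp, cfg = conditioning_config()) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (n < 10L)
    pmri_stop("too_few_points", "outlier rejection needs at least 10 points")
  d <- point_mesh_distances(points, scalp)
  n_min <- ceiling(cfg$min_reject_frac * n)
  n_cap <- floor(cfg$max_reject_frac * n)
  # order by distance descending; ties broken by higher index first
  ord <- order(d, seq_len(n), decreasing = TRUE)
  drop <- ord[seq_len(n_min)]
  thr <- median(d) + 3 * mad(d, constant = 1.4826)
  extra <- setdiff(ord[d[ord] > thr], drop)
  if (length(extra) > 0L && n_min < n_cap)
    drop <- c(drop, extra[seq_len(min(length(extra), n_cap - n_min))])
  keep <- setdiff(seq_len(n), drop)
  list(points = points[keep, , drop = FALSE], kept = keep,
       dropped = sort(drop), distances = d)
}

#' Densify head points by sagittal mirroring
#'
#' Exploits left-right head symmetry: reflects the points across the
#' sagittal plane (x = nasion_x in the head frame) and appends the
#' reflections, skipping any reflection closer than `dedupe_tol_mm` to an
#' existing or already-added point. Doubles point density (up to dedupe)
#' without any scalp database.
#'
#' @param points n x 3 matrix in the head frame.
#' @param fids head-frame [fiducials()] (fixes the sagittal plane).
#' @param dedupe_tol_mm duplicate-merge tolerance (mm).
#' @return list `(points, source_index)`; `source_index[i]` gives the input
#'   row each output row derives from (mirrored rows point to their
#'   original).
#' @export
mirror_densify <- function(points, fids, dedupe_tol_mm = 1.0) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  x0 <- fids$nasion[1]
  mir <- points
  mir[, 1] <- 2 * x0 - mir[, 1]
  keep <- logical(n)
  pool <- points
  for (i in seq_len(n)) {
    d <- row_norms(sweep(pool, 2, mir[i, ]))
    if (min(d) >= dedupe_tol_mm) {
      keep[i] <- TRUE
      pool <- rbind(pool, mir[i, ])
    }
  }
  list(points = rbind(points, mir[keep, , drop = FALSE]),
       source_index = c(seq_len(n), which(keep)))
}

#' Inward shift for stylus standoff
#'
#' Moves each point `shift_mm` along the ray toward `origin`, compensating
#' the systematic outward offset left by the stylus cap or hair during
#' digitization.
#'
#' @param points n x 3 matrix (mm).
#' @param origin length-3 head-frame origin.
#' @param shift_mm shift magnitude (mm, typically 1-2).
#' @return shifted n x 3 matrix.
#' @export
inward_shift <- function(points, origin = c(0, 0, 0), shift_mm = 1.5) {
  points <- as_point_matrix(points)
  if (shift_mm == 0) return(points)
  v <- sweep(points, 2, as.numeric(origin))
  r <- row_norms(v)
  if (any(r <= shift_mm + 1e-12))
    pmri_stop("degenerate_direction",
              "point at or within shift_mm of the origin")
  points - v * (shift_mm / r)
}

#' Full digitization-conditioning pipeline
#'
#' Composes, in order: fiducial-plane filter, robust scalp-distance
#' outlier rejection, sagittal-mirror densification when fewer than
#' `densify_threshold` points survive, farthest-point downsampling to
#' `n_max`, and the inward stylus-standoff shift. Points must already be
#' rigidly co-registered to the template frame and expressed in the head
#' frame (fiducial plane ~ z = 0).
#'
#' @param points n x 3 digitized scalp points (head frame, mm).
#' @param fids head-frame [fiducials()].
#' @param scalp template scalp [trimesh()] in the same frame.
#' @param cfg a [conditioning_config()].
#' @param seed integer used only for downsampling tie-breaks.
#' @param origin head-frame origin in the working frame (target of the
#'   inward shift).
#' @return list with `points` (the conditioned destination points) and
#'   `report` (per-stage counts and dropped indices).
#' @export
condition_digitization <- function(points, fids, scalp,
                                   cfg = conditioning_config(), seed = 0L,
                                   origin = c(0, 0, 0)) {
  points <- as_point_matrix(points)
  report <- list(input = nrow(points))
  st1 <- filter_below_fiducial_plane(points, fids, cfg$plane_margin_mm)
  report$after_plane_filter <- nrow(st1$points)
  report$plane_dropped <- st1$dropped
  st2 <- reject_scalp_outliers(st1$points, scalp, cfg)
  report$after_outlier_rejection <- nrow(st2$points)
  report$outlier_dropped <- st1$kept[st2$dropped]
  report$scalp_distance_before <- summary_stats(st2$distances)
  pts <- st2$points
  report$densified <- FALSE
  if (nrow(pts) < cfg$densify_threshold) {
    md <- mirror_densify(pts, fids, cfg$dedupe_tol_mm)
    pts <- md$points
    report$densified <- TRUE
  }
  report$after_densification <- nrow(pts)
  if (nrow(pts) > cfg$n_max) {
    ds <- farthest_point_downsample(pts, cfg$n_max, seed)
    pts <- ds$points
  }
  report$after_downsampling <- nrow(pts)
  if (nrow(pts) < 4L)
    pmri_stop("insufficient_coverage", "fewer than 4 points survived conditioning")
  if (cfg$inward_shift_mm > 0)
    pts <- inward_shift(pts, origin, cfg$inward_shift_mm)
  report$scalp_distance_after <- summary_stats(point_mesh_distances(pts, scalp))
  list(points = pts, report = report)
}

summary_stats <- function(x) {
  if (length(x) == 0L) return(list(n = 0L))
  list(n = length(x), mean = mean(x), median = median(x),
       min = min(x), max = max(x))
}
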