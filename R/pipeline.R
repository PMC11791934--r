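## End-to-end pseudo-MRI generation: load -> rigid co-registration ->
## conditioning -> control-point pairing + TPS -> warp everything ->
## write the output bundle, transform, config snapshot and report.

#' Engine configuration
#'
#' @param conditioning a [conditioning_config()].
#' @param kernel,lambda_init,lambda_growth,lambda_max,cond_max TPS solver
#'   settings (see [tps_fit()]).
#' @param targets names of bundle surfaces/volumes to warp; `NULL` warps
#'   everything present.
#' @param seed integer driving every stochastic step.
#' @param report_html also render the HTML report.
#' @return an object of class `"engine_config"`.
#' @export
engine_config <- function(conditioning = conditioning_config(),
                          kernel = "r", lambda_init = 1e-10,
                          lambda_growth = 10, lambda_max = 1e-2,
                          cond_max = 1e12, targets = NULL, seed = 1L,
                          report_html = FALSE) {
  if (lambda_init <= 0 || lambda_growth <= 1 || lambda_max <= 0 || cond_max <= 0)
    pmri_stop("invalid_config", "TPS solver parameters must be positive")
  structure(list(conditioning = conditioning, kernel = kernel,
                 lambda_init = lambda_init, lambda_growth = lambda_growth,
                 lambda_max = lambda_max, cond_max = cond_max,
                 targets = targets, seed = as.integer(seed),
                 report_html = report_html),
            class = "engine_config")
}

#' Generate a pseudo-MRI from a template bundle and head digitization
#'
#' Runs the full workflow: loads the template bundle and head-point file,
#' rigidly co-registers the head points to the template frame by matching
#' fiducials, conditions the digitization (plane filter, outlier
#' rejection, optional mirror densification, density cap, inward shift),
#' pairs control points by radial projection onto the template scalp,
#' solves the adaptively regularized TPS warp, applies it to every
#' target surface and volume, and writes the output bundle together with
#' the warp file, MRI-to-head transform, warped fiducials, config
#' snapshot and run report. On any stage error the partially written
#' output directory is removed.
#'
#' @param template_dir template bundle directory (see
#'   [write_template_bundle()]).
#' @param headpoints_path head-point file (text or JSON dialect).
#' @param out_dir output directory for the pseudo-MRI bundle.
#' @param config an [engine_config()].
#' @return run summary: control-point count, lambda, energies, residual
#'   RMS, per-surface fold counts, inverse round-trip error, paths.
#' @export
generate_pseudo_mri <- function(template_dir, headpoints_path, out_dir,
                                config = engine_config()) {
  existed <- dir.exists(out_dir)
  cleanup <- function() {
    if (!existed && dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  }
  tryCatch(
    generate_pseudo_mri_impl(template_dir, headpoints_path, out_dir, config),
    pseudomri_error = function(e) { cleanup(); stop(e) },
    error = function(e) { cleanup(); stop(e) })
}

generate_pseudo_mri_impl <- function(template_dir, headpoints_path, out_dir,
                                     config) {
  report <- list()
  # (a, b) inputs
  hp <- read_headpoints(headpoints_path)
  template <- load_template_bundle(template_dir)
  report$a_headpoints <- list(n_points = nrow(hp$points),
                              n_hpi = sum(hp$labels == "hpi"))
  report$b_template <- list(surfaces = names(template$surfaces),
                            volumes = names(template$volumes))

  # (c) rigid co-registration by fiducial matching: head -> template frame
  head_to_mri <- fit_rigid_landmarks(fiducial_matrix(hp$fiducials),
                                     fiducial_matrix(template$fiducials),
                                     from_frame = "head", to_frame = "mri")
  mri_to_head <- invert_rigid(head_to_mri)
  scalp_pts <- hp$points[hp$labels != "hpi", , drop = FALSE]
  pts_mri <- apply_rigid(head_to_mri, scalp_pts)
  fid_res <- max(row_norms(apply_rigid(head_to_mri, fiducial_matrix(hp$fiducials)) -
                             fiducial_matrix(template$fiducials)))
  report$c_coregistration <- list(fiducial_residual_mm = fid_res)

  # template-frame head frame: template fiducials define the plane/origin
  tf_head <- define_head_frame(template$fiducials)
  origin_mri <- as.numeric(invert_rigid(tf_head)$translation)

  # (d, e) conditioning in the template frame
  cond <- condition_digitization(pts_mri, template$fiducials,
                                 template$surfaces$scalp,
                                 config$conditioning, seed = config$seed,
                                 origin = origin_mri)
  report$d_outlier_rejection <- cond$report[c("input", "after_plane_filter",
                                              "after_outlier_rejection")]
  report$e_densification <- cond$report[c("densified", "after_densification",
                                          "after_downsampling")]

  # (f) control points by radial projection + adaptive TPS solve; the
  # digitized fiducials (in the template frame) are appended as pairs so
  # the warp is anchored at the landmarks
  fidm_mri <- apply_rigid(head_to_mri, fiducial_matrix(hp$fiducials))
  cps <- pair_control_points(rbind(cond$points, fidm_mri),
                             template$surfaces$scalp, origin = origin_mri)
  warp <- tps_fit(cps$source, cps$destination, kernel = config$kernel,
                  lambda_init = config$lambda_init,
                  lambda_growth = config$lambda_growth,
                  lambda_max = config$lambda_max, cond_max = config$cond_max)
  report$f_warp <- list(n_control = warp$n, lambda_used = warp$lambda_used,
                        residual_rms_mm = warp$residual_rms,
                        bending_energy = warp$bending_energy,
                        residual_energy = warp$residual_energy,
                        n_projection_fallback = sum(cps$fallback))

  # (g) warp all target surfaces and volumes
  targets_s <- config$targets %||% names(template$surfaces)
  targets_v <- config$targets %||% names(template$volumes)
  folds <- list()
  out_surfaces <- list()
  for (nm in intersect(targets_s, names(template$surfaces))) {
    wm <- warp_mesh(warp, template$surfaces[[nm]])
    out_surfaces[[nm]] <- wm$mesh
    folds[[nm]] <- wm$n_flipped
  }
  inv <- NULL
  out_volumes <- list()
  if (length(intersect(targets_v, names(template$volumes)))) {
    inv <- build_inverse_warp(warp)
    for (nm in intersect(targets_v, names(template$volumes)))
      out_volumes[[nm]] <- warp_volume(warp, template$volumes[[nm]],
                                       inverse = inv)
  }
  fidm_w <- predict(warp, fiducial_matrix(template$fiducials))
  out_fids <- fiducials(fidm_w[1, ], fidm_w[2, ], fidm_w[3, ], frame = "mri")
  report$g_warp_applied <- list(
    surfaces = names(out_surfaces), volumes = names(out_volumes),
    flipped_faces = folds,
    inverse_roundtrip_median_mm = if (!is.null(inv))
      attr(inv, "roundtrip_median_mm") else NA)

  # (h) write output bundle + warp + transform + config + report
  out_bundle <- list(surfaces = out_surfaces, volumes = out_volumes,
                     fiducials = out_fids)
  write_template_bundle(out_bundle, out_dir)
  write_tps(warp, file.path(out_dir, "warp.json"))
  write_transform(mri_to_head, file.path(out_dir, "mri_head-trans.txt"))
  cfg_snapshot <- config
  class(cfg_snapshot) <- NULL
  cfg_snapshot$conditioning <- unclass(cfg_snapshot$conditioning)
  jsonlite::write_json(cfg_snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  report$h_output <- list(dir = out_dir,
                          files = list.files(out_dir, recursive = TRUE))
  write_report(report, file.path(out_dir, "report.json"),
               html = config$report_html)

  list(n_control = warp$n, lambda_used = warp$lambda_used,
       residual_rms = warp$residual_rms,
       bending_energy = warp$bending_energy,
       residual_energy = warp$residual_energy,
       fold_counts = folds, warp = warp,
       out_dir = out_dir, report = report)
}
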