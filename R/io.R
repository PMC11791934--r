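## Readers/writers: FreeSurfer binary surfaces, Wavefront OBJ, NIfTI-1
## volumes, head-point files, 4x4 transform text, bundle directories.

FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)

#' Read a triangulated surface file
#'
#' Supports the FreeSurfer binary triangle format (magic 0xFFFFFE,
#' big-endian) and Wavefront OBJ (extension `.obj`); OBJ 1-based face
#' indices are converted to this package's 1-based [trimesh()] directly,
#' FreeSurfer's 0-based indices are shifted.
#'
#' @param path file path.
#' @return a [trimesh()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path))
    pmri_stop("format_error", sprintf("no such file: %s", path))
  if (grepl("\\.obj$", path, ignore.case = TRUE)) return(read_obj(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(magic) < 3 || !all(magic == FS_TRIANGLE_MAGIC))
    pmri_stop("format_error",
              sprintf("%s: unknown magic at byte 0 (not a FreeSurfer triangle surface)", path))
  # comment string terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0)
      pmri_stop("format_error", sprintf("%s: unterminated comment header", path))
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  if (length(counts) < 2 || any(counts < 0))
    pmri_stop("format_error", sprintf("%s: malformed vertex/face counts", path))
  nv <- counts[1]; nf <- counts[2]
  v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  if (length(v) < 3 * nv)
    pmri_stop("format_error",
              sprintf("%s: vertex data truncated at byte %d (expected %d vertices)",
                      path, seek(con), nv))
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(f) < 3 * nf)
    pmri_stop("format_error",
              sprintf("%s: face data truncated at byte %d (expected %d faces)",
                      path, seek(con), nf))
  verts <- matrix(v, ncol = 3, byrow = TRUE)
  faces <- matrix(f, ncol = 3, byrow = TRUE) + 1L
  if (nf > 0 && (min(faces) < 1 || max(faces) > nv))
    pmri_stop("format_error", sprintf("%s: face index out of range", path))
  trimesh(verts, faces, allow_degenerate = TRUE)
}

#' Write a triangulated surface file
#'
#' Format chosen by extension: `.obj` gives Wavefront OBJ, anything else
#' the FreeSurfer binary triangle format. Vertices survive the FreeSurfer
#' round-trip within float32 precision; faces exactly.
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  if (grepl("\\.obj$", path, ignore.case = TRUE)) return(write_obj(mesh, path))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_TRIANGLE_MAGIC), con)
  writeBin(charToRaw("created by pseudomri\n\n"), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4, endian = "big")
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl)) pmri_stop("format_error", sprintf("%s: no vertices", path))
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  if (any(!is.finite(v)) || (length(f) && any(is.na(f))))
    pmri_stop("format_error", sprintf("%s: malformed OBJ records", path))
  trimesh(v, f, allow_degenerate = TRUE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Uses the sform when valid, else the qform. Integer-typed images are
#' loaded as label volumes, floating-point as intensity.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param role override the inferred `"intensity"`/`"label"` role.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, role = NULL) {
  if (!file.exists(path))
    pmri_stop("format_error", sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   class = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  data <- array(as.numeric(img), dim(img))
  if (is.null(role)) {
    role <- if (all(data == round(data)) &&
                 grepl("INT|UINT", toupper(RNifti::niftiHeader(img)$datatype_string %||% "")))
      "label" else "intensity"
  }
  volume_image(data, aff, role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a NIfTI-1 volume
#' @param vol a [volume_image()].
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  dat <- vol$data
  if (vol$role == "label") storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a digitized head-point file
#'
#' Two dialects: (a) whitespace-delimited text with one point per line,
#' `<category> <id> <x> <y> <z>`, categories `cardinal`/`hpi`/`extra` and
#' cardinal ids 1 = LPA, 2 = nasion, 3 = RPA; (b) JSON with explicit
#' `fiducials` (nasion/lpa/rpa), `points`, and a `units` field.
#' Coordinates are converted to mm; meters are auto-detected when every
#' coordinate magnitude is below 1.
#'
#' @param path file path.
#' @return list `(points, fiducials, labels)`; `labels` tags each row of
#'   `points` (`"extra"` or `"hpi"`). HPI coil points are never treated
#'   as scalp evidence downstream.
#' @export
read_headpoints <- function(path) {
  if (!file.exists(path))
    pmri_stop("format_error", sprintf("no such file: %s", path))
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*\\{", first)) return(read_headpoints_json(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) != 5)
  if (length(bad))
    pmri_stop("format_error",
              sprintf("%s: malformed record on line %d", path, bad[1]))
  cat_ <- vapply(toks, `[[`, "", 1)
  id <- vapply(toks, `[[`, "", 2)
  xyz <- do.call(rbind, lapply(toks, function(t) as.numeric(t[3:5])))
  if (any(!is.finite(xyz)))
    pmri_stop("format_error", sprintf("%s: non-numeric coordinates", path))
  card <- cat_ == "cardinal"
  fidm <- matrix(NA_real_, 3, 3)  # rows: lpa, nasion, rpa
  for (i in which(card)) {
    k <- match(id[i], c("1", "2", "3"))
    if (is.na(k))
      pmri_stop("format_error",
                sprintf("%s: unknown cardinal id '%s' on line %d", path, id[i], i))
    if (!is.na(fidm[k, 1]))
      pmri_stop("format_error",
                sprintf("%s: duplicated cardinal id %s on line %d", path, id[i], i))
    fidm[k, ] <- xyz[i, ]
  }
  if (anyNA(fidm))
    pmri_stop("missing_fiducials",
              sprintf("%s: missing cardinal landmark(s)", path))
  pts <- xyz[!card, , drop = FALSE]
  labels <- ifelse(cat_[!card] == "hpi", "hpi", "extra")
  scale <- if (max(abs(rbind(pts, fidm))) < 1) 1000 else 1
  list(points = pts * scale,
       fiducials = fiducials(fidm[2, ] * scale, fidm[1, ] * scale,
                             fidm[3, ] * scale, frame = "head"),
       labels = labels)
}

read_headpoints_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$fiducials) || anyNA(match(c("nasion", "lpa", "rpa"),
                                            names(obj$fiducials))))
    pmri_stop("missing_fiducials", sprintf("%s: missing fiducials", path))
  units <- obj$units %||% "mm"
  pts <- if (is.null(obj$points)) matrix(0, 0, 3) else
    matrix(as.numeric(as.matrix(obj$points)), ncol = 3)
  fid <- lapply(obj$fiducials[c("nasion", "lpa", "rpa")], as.numeric)
  scale <- if (identical(units, "m") ||
               (max(abs(c(pts, unlist(fid)))) < 1)) 1000 else 1
  list(points = pts * scale,
       fiducials = fiducials(fid$nasion * scale, fid$lpa * scale,
                             fid$rpa * scale, frame = "head"),
       labels = rep("extra", nrow(pts)))
}

#' Write a head-point text file
#' @param points n x 3 matrix (mm).
#' @param fids a [fiducials()].
#' @param path output path.
#' @param labels optional per-point categories (`"extra"` or `"hpi"`).
#' @export
write_headpoints <- function(points, fids, path, labels = NULL) {
  points <- as_point_matrix(points)
  if (is.null(labels)) labels <- rep("extra", nrow(points))
  con <- file(path, "w")
  on.exit(close(con))
  fm <- rbind(fids$lpa, fids$nasion, fids$rpa)
  writeLines(sprintf("cardinal %d %.17g %.17g %.17g", 1:3,
                     fm[, 1], fm[, 2], fm[, 3]), con)
  if (nrow(points))
    writeLines(sprintf("%s %d %.17g %.17g %.17g", labels, seq_len(nrow(points)),
                       points[, 1], points[, 2], points[, 3]), con)
  invisible(path)
}

#' Read/write a 4x4 rigid transform as plain text
#'
#' One header line `from=<a> to=<b> units=mm`, then four rows of four
#' numbers (row-major homogeneous matrix).
#'
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()].
#' @export
write_transform <- function(tf, path) {
  m <- rigid_to_mat4(tf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("from=%s to=%s units=mm", tf$from_frame, tf$to_frame), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1], regexec("from=(\\S+) to=(\\S+)", lines[1]))[[1]]
  if (length(hdr) != 3)
    pmri_stop("format_error", sprintf("%s: missing frame header", path))
  m <- do.call(rbind, lapply(lines[2:5],
                             function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!all(dim(m) == c(4, 4)) || any(!is.finite(m)))
    pmri_stop("format_error", sprintf("%s: malformed matrix", path))
  rigid_transform(m[1:3, 1:3], m[1:3, 4], hdr[2], hdr[3])
}

write_fiducials_json <- function(fids, path) {
  jsonlite::write_json(list(frame = fids$frame, nasion = fids$nasion,
                            lpa = fids$lpa, rpa = fids$rpa),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

read_fiducials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fiducials(obj$nasion, obj$lpa, obj$rpa, frame = obj$frame %||% "unknown")
}

#' Write a template bundle directory
#'
#' Layout: `surfaces/<name>.surf` (FreeSurfer binary),
#' `volumes/<name>.nii.gz`, `fiducials.json`, and a `manifest.json`
#' listing every file with an MD5 checksum.
#'
#' @param bundle list with `surfaces`, `volumes`, `fiducials` (as
#'   produced by [make_template()] or [load_template_bundle()]).
#' @param dir output directory (created).
#' @export
write_template_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "surfaces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
  files <- character(0)
  for (nm in names(bundle$surfaces)) {
    rel <- file.path("surfaces", paste0(nm, ".surf"))
    write_surface(bundle$surfaces[[nm]], file.path(dir, rel))
    files <- c(files, rel)
  }
  for (nm in names(bundle$volumes)) {
    rel <- file.path("volumes", paste0(nm, ".nii.gz"))
    write_volume(bundle$volumes[[nm]], file.path(dir, rel))
    files <- c(files, rel)
  }
  write_fiducials_json(bundle$fiducials, file.path(dir, "fiducials.json"))
  files <- c(files, "fiducials.json")
  sums <- as.character(tools::md5sum(file.path(dir, files)))
  manifest <- list(format = "pseudomri-bundle-1",
                   surfaces = as.list(setNames(
                     file.path("surfaces", paste0(names(bundle$surfaces), ".surf")),
                     names(bundle$surfaces))),
                   volumes = as.list(setNames(
                     file.path("volumes", paste0(names(bundle$volumes), ".nii.gz")),
                     names(bundle$volumes))),
                   volume_roles = as.list(setNames(
                     vapply(bundle$volumes, `[[`, "", "role"),
                     names(bundle$volumes))),
                   fiducials = "fiducials.json",
                   checksums = as.list(setNames(sums, files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a template bundle directory
#'
#' Verifies the manifest checksums before reading; a scalp surface is
#' mandatory since it anchors the control-point pairing.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @param verify_checksums refuse to load on checksum mismatch.
#' @return bundle list `(surfaces, volumes, fiducials, manifest)`.
#' @export
load_template_bundle <- function(dir, verify_checksums = TRUE) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    pmri_stop("incomplete_template", sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (verify_checksums && length(manifest$checksums)) {
    for (rel in names(manifest$checksums)) {
      got <- as.character(tools::md5sum(file.path(dir, rel)))
      if (is.na(got) || got != manifest$checksums[[rel]])
        pmri_stop("checksum_mismatch",
                  sprintf("checksum mismatch for %s", rel))
    }
  }
  if (!("scalp" %in% names(manifest$surfaces)))
    pmri_stop("incomplete_template", "bundle has no scalp surface")
  surfaces <- lapply(manifest$surfaces, function(rel)
    read_surface(file.path(dir, rel)))
  # manifest-declared roles override NIfTI datatype inference
  volumes <- lapply(names(manifest$volumes), function(nm)
    read_volume(file.path(dir, manifest$volumes[[nm]]),
                role = manifest$volume_roles[[nm]]))
  names(volumes) <- names(manifest$volumes)
  fids <- read_fiducials_json(file.path(dir, manifest$fiducials))
  list(surfaces = surfaces, volumes = volumes, fiducials = fids,
       manifest = manifest)
}

#' Write a pipeline run report
#'
#' JSON always; a minimal self-contained HTML rendering on request.
#'
#' @param report named list of per-stage entries.
#' @param path output path for the JSON report.
#' @param html also write an `.html` file next to it.
#' @export
write_report <- function(report, path, html = FALSE) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  if (html) {
    hpath <- sub("\\.json$", ".html", path)
    body <- paste(vapply(names(report), function(nm) {
      sprintf("<h2>%s</h2><pre>%s</pre>", nm,
              jsonlite::toJSON(report[[nm]], auto_unbox = TRUE, pretty = TRUE,
                               force = TRUE))
    }, ""), collapse = "\n")
    writeLines(sprintf(
      "<html><head><title>pseudo-MRI report</title></head><body>%s</body></html>",
      body), hpath)
  }
  invisible(path)
}
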