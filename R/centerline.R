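#' Vessel centerline
#'
#' An ordered polyline of world-coordinate points (mm) tracing a vessel from
#' proximal to distal, with the rigid transform mapping the occluded side
#' onto the contralateral side and, optionally, an explicit contralateral
#' centerline used to snap the mirrored reference position onto the actual
#' contralateral vessel axis.
#'
#' @param points n x 3 matrix of world points, proximal first.
#' @param mirror `rigid_transform` mapping the occluded onto the
#'   contralateral side (e.g. a 180-degree rotation about the midsagittal
#'   axis when the vessel plane is symmetric about it).
#' @param contralateral optional m x 3 matrix, contralateral vessel polyline.
#' @return object of class `centerline_path`.
#' @export
centerline_path <- function(points, mirror = rigid_transform(),
                            contralateral = NULL) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L || nrow(pts) < 2L ||
      any(!is.finite(pts))) {
    perv_error("points must be a finite n x 3 matrix with n >= 2",
               "perv_input_error")
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg <= 0)) {
    perv_error("consecutive centerline points must be distinct",
               "perv_input_error")
  }
  if (!inherits(mirror, "rigid_transform")) {
    perv_error("mirror must be a rigid_transform", "perv_input_error")
  }
  if (!is.null(contralateral)) {
    contralateral <- as.matrix(contralateral)
    if (ncol(contralateral) != 3L || any(!is.finite(contralateral))) {
      perv_error("contralateral must be a finite m x 3 matrix",
                 "perv_input_error")
    }
  }
  structure(
    list(points = unname(pts), mirror = mirror,
         contralateral = if (is.null(contralateral)) NULL else unname(contralateral),
         arclen = c(0, cumsum(seg))),
    class = "centerline_path"
  )
}

#' Total arc length of a centerline
#' @param path a `centerline_path`.
#' @return arc length in mm.
#' @export
centerline_length <- function(path) {
  path$arclen[length(path$arclen)]
}

#' Point on a centerline at a given arc length
#' @param path a `centerline_path`.
#' @param s arc length(s) in mm from the proximal end, in `[0, L]`.
#' @return 3-vector (or n x 3 matrix) of world coordinates.
#' @export
centerline_point_at <- function(path, s) {
  L <- centerline_length(path)
  if (any(s < -1e-9 | s > L + 1e-9)) {
    perv_error(sprintf("arc length out of range [0, %.3f]", L),
               "perv_geometry_error")
  }
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, path$arclen, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(path$points) - 1L)
  f <- (s - path$arclen[idx]) / (path$arclen[idx + 1L] - path$arclen[idx])
  out <- path$points[idx, , drop = FALSE] * (1 - f) +
    path$points[idx + 1L, , drop = FALSE] * f
  if (length(s) == 1L) as.numeric(out) else out
}

# closest point on a polyline to p; returns list(point, dist)
nearest_on_polyline <- function(pts, p) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  t <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
  proj <- a + ab * t
  d2 <- rowSums((proj - matrix(p, nrow(a), 3, byrow = TRUE))^2)
  i <- which.min(d2)
  list(point = as.numeric(proj[i, ]), dist = sqrt(d2[i]))
}

#' Read a centerline from JSON
#'
#' Schema: `{"points_mm": [[x,y,z],...], "mirror": {"rotation_deg": [...],
#' "translation_mm": [...]}, "contralateral_points_mm": [[...]] (optional)}`.
#'
#' @param path JSON file path.
#' @return a `centerline_path`.
#' @export
read_centerline_json <- function(path) {
  if (!file.exists(path)) {
    perv_error(sprintf("centerline file not found: %s", path),
               "perv_input_error")
  }
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    perv_error(sprintf("malformed centerline JSON: %s",
                                       conditionMessage(e)),
                               "perv_input_error")
                  })
  if (is.null(obj$points_mm)) {
    perv_error("centerline JSON lacks required field 'points_mm'",
               "perv_input_error")
  }
  mirror <- rigid_transform()
  if (!is.null(obj$mirror)) {
    mirror <- rigid_transform(
      rotation_deg = obj$mirror$rotation_deg %||% c(0, 0, 0),
      translation_mm = obj$mirror$translation_mm %||% c(0, 0, 0),
      center_mm = obj$mirror$center_mm %||% c(0, 0, 0))
  }
  centerline_path(obj$points_mm, mirror = mirror,
                  contralateral = obj$contralateral_points_mm)
}

#' Write a centerline to JSON
#' @param path a `centerline_path`.
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_centerline_json <- function(path, file) {
  obj <- list(
    points_mm = unname(path$points),
    mirror = list(rotation_deg = path$mirror$rotation_deg,
                  translation_mm = path$mirror$translation_mm,
                  center_mm = path$mirror$center_mm))
  if (!is.null(path$contralateral)) {
    obj$contralateral_points_mm <- unname(path$contralateral)
  }
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
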