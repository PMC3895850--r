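#' DENSE acquisition container
#'
#' One displacement-encoded slice: a magnitude image plus one wrapped
#' phase image per encoding acquisition, with geometry and encoding
#' metadata. Phase images are stored wrapped to (-pi, pi] and
#' reference-uncorrected; the encoding direction of the reference
#' acquisition is the zero vector or, for balanced sets, any member
#' designated by `reference`.
#'
#' @param magnitude 2-D numeric matrix (signal units).
#' @param phases list of 2-D wrapped-phase matrices, one per acquisition.
#' @param encoding_directions numeric matrix (n_acq x 3); row a is the
#'   displacement-sensitivity direction of acquisition a (unit length,
#'   or zero for a pure reference).
#' @param k_e encoding frequency in cycles/mm (> 0).
#' @param pixel_spacing (dx, dy) mm.
#' @param slice_thickness mm.
#' @param reference index of the reference acquisition (default 1).
#' @return object of class `dense_acquisition`.
#' @export
dense_acquisition <- function(magnitude, phases, encoding_directions,
                              k_e, pixel_spacing, slice_thickness = 8,
                              reference = 1L) {
  if (!is.matrix(magnitude)) abort("magnitude must be a matrix", "format_error")
  if (!is.list(phases) || length(phases) < 1)
    abort("phases must be a non-empty list of matrices", "format_error")
  dims <- dim(magnitude)
  for (ph in phases) {
    if (!is.matrix(ph) || !all(dim(ph) == dims))
      abort("all images must share one shape", "validation_error")
    if (any(ph <= -pi - 1e-12 | ph > pi + 1e-12))
      abort("phase values must lie in (-pi, pi]", "validation_error")
  }
  D <- as.matrix(encoding_directions)
  if (ncol(D) != 3 || nrow(D) != length(phases))
    abort("encoding_directions must be n_acq x 3", "validation_error")
  if (!is.numeric(k_e) || length(k_e) != 1 || k_e <= 0)
    abort("k_e must be a positive scalar (cycles/mm)", "validation_error")
  sp <- rep(pixel_spacing, length.out = 2)
  if (any(sp <= 0)) abort("pixel_spacing must be positive", "validation_error")
  reference <- as.integer(reference)
  if (reference < 1 || reference > length(phases))
    abort("reference index out of range", "validation_error")
  structure(list(magnitude = magnitude, phases = phases,
                 encoding_directions = D, k_e = k_e,
                 pixel_spacing = sp, slice_thickness = slice_thickness,
                 reference = reference),
            class = "dense_acquisition")
}

#' @export
print.dense_acquisition <- function(x, ...) {
  cat(sprintf(paste0("<dense_acquisition> %d x %d pixels, %d acquisitions, ",
                     "k_e = %g cycles/mm, pixel %g x %g mm\n"),
              nrow(x$magnitude), ncol(x$magnitude), length(x$phases),
              x$k_e, x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

fmt_matrix <- function(m) {
  apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
}

read_matrix_file <- function(path, nrow, ncol) {
  v <- scan(path, what = double(), quiet = TRUE)
  if (length(v) != nrow * ncol)
    abort(sprintf("array file %s has %d values, expected %d",
                  basename(path), length(v), nrow * ncol), "format_error")
  matrix(v, nrow = nrow, ncol = ncol, byrow = TRUE)
}

#' Write / read a DENSE acquisition directory
#'
#' One directory per slice: `meta.yaml` with all metadata plus
#' `magnitude.txt` and `phase_<a>.txt` whitespace-delimited arrays
#' written at full double precision, so write-then-read round trips are
#' bit exact.
#'
#' @param acq a [dense_acquisition()].
#' @param path directory to create/read.
#' @return `read_acquisition` returns a `dense_acquisition`;
#'   `write_acquisition` returns `path` invisibly.
#' @export
write_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "dense_acquisition"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "aortastretch-dense-v1",
    shape = as.integer(dim(acq$magnitude)),
    n_acquisitions = length(acq$phases),
    k_e = acq$k_e,
    pixel_spacing = as.numeric(acq$pixel_spacing),
    slice_thickness = acq$slice_thickness,
    reference = acq$reference,
    encoding_directions = lapply(seq_len(nrow(acq$encoding_directions)),
                                 function(i) as.numeric(acq$encoding_directions[i, ]))
  )
  yaml::write_yaml(meta, file.path(path, "meta.yaml"), precision = 17)
  writeLines(fmt_matrix(acq$magnitude), file.path(path, "magnitude.txt"))
  for (a in seq_along(acq$phases))
    writeLines(fmt_matrix(acq$phases[[a]]),
               file.path(path, sprintf("phase_%02d.txt", a)))
  invisible(path)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(path) {
  mf <- file.path(path, "meta.yaml")
  if (!file.exists(mf)) abort(sprintf("missing %s", mf), "format_error")
  meta <- yaml::read_yaml(mf)
  for (key in c("shape", "n_acquisitions", "k_e", "pixel_spacing",
                "encoding_directions", "reference"))
    if (is.null(meta[[key]]))
      abort(sprintf("acquisition metadata lacks required key '%s'", key),
            "format_error")
  nr <- meta$shape[1]; nc <- meta$shape[2]
  magnitude <- read_matrix_file(file.path(path, "magnitude.txt"), nr, nc)
  phases <- lapply(seq_len(meta$n_acquisitions), function(a)
    read_matrix_file(file.path(path, sprintf("phase_%02d.txt", a)), nr, nc))
  D <- do.call(rbind, lapply(meta$encoding_directions, as.numeric))
  dense_acquisition(magnitude, phases, D, k_e = meta$k_e,
                    pixel_spacing = as.numeric(meta$pixel_spacing),
                    slice_thickness = meta$slice_thickness %||% 8,
                    reference = meta$reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contour record
#'
#' Ordered (x, y) control points in mm with a role label and frame index.
#'
#' @param points n x 2 numeric matrix (mm).
#' @param role one of "inner", "outer", "mid", "lumen".
#' @param frame integer frame index (0-based; 0 for static contours).
#' @param closed logical; closed curves need >= 4 points.
#' @export
contour_record <- function(points, role, frame = 0L, closed = TRUE) {
  p <- as.matrix(points)
  if (ncol(p) != 2) abort("contour points must be n x 2", "validation_error")
  role <- match.arg(role, c("inner", "outer", "mid", "lumen"))
  if (closed && nrow(p) < 4)
    abort("a closed contour needs at least 4 points", "validation_error")
  if (nrow(p) > 1) {
    dup <- rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2) == 0
    if (any(dup)) abort("duplicated consecutive contour points", "validation_error")
  }
  structure(list(points = p, role = role, frame = as.integer(frame),
                 closed = isTRUE(closed)),
            class = "contour_record")
}

#' Write / read contour text files
#'
#' Plain text, one point per line (`x y` in mm, full precision), each
#' contour preceded by a header block:
#' \preformatted{
#' # role: inner
#' # frame: 0
#' # closed: TRUE
#' }
#' Multiple contours per file are supported; round trips are lossless
#' well below 1e-9 mm.
#'
#' @param contours a `contour_record` or list of them.
#' @param path file path.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour_record")) contours <- list(contours)
  lines <- character(0)
  for (ct in contours) {
    lines <- c(lines,
               sprintf("# role: %s", ct$role),
               sprintf("# frame: %d", ct$frame),
               sprintf("# closed: %s", ct$closed),
               sprintf("%.17g %.17g", ct$points[, 1], ct$points[, 2]),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_contours
#' @return `read_contours` returns a list of `contour_record`s.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such contour file: %s", path),
                                "format_error")
  lines <- readLines(path)
  out <- list()
  role <- NULL; frame <- 0L; closed <- TRUE; pts <- NULL
  flush <- function() {
    if (!is.null(role) && !is.null(pts))
      out[[length(out) + 1L]] <<- contour_record(pts, role, frame, closed)
    pts <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
      if (kv[1] == "role") { flush(); role <- kv[2] }
      if (kv[1] == "frame") frame <- as.integer(kv[2])
      if (kv[1] == "closed") closed <- as.logical(kv[2])
    } else {
      xy <- as.numeric(strsplit(ln, "\\s+")[[1]])
      if (length(xy) != 2 || any(is.na(xy)))
        abort(sprintf("malformed contour line: '%s'", ln), "format_error")
      pts <- rbind(pts, xy)
    }
  }
  flush()
  if (length(out) == 0) abort("contour file contains no contours", "format_error")
  out
}
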