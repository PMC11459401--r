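#' Area-of-interest schema for a combined-face stimulus
#'
#' Each stimulus pairs two emotional faces side by side. The default schema
#' has 11 regions per image: the two whole-face regions (`face_L`, `face_R`),
#' four facial-element regions per face (left eye, right eye, nose, mouth,
#' nested inside their face polygon) and one explicit `background` region
#' covering everything outside the two faces. Polygons are axis-aligned
#' rectangles in screen-pixel coordinates (origin top-left, y downward); any
#' simple polygon is accepted when building a schema by hand.
#'
#' @param image_index zero-based stimulus image index the schema describes.
#' @param geometry a [screen_geometry()] (used for the background extent).
#' @return An object of class `aoi_schema`: a list with `image_index` and
#'   `regions`, a named list where each region has `name`, `kind`
#'   (`"face"`, `"element"` or `"background"`), `parent` and `polygon`
#'   (n x 2 matrix of vertices).
#' @export
default_aoi_schema <- function(image_index = 0L, geometry = screen_geometry()) {
  rect <- function(x0, y0, x1, y1) {
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  face_w <- 700
  face_h <- 700
  y0 <- 190
  lx0 <- 160
  rx0 <- 1060
  elements <- function(x0, prefix, parent) {
    list(
      list(name = paste0(prefix, "_eye_L"), kind = "element", parent = parent,
           polygon = rect(x0 + 140, y0 + 190, x0 + 280, y0 + 270)),
      list(name = paste0(prefix, "_eye_R"), kind = "element", parent = parent,
           polygon = rect(x0 + 420, y0 + 190, x0 + 560, y0 + 270)),
      list(name = paste0(prefix, "_nose"), kind = "element", parent = parent,
           polygon = rect(x0 + 300, y0 + 310, x0 + 400, y0 + 450)),
      list(name = paste0(prefix, "_mouth"), kind = "element", parent = parent,
           polygon = rect(x0 + 230, y0 + 510, x0 + 470, y0 + 590))
    )
  }
  regions <- c(
    list(
      list(name = "face_L", kind = "face", parent = NA_character_,
           polygon = rect(lx0, y0, lx0 + face_w, y0 + face_h)),
      list(name = "face_R", kind = "face", parent = NA_character_,
           polygon = rect(rx0, y0, rx0 + face_w, y0 + face_h))
    ),
    elements(lx0, "face_L", "face_L"),
    elements(rx0, "face_R", "face_R"),
    list(
      list(name = "background", kind = "background", parent = NA_character_,
           polygon = rect(0, 0, geometry$width_px, geometry$height_px))
    )
  )
  names(regions) <- vapply(regions, `[[`, "", "name")
  structure(list(image_index = as.integer(image_index), regions = regions),
            class = "aoi_schema")
}

#' Region names of a schema
#' @param schema an `aoi_schema`.
#' @return character vector of region names in schema order.
#' @export
aoi_region_names <- function(schema) {
  names(schema$regions)
}

#' Point-in-polygon test with boundary counted inside
#'
#' Ray-casting containment for a simple polygon; points lying exactly on an
#' edge or vertex are counted as inside.
#'
#' @param px,py point coordinates (vectorised).
#' @param polygon n x 2 matrix of vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  if (!is.matrix(polygon) || ncol(polygon) != 2 || nrow(polygon) < 3) {
    stop("polygon must be an n x 2 matrix with n >= 3")
  }
  if (anyNA(polygon)) stop("malformed polygon: NA vertices")
  vx <- polygon[, 1]
  vy <- polygon[, 2]
  nv <- length(vx)
  jx <- vx[c(nv, seq_len(nv - 1))]
  jy <- vy[c(nv, seq_len(nv - 1))]
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    # boundary check: point on any edge segment
    dx1 <- vx - x; dy1 <- vy - y
    dx2 <- jx - x; dy2 <- jy - y
    cross <- dx1 * dy2 - dx2 * dy1
    dot <- dx1 * dx2 + dy1 * dy2
    if (any(abs(cross) < 1e-9 & dot <= 1e-9)) return(TRUE)
    inside <- FALSE
    for (k in seq_len(nv)) {
      if ((vy[k] > y) != (jy[k] > y)) {
        xint <- (jx[k] - vx[k]) * (y - vy[k]) / (jy[k] - vy[k]) + vx[k]
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Total fixation duration per area of interest
#'
#' Credits each fixation's full duration to every region whose polygon
#' contains its centroid; nested regions (an eye inside a face) both accrue.
#' The `background` region accrues only when the centroid falls inside no
#' face polygon, so the top-level regions (faces + background) are mutually
#' exclusive and their dwell totals sum exactly to the total fixation
#' duration.
#'
#' @param fixations an `event_table` (saccade rows are ignored) or any data
#'   frame with `kind`, `duration_ms`, `cx_px`, `cy_px`.
#' @param schema an `aoi_schema`.
#' @return Named numeric vector of dwell times in ms, one entry per region.
#' @export
aoi_dwell <- function(fixations, schema) {
  fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
  out <- stats::setNames(numeric(length(schema$regions)), names(schema$regions))
  if (nrow(fx) == 0) return(out)
  face_names <- names(schema$regions)[
    vapply(schema$regions, `[[`, "", "kind") == "face"]
  in_face <- rep(FALSE, nrow(fx))
  for (rn in names(schema$regions)) {
    reg <- schema$regions[[rn]]
    if (reg$kind == "background") next
    hit <- point_in_polygon(fx$cx_px, fx$cy_px, reg$polygon)
    out[rn] <- sum(fx$duration_ms[hit])
    if (rn %in% face_names) in_face <- in_face | hit
  }
  bg <- names(schema$regions)[
    vapply(schema$regions, `[[`, "", "kind") == "background"]
  for (rn in bg) out[rn] <- sum(fx$duration_ms[!in_face])
  out
}

#' Read / write an AOI schema as JSON
#'
#' @param schema an `aoi_schema`.
#' @param path file path.
#' @return `read_aoi_schema_json` returns an `aoi_schema`.
#' @export
write_aoi_schema_json <- function(schema, path) {
  obj <- list(
    image_index = schema$image_index,
    regions = lapply(unname(schema$regions), function(r) {
      list(name = r$name, kind = r$kind,
           parent = if (is.na(r$parent)) NULL else r$parent,
           polygon = unname(apply(r$polygon, 1, as.numeric, simplify = FALSE)))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aoi_schema_json
#' @export
read_aoi_schema_json <- function(path) {
  obj <- jsonlite::read_json(path)
  regions <- lapply(obj$regions, function(r) {
    list(name = r$name, kind = r$kind,
         parent = r$parent %||% NA_character_,
         polygon = do.call(rbind, lapply(r$polygon, function(v) {
           c(as.numeric(v[[1]]), as.numeric(v[[2]]))
         })))
  })
  names(regions) <- vapply(regions, `[[`, "", "name")
  structure(list(image_index = as.integer(obj$image_index), regions = regions),
            class = "aoi_schema")
}
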