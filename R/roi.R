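# Region-of-interest geometry: default stimulus layouts, JSON round-trip,
# and gaze-sample labelling with fixed precedence.

ROI_PRECEDENCE <- c("face", "body", "activity", "bio", "control",
                    "validation_target", "other")

#' Default synthetic ROI layouts per task and day
#'
#' Stimulus content is not rendered; ROIs are schematic rectangles whose
#' face-region area fractions equal the area-based chance levels used for
#' construct validity (AM 3.2%, SI 8.3%, SS 3.9% of the screen). Biomotion
#' uses left (biological motion) and right (control) panels. StaticScenes on
#' day 2 is the horizontal mirror of day 1.
#'
#' @param screen list(width_px, height_px, px_per_degree)
#' @param roi_area_frac named face-area fractions for AM/SI/SS
#' @return named list `task` or `task.day` -> data.frame with columns
#'   label, shape, x0, y0, x1, y1, t_start_ms, t_end_ms, affective
#' @export
default_rois <- function(screen = list(width_px = 1920L, height_px = 1200L,
                                       px_per_degree = 42),
                         roi_area_frac = c(AM = 0.032, SI = 0.083,
                                           SS = 0.039)) {
  W <- screen$width_px; H <- screen$height_px
  A <- W * H
  rect <- function(label, cx, cy, w, h, affective = FALSE) {
    data.frame(label = label, shape = "rect",
               x0 = cx - w / 2, y0 = cy - h / 2,
               x1 = cx + w / 2, y1 = cy + h / 2,
               t_start_ms = 0, t_end_ms = Inf,
               affective = affective, stringsAsFactors = FALSE)
  }
  face_rect <- function(frac) {
    # fixed aspect ratio 1.6 (two adjacent head-and-shoulder zones)
    w <- sqrt(frac * A * 1.6); h <- w / 1.6
    rect("face", 0.5 * W, 0.35 * H, w, h)
  }
  social <- function(frac) {
    rbind(face_rect(frac),
          rect("body", 0.5 * W, 0.52 * H, 500, 700),
          rect("activity", 0.5 * W, 0.915 * H, 700, 200))
  }
  bm <- rbind(rect("bio", 0.24 * W, 0.5 * H, 600, 600),
              rect("control", 0.76 * W, 0.5 * H, 600, 600))
  plr <- rect("other", 0.5 * W, 0.5 * H, 2 * 0.7 * screen$px_per_degree,
              2 * 0.7 * screen$px_per_degree)
  ss1 <- social(roi_area_frac[["SS"]])
  list(AM = social(roi_area_frac[["AM"]]),
       SI = social(roi_area_frac[["SI"]]),
       SS.1 = ss1,
       SS.2 = roi_mirror_x(ss1, W),
       BM = bm,
       PLR = plr)
}

#' Mirror an ROI table horizontally
#'
#' @param rois ROI data.frame
#' @param width_px screen width
#' @return mirrored ROI data.frame
#' @export
roi_mirror_x <- function(rois, width_px) {
  out <- rois
  out$x0 <- width_px - rois$x1
  out$x1 <- width_px - rois$x0
  out
}

# Pick the ROI table for a task on a given day.
rois_for <- function(roi_sets, task, day) {
  key <- paste(task, day, sep = ".")
  roi_sets[[key]] %||% roi_sets[[task]]
}

#' Write / read ROI definitions as JSON
#'
#' The on-disk schema is a list per task (or `task.day`) of objects with
#' fields label, shape ("rect" or "poly"), coords, t_start_ms, t_end_ms and
#' affective. Rect coords are `[x0, y0, x1, y1]`; poly coords are
#' `[[x...],[y...]]`.
#'
#' @param roi_sets named list of ROI data.frames
#' @param path JSON file path
#' @return `read_roi_json` returns the named list of ROI data.frames
#' @export
write_roi_json <- function(roi_sets, path) {
  enc <- lapply(roi_sets, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      coords <- if (r$shape == "rect") c(r$x0, r$y0, r$x1, r$y1)
                else list(x = r$poly_x[[1]], y = r$poly_y[[1]])
      list(label = r$label, shape = r$shape, coords = coords,
           t_start_ms = r$t_start_ms,
           t_end_ms = if (is.finite(r$t_end_ms)) r$t_end_ms else "inf",
           affective = r$affective)
    })
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(task_rois) {
    rows <- lapply(task_rois, function(r) {
      if (!all(c("label", "shape", "coords") %in% names(r)))
        stop_config("ROI entry missing label/shape/coords")
      if (!r$label %in% ROI_PRECEDENCE)
        stop_config("unknown ROI label '%s'", r$label)
      tend <- r$t_end_ms %||% "inf"
      tend <- if (identical(tend, "inf")) Inf else as.numeric(tend)
      if (r$shape == "rect") {
        co <- as.numeric(unlist(r$coords))
        if (length(co) != 4 || co[3] <= co[1] || co[4] <= co[2])
          stop_config("degenerate rect ROI '%s'", r$label)
        data.frame(label = r$label, shape = "rect",
                   x0 = co[1], y0 = co[2], x1 = co[3], y1 = co[4],
                   t_start_ms = as.numeric(r$t_start_ms %||% 0),
                   t_end_ms = tend,
                   affective = isTRUE(r$affective),
                   stringsAsFactors = FALSE)
      } else if (r$shape == "poly") {
        px <- as.numeric(unlist(r$coords$x)); py <- as.numeric(unlist(r$coords$y))
        if (length(px) < 3 || length(px) != length(py))
          stop_config("degenerate poly ROI '%s'", r$label)
        d <- data.frame(label = r$label, shape = "poly",
                        x0 = min(px), y0 = min(py), x1 = max(px), y1 = max(py),
                        t_start_ms = as.numeric(r$t_start_ms %||% 0),
                        t_end_ms = tend,
                        affective = isTRUE(r$affective),
                        stringsAsFactors = FALSE)
        d$poly_x <- list(px); d$poly_y <- list(py)
        d
      } else stop_config("unknown ROI shape '%s'", r$shape)
    })
    do.call(rbind_fill_poly, rows)
  })
}

# rbind ROI rows that may or may not carry polygon list-columns
rbind_fill_poly <- function(...) {
  rows <- list(...)
  has_poly <- any(vapply(rows, function(r) "poly_x" %in% names(r), logical(1)))
  if (has_poly)
    rows <- lapply(rows, function(r) {
      if (!"poly_x" %in% names(r)) { r$poly_x <- list(NULL); r$poly_y <- list(NULL) }
      r
    })
  do.call(rbind, rows)
}

#' Assign gaze samples to ROI labels
#'
#' Labels each tracked on-screen sample with the containing active region.
#' Overlaps are resolved by fixed precedence
#' face > body > activity > bio > control > validation_target > other.
#' Samples outside every region, off screen, or untracked get `NA`.
#'
#' @param x,y sample coordinates in pixels (origin top-left, half-open
#'   screen bounds)
#' @param t_ms sample times, compared against ROI time windows
#' @param rois ROI data.frame (one task/day)
#' @param screen list with width_px and height_px
#' @return character vector of labels (NA where unassigned)
#' @export
assign_sample_to_roi <- function(x, y, t_ms, rois,
                                 screen = list(width_px = 1920L,
                                               height_px = 1200L)) {
  lab <- rep(NA_character_, length(x))
  on_screen <- !is.na(x) & !is.na(y) &
    x >= 0 & x < screen$width_px & y >= 0 & y < screen$height_px
  ord <- order(match(rois$label, ROI_PRECEDENCE))
  for (i in ord) {
    r <- rois[i, ]
    active <- on_screen & is.na(lab) & t_ms >= r$t_start_ms & t_ms < r$t_end_ms
    if (!any(active)) next
    inside <- if (r$shape == "rect") {
      x >= r$x0 & x < r$x1 & y >= r$y0 & y < r$y1
    } else {
      point_in_polygon(x, y, r$poly_x[[1]], r$poly_y[[1]])
    }
    lab[active & inside] <- r$label
  }
  lab
}
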