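#' Build an AOI layout table
#'
#' An AOI (area of interest) is a labelled screen rectangle with a content
#' category. Categories: `payoff_own`, `payoff_other`, `difference`, `sum`
#' (the eight payoff cells, two options by four rows), `row_label` (the
#' four row captions), and the identity-box items `group_id`, `coin`,
#' `code`.
#'
#' @param name Unique AOI names.
#' @param category One of the categories above, per AOI.
#' @param x0,y0 Top-left corner, pixels (origin top-left, y downward).
#' @param w,h Width and height, pixels.
#' @param screen `c(width, height)` of the display.
#' @return A data.frame of class `aoi_layout`.
#' @export
aoi_layout <- function(name, category, x0, y0, w, h,
                       screen = c(1280, 1024)) {
  cats <- c("payoff_own", "payoff_other", "difference", "sum",
            "row_label", "group_id", "coin", "code")
  stopifnot(length(name) == length(category),
            all(category %in% cats), !anyDuplicated(name))
  layout <- data.frame(name = name, category = category,
                       x0 = x0, y0 = y0, w = w, h = h)
  if (any(layout$x0 < 0 | layout$y0 < 0 |
            layout$x0 + layout$w > screen[1] |
            layout$y0 + layout$h > screen[2]))
    stop("AOIs must lie within the screen", call. = FALSE)
  check_aoi_overlap(layout)
  attr(layout, "screen") <- screen
  class(layout) <- c("aoi_layout", "data.frame")
  layout
}

check_aoi_overlap <- function(layout) {
  n <- nrow(layout)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sep <- layout$x0[i] + layout$w[i] <= layout$x0[j] ||
      layout$x0[j] + layout$w[j] <= layout$x0[i] ||
      layout$y0[i] + layout$h[i] <= layout$y0[j] ||
      layout$y0[j] + layout$h[j] <= layout$y0[i]
    if (!sep)
      stop(sprintf("AOIs '%s' and '%s' overlap",
                   layout$name[i], layout$name[j]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign fixations to AOIs
#'
#' A fixation belongs to the AOI whose half-open rectangle
#' `[x0, x0 + w) x [y0, y0 + h)` contains its centroid; fixations outside
#' every AOI are labelled `"none"`. Overlapping layouts are rejected.
#'
#' @param fixations A data.frame from [detect_fixations()] (columns `x`,
#'   `y` at minimum).
#' @param layout An [aoi_layout()].
#' @return `fixations` with added columns `aoi` and `category`.
#' @export
assign_fixations <- function(fixations, layout) {
  stopifnot(is.data.frame(fixations), inherits(layout, "aoi_layout"))
  check_aoi_overlap(layout)
  lab <- rep("none", nrow(fixations))
  cat <- rep("none", nrow(fixations))
  for (k in seq_len(nrow(layout))) {
    inside <- fixations$x >= layout$x0[k] &
      fixations$x < layout$x0[k] + layout$w[k] &
      fixations$y >= layout$y0[k] &
      fixations$y < layout$y0[k] + layout$h[k]
    lab[inside] <- layout$name[k]
    cat[inside] <- layout$category[k]
  }
  fixations$aoi <- lab
  fixations$category <- cat
  fixations
}

#' Write / read an AOI layout as YAML
#'
#' @param layout An [aoi_layout()].
#' @param path File path.
#' @return `read_layout_yaml` returns an [aoi_layout()].
#' @export
write_layout_yaml <- function(layout, path) {
  obj <- list(screen = as.integer(attr(layout, "screen")),
              aois = lapply(seq_len(nrow(layout)), function(i) {
                as.list(layout[i, c("name", "category", "x0", "y0",
                                    "w", "h")])
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  a <- do.call(rbind, lapply(obj$aois, as.data.frame))
  aoi_layout(a$name, a$category, a$x0, a$y0, a$w, a$h,
             screen = unlist(obj$screen))
}
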