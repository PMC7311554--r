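#' Payoff table of the six primary SVO slider items
#'
#' Each of the six items offers nine (self, other) point allocations along
#' a line between two anchor allocations; respondents pick one per item.
#' The table ships with the package as a plain-text file.
#'
#' @return A data.frame with columns `item_id`, `position` (1-9),
#'   `alloc_self`, `alloc_other`.
#' @examples
#' head(svo_items())
#' @export
svo_items <- function() {
  path <- system.file("extdata", "svo_slider_items.csv",
                      package = "intergaze", mustWork = TRUE)
  utils::read.csv(path)
}

#' Compute the SVO angle from six slider responses
#'
#' The angle is `atan((mean_other - 50) / (mean_self - 50))`, in degrees,
#' where the means are taken over the six chosen allocations and 50 is the
#' neutral point of the slider scale. Larger angles indicate greater weight
#' on the other person's payoff.
#'
#' When `mean_self == 50` the slope is undefined; by convention the angle
#' is reported as 90 degrees when `mean_other > 50`, otherwise an error is
#' raised.
#'
#' @param responses A data.frame with columns `alloc_self` and
#'   `alloc_other`, one row per item (six rows).
#' @param validate If `TRUE`, check each response against the packaged item
#'   table (requires an `item_id` column).
#'
#' @return The SVO angle in degrees.
#' @examples
#' r <- data.frame(alloc_self = rep(85, 6), alloc_other = rep(85, 6))
#' svo_angle(r)  # 45
#' @export
svo_angle <- function(responses, validate = FALSE) {
  stopifnot(is.data.frame(responses),
            all(c("alloc_self", "alloc_other") %in% names(responses)))
  if (nrow(responses) != 6L)
    stop("exactly six primary-item responses are required", call. = FALSE)
  if (validate) {
    if (!"item_id" %in% names(responses))
      stop("validation requires an item_id column", call. = FALSE)
    items <- svo_items()
    for (i in seq_len(6L)) {
      ok <- any(items$item_id == responses$item_id[i] &
                  items$alloc_self == responses$alloc_self[i] &
                  items$alloc_other == responses$alloc_other[i])
      if (!ok)
        stop(sprintf("response %d is not one of item %s's nine allocations",
                     i, responses$item_id[i]), call. = FALSE)
    }
  }
  mean_self <- mean(responses$alloc_self)
  mean_other <- mean(responses$alloc_other)
  if (mean_self == 50) {
    if (mean_other > 50) return(90)
    stop("undefined slope: mean self-allocation equals the neutral point 50",
         call. = FALSE)
  }
  atan((mean_other - 50) / (mean_self - 50)) * 180 / pi
}

#' Classify an SVO angle into a preference type
#'
#' Uses the conventional open-interval cutoffs: prosocial for angles in
#' (22.45, 57.15) degrees, individualist in (-12.04, 22.45), competitive
#' below -12.04, altruistic above 57.15. Angles exactly on a cutoff are
#' labelled `"boundary"`.
#'
#' @param angle SVO angle(s) in degrees; finite.
#' @return A character vector of types.
#' @examples
#' svo_classify(c(30, 0, 22.45, -20, 60))
#' @export
svo_classify <- function(angle) {
  stopifnot(is.numeric(angle), all(is.finite(angle)))
  vapply(angle, function(a) {
    if (a %in% c(-12.04, 22.45, 57.15)) return("boundary")
    if (a > 22.45 && a < 57.15) return("prosocial")
    if (a > -12.04 && a < 22.45) return("individualist")
    if (a < -12.04) return("competitive")
    "altruistic"
  }, character(1))
}

#' Map an SVO angle to utility weights
#'
#' Bridges the continuous SVO measure to the decision weights of the
#' social-utility model via `w_own = cos(angle)`, `w_other = sin(angle)`.
#' This mapping preserves the angular geometry of the measure:
#' `atan(w_other / w_own)` recovers the angle exactly. An alternative
#' convex mapping (`w_own = 1 - w_other`) would compress extreme angles
#' and is not used.
#'
#' @param angle SVO angle in degrees, strictly inside (-90, 90).
#' @return A [social_preference()].
#' @examples
#' angle_to_weights(45)
#' angle_to_weights(0)   # pure self-interest: w = (1, 0)
#' @export
angle_to_weights <- function(angle) {
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  if (angle <= -90 || angle >= 90)
    stop("angle must lie strictly inside (-90, 90) degrees", call. = FALSE)
  rad <- angle * pi / 180
  structure(list(w_own = cos(rad), w_other = sin(rad), svo_angle = angle),
            class = "social_preference")
}

#' Read slider responses from a delimited file
#'
#' Expects columns `participant`, `item_id`, `alloc_self`, `alloc_other`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of responses.
#' @export
read_slider_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("participant", "item_id", "alloc_self", "alloc_other")
  if (!all(need %in% names(x)))
    stop("slider CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' Score a table of slider responses by participant
#'
#' @param responses A data.frame as returned by [read_slider_csv()].
#' @param validate Passed to [svo_angle()].
#' @return A data.frame with one row per participant: `participant`,
#'   `svo_angle`, `svo_type`.
#' @export
score_svo <- function(responses, validate = FALSE) {
  parts <- split(responses, responses$participant)
  out <- lapply(names(parts), function(p) {
    a <- svo_angle(parts[[p]], validate = validate)
    data.frame(participant = p, svo_angle = a, svo_type = svo_classify(a))
  })
  do.call(rbind, out)
}
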