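#' Construct an allocation option
#'
#' One of the two alternatives in a decomposed (minimal) dictator game: a
#' pair of payoffs, one for the decision maker ("own") and one for the
#' matched receiver ("other").
#'
#' @param own Own payoff in EUR; finite and non-negative.
#' @param other Receiver's payoff in EUR; finite and non-negative.
#' @param side Optional screen side, `"left"` or `"right"`.
#' @param role Optional annotation, `"selfish"` or `"prosocial"`.
#'
#' @return An object of class `allocation_option`.
#' @examples
#' allocation_option(7.50, 5.20)
#' @export
allocation_option <- function(own, other, side = NA_character_,
                              role = NA_character_) {
  stopifnot(is.numeric(own), is.numeric(other), length(own) == 1L,
            length(other) == 1L)
  if (!is.finite(own) || !is.finite(other) || own < 0 || other < 0)
    stop("payoffs must be finite and non-negative", call. = FALSE)
  if (!is.na(side)) side <- match.arg(side, c("left", "right"))
  if (!is.na(role)) role <- match.arg(role, c("selfish", "prosocial"))
  structure(list(own = own, other = other, side = side, role = role),
            class = "allocation_option")
}

#' Construct a social preference
#'
#' Decision weights placed on own and others' payoffs. Weights need not sum
#' to one; the canonical individualist and prosocial examples use
#' (0.9, 0.1) and (0.5, 0.5). If an SVO angle is supplied instead of
#' weights, they are derived as `w_own = cos(angle)`, `w_other = sin(angle)`
#' (see [angle_to_weights()]).
#'
#' @param w_own Weight on own payoff, >= 0.
#' @param w_other Weight on the receiver's payoff.
#' @param svo_angle Optional SVO angle in degrees used to derive weights.
#'
#' @return An object of class `social_preference` with fields `w_own`,
#'   `w_other` and (possibly `NA`) `svo_angle`.
#' @examples
#' social_preference(0.5, 0.5)
#' social_preference(svo_angle = 45)
#' @export
social_preference <- function(w_own = NULL, w_other = NULL, svo_angle = NULL) {
  if (is.null(w_own) && is.null(w_other)) {
    if (is.null(svo_angle))
      stop("supply either weights or an SVO angle", call. = FALSE)
    return(angle_to_weights(svo_angle))
  }
  stopifnot(is.numeric(w_own), is.numeric(w_other))
  if (!is.finite(w_own) || !is.finite(w_other) || w_own < 0)
    stop("w_own must be finite and non-negative; w_other finite",
         call. = FALSE)
  structure(list(w_own = w_own, w_other = w_other,
                 svo_angle = if (is.null(svo_angle)) NA_real_ else svo_angle),
            class = "social_preference")
}

#' Construct a group context
#'
#' The partner's group membership and the associated outgroup discount
#' `beta`. Ingroup partners carry `beta = 1`; outgroup partners carry
#' `0 < beta < 1`, multiplicatively down-weighting the receiver's payoff.
#'
#' @param membership `"ingroup"` or `"outgroup"`.
#' @param beta Discount factor; forced to 1 for ingroup, must lie strictly
#'   in (0, 1) for outgroup. Default 0.5.
#'
#' @return An object of class `group_context`.
#' @examples
#' group_context("ingroup")
#' group_context("outgroup", beta = 0.5)
#' @export
group_context <- function(membership = c("ingroup", "outgroup"), beta = 0.5) {
  membership <- match.arg(membership)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("beta must be a finite number", call. = FALSE)
  if (membership == "ingroup") {
    beta <- 1
  } else if (beta <= 0 || beta >= 1) {
    stop("outgroup beta must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(membership = membership, beta = beta),
            class = "group_context")
}

as_option <- function(x) {
  if (inherits(x, "allocation_option")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(allocation_option(x[1], x[2]))
  stop("expected an allocation_option or a numeric (own, other) pair",
       call. = FALSE)
}

as_preference <- function(x) {
  if (inherits(x, "social_preference")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(social_preference(x[1], x[2]))
  stop("expected a social_preference or a numeric (w_own, w_other) pair",
       call. = FALSE)
}

#' Social utility of an allocation option
#'
#' Computes `U = w_own * u(own) + beta * w_other * u(other)`, where `beta`
#' is 1 for ingroup partners and lies in (0, 1) for outgroup partners, so
#' that the ingroup case reduces to the undiscounted model
#' `U = w_own * u(own) + w_other * u(other)`. The payoff transform `u` is
#' the identity.
#'
#' @param option An [allocation_option()] or numeric `(own, other)` pair.
#' @param pref A [social_preference()] or numeric `(w_own, w_other)` pair.
#' @param ctx A [group_context()]. Defaults to ingroup.
#'
#' @return Utility as a single number (dimensionless, EUR-weighted).
#' @examples
#' utility(c(7.50, 5.20), c(0.5, 0.5))                        # 6.35
#' utility(c(7.50, 5.20), c(0.9, 0.1), group_context("outgroup", 0.5)) # 7.01
#' @export
utility <- function(option, pref, ctx = group_context("ingroup")) {
  option <- as_option(option)
  pref <- as_preference(pref)
  if (!inherits(ctx, "group_context"))
    stop("ctx must be a group_context", call. = FALSE)
  pref$w_own * option$own + ctx$beta * pref$w_other * option$other
}

#' Utility difference between two options
#'
#' Signed difference `U(A) - U(B)` (and its absolute value) under a social
#' preference and group context. The magnitude of this difference drives
#' the drift rate in the attentional drift-diffusion account of decision
#' effort: larger differences mean steeper evidence accumulation and less
#' effortful decisions.
#'
#' @param optA,optB The two options on a trial.
#' @inheritParams utility
#'
#' @return A list with `signed` (`U(A) - U(B)`) and `absolute`.
#' @examples
#' utility_difference(c(7.50, 5.20), c(6.90, 6.10), c(0.9, 0.1))$absolute # 0.45
#' @export
utility_difference <- function(optA, optB, pref,
                               ctx = group_context("ingroup")) {
  d <- utility(optA, pref, ctx) - utility(optB, pref, ctx)
  list(signed = d, absolute = abs(d))
}

#' Predict the chosen option
#'
#' Deterministic argmax choice under the discounted social-utility model,
#' with a declared tie-break applied when the absolute utility difference
#' falls below `tolerance`.
#'
#' @inheritParams utility_difference
#' @param tie_rule `"random"` (seeded by the caller's RNG state; mirrors
#'   indifference), `"first"` (option A), or `"abstain"` (`NA`).
#' @param tolerance Utility differences below this count as ties.
#'
#' @return `"A"`, `"B"`, or `NA_character_` when abstaining on a tie.
#' @examples
#' predict_choice(c(7.50, 5.20), c(6.90, 6.10), c(0.5, 0.5)) # "B"
#' @export
predict_choice <- function(optA, optB, pref, ctx = group_context("ingroup"),
                           tie_rule = c("random", "first", "abstain"),
                           tolerance = 1e-9) {
  tie_rule <- match.arg(tie_rule)
  d <- utility_difference(optA, optB, pref, ctx)
  if (d$absolute < tolerance) {
    return(switch(tie_rule,
                  random = sample(c("A", "B"), 1L),
                  first = "A",
                  abstain = NA_character_))
  }
  if (d$signed > 0) "A" else "B"
}

#' Change in the utility difference between group contexts
#'
#' How much the absolute utility difference between two options changes
#' when the partner switches from ingroup (`beta = 1`) to outgroup
#' (`beta = beta_out`): `| |dU_in| - |dU_out| |`. Under the identity payoff
#' transform this equals `|1 - beta_out| * w_other * |other_A - other_B|`
#' whenever the difference does not change sign. Decision makers whose
#' utility difference shifts more between contexts are predicted to show
#' larger context differences in processing effort.
#'
#' @inheritParams utility_difference
#' @param beta_out Outgroup discount in (0, 1].
#'
#' @return The absolute change in `|U(A) - U(B)|` across contexts.
#' @examples
#' # prosocial weights: the difference moves from 0.15 to 0.075
#' context_shift(c(7.50, 5.20), c(6.90, 6.10), c(0.5, 0.5), 0.5) # 0.075
#' @export
context_shift <- function(optA, optB, pref, beta_out) {
  if (!is.numeric(beta_out) || beta_out <= 0 || beta_out > 1)
    stop("beta_out must lie in (0, 1]", call. = FALSE)
  d_in <- utility_difference(optA, optB, pref)$absolute
  if (beta_out == 1) return(abs(d_in - d_in))
  d_out <- utility_difference(optA, optB, pref,
                              group_context("outgroup", beta_out))$absolute
  abs(d_in - d_out)
}

#' @export
print.allocation_option <- function(x, ...) {
  cat(sprintf("<allocation_option> own %.2f / other %.2f\n", x$own, x$other))
  invisible(x)
}

#' @export
print.social_preference <- function(x, ...) {
  cat(sprintf("<social_preference> w_own = %.4f, w_other = %.4f\n",
              x$w_own, x$w_other))
  invisible(x)
}

#' @export
print.group_context <- function(x, ...) {
  cat(sprintf("<group_context> %s (beta = %g)\n", x$membership, x$beta))
  invisible(x)
}
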