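#' Convert an annual probability to a monthly probability
#'
#' The engine advances in monthly cycles while lifetables and contraceptive
#' failure rates are quoted per year; `m = 1 - (1 - q)^(1/12)` so that
#' compounding twelve monthly draws reproduces the annual probability.
#'
#' @param q annual probability in \[0, 1\]; vectorised.
#' @return Monthly probability.
#' @export
annual_to_monthly <- function(q) {
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - q)^(1 / 12)
}

#' Draw month of delivery from a fetal lifetable
#'
#' Gestation length is drawn once at conception from a categorical
#' distribution over gestational months 7--10 (the monthly-resolution
#' analogue of a fetal lifetable).
#'
#' @param n number of draws.
#' @param probs probabilities over `months`; must sum to 1 (within 1e-8).
#' @param months candidate delivery months (default 7:10).
#' @return Integer vector of scheduled delivery months.
#' @export
schedule_delivery <- function(n, probs, months = 7:10) {
  probs <- as.numeric(probs)
  stopifnot(length(probs) == length(months), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("delivery-month distribution must sum to 1", call. = FALSE)
  }
  months[sample.int(length(months), n, replace = TRUE, prob = probs)]
}

#' Draw a desired family size from an inflated Poisson
#'
#' With probability `inflate_weight` the draw equals `inflate_value`
#' (a culturally focal family size); otherwise it is Poisson with mean
#' `lambda`.
#'
#' @param n number of draws.
#' @param inflate_weight mixture weight in \[0, 1\].
#' @param inflate_value inflation point (non-negative integer).
#' @param lambda Poisson mean (>= 0).
#' @return Integer vector of desired family sizes.
#' @export
desired_family_size <- function(n, inflate_weight, inflate_value, lambda) {
  stopifnot(length(inflate_weight) == 1L, length(lambda) == 1L)
  if (!is.finite(inflate_weight) || inflate_weight < 0 || inflate_weight > 1) {
    stop("inflate_weight must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0",
                                             call. = FALSE)
  if (!.is_count(inflate_value) || inflate_value < 0) {
    stop("inflate_value must be a non-negative integer", call. = FALSE)
  }
  k <- stats::rpois(n, lambda)
  inflated <- stats::runif(n) < inflate_weight
  k[inflated] <- inflate_value
  as.integer(k)
}

#' Real-world effectiveness of a clinical intervention
#'
#' An intervention's impact at a site interpolates between no effect and its
#' full efficacy: `RR_applied = 1 - a * kappa * (1 - RR_efficacy)`, where `a`
#' is the availability probability at that site and year and `kappa` in
#' \[0, 1\] the site quality factor. For curative interventions the result
#' multiplies the case-fatality rate; for preventive interventions it
#' multiplies complication incidence. Below the intervention's minimum
#' capable site the returned relative risk is 1 (no effect).
#'
#' @param availability probability the intervention can be used (per site/year).
#' @param quality site quality factor in \[0, 1\].
#' @param efficacy relative risk under ideal use, in \[0, 1\].
#' @param applicable logical; `FALSE` where the site is below the
#'   intervention's minimum site (returns 1 there). Vectorised.
#' @return Applied relative risk in \[`efficacy`, 1\].
#' @export
effectiveness <- function(availability, quality, efficacy, applicable = TRUE) {
  if (any(availability < 0 | availability > 1, na.rm = TRUE) ||
      any(quality < 0 | quality > 1, na.rm = TRUE) ||
      any(efficacy < 0 | efficacy > 1, na.rm = TRUE)) {
    stop("availability, quality and efficacy must lie in [0, 1]",
         call. = FALSE)
  }
  rr <- 1 - availability * quality * (1 - efficacy)
  app <- rep_len(applicable, length(rr))
  rr[!app] <- 1
  rr
}

# Zero-truncated Poisson draws by inversion (antenatal visit counts given
# any attendance).
.rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  lambda <- rep_len(lambda, n)
  lo <- stats::dpois(0, lambda)
  stats::qpois(lo + stats::runif(n) * (1 - lo), lambda)
}
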