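#' Hierarchical parameter prior
#'
#' A model parameter is represented on a transformed scale (logit for
#' probabilities, log for rates, identity for unbounded quantities) as a sum
#' of contributions from the five hierarchy levels. Each level carries a
#' mean and a non-negative dispersion; country-level values are obtained by
#' adding independent normal offsets (one per level along the country's
#' ancestor path) to the level means and applying the inverse transform.
#' This gives standard hierarchical shrinkage: countries in the same region,
#' continent or income group share the corresponding offsets.
#'
#' @param name parameter name (dot-namespaced, e.g. `"comp.pph.base"`).
#' @param scale `"logit"`, `"log"` or `"identity"`.
#' @param level_means numeric(5), transformed-scale mean per level
#'   (global, income_group, continent, region, country).
#' @param level_sds numeric(5), non-negative dispersion per level.
#' @param bounds optional natural-scale `c(lo, hi)` applied after the
#'   inverse transform.
#' @return Object of class `parameter_prior`.
#' @export
parameter_prior <- function(name, scale, level_means, level_sds, bounds = NULL) {
  .check_scale(scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  level_means <- as.numeric(level_means)
  level_sds <- as.numeric(level_sds)
  if (length(level_means) != 5L || length(level_sds) != 5L) {
    stop("level_means and level_sds must have length 5", call. = FALSE)
  }
  if (any(!is.finite(level_sds)) || any(level_sds < 0)) {
    stop("level_sds must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  }
  structure(
    list(name = name, scale = scale,
         level_means = stats::setNames(level_means, .geo_levels),
         level_sds = stats::setNames(level_sds, .geo_levels),
         bounds = bounds),
    class = "parameter_prior"
  )
}

#' Resolve a hierarchical prior to a country-level natural-scale value
#'
#' Sums the prior's level means and the supplied per-level offsets on the
#' transformed scale, applies the inverse transform and clips to the prior's
#' natural-scale bounds. Deterministic given the offsets; the order in which
#' level offsets are supplied does not matter.
#'
#' @param prior a [parameter_prior()].
#' @param offsets numeric(5) of transformed-scale offsets, one per level; a
#'   named vector is matched to the level names, an unnamed vector is taken
#'   in level order (global, income_group, continent, region, country).
#' @param country optional country id, validated against `hierarchy`.
#' @param hierarchy optional [geo_hierarchy()] used to validate `country`.
#' @return Natural-scale scalar.
#' @export
resolve_parameter <- function(prior, offsets, country = NULL, hierarchy = NULL) {
  stopifnot(inherits(prior, "parameter_prior"))
  if (!is.null(country)) {
    if (is.null(hierarchy)) stop("supply `hierarchy` to validate `country`",
                                 call. = FALSE)
    country_path(hierarchy, country) # errors if absent
  }
  offsets <- as.numeric(if (!is.null(names(offsets))) {
    if (!setequal(names(offsets), .geo_levels)) {
      stop("named offsets must cover exactly the five hierarchy levels",
           call. = FALSE)
    }
    offsets[.geo_levels]
  } else offsets)
  if (length(offsets) != 5L || any(!is.finite(offsets))) {
    stop("offsets must be 5 finite values", call. = FALSE)
  }
  val <- .inv(sum(prior$level_means) + sum(offsets), prior$scale)
  if (!is.null(prior$bounds)) val <- .clip(val, prior$bounds[1], prior$bounds[2])
  val
}

#' Draw one set of level offsets from a prior
#' @param prior a [parameter_prior()].
#' @return numeric(5) of transformed-scale offsets (one per level).
#' @export
draw_offsets <- function(prior) {
  stats::setNames(stats::rnorm(5L, 0, prior$level_sds), .geo_levels)
}

#' Damped time trend
#'
#' Year-varying parameters follow a linear trend on their transformed scale,
#' with an exponential damping factor `alpha` in (0, 1] controlling how the
#' trend saturates: the effective elapsed time is the partial geometric sum
#' `(1 - alpha^t) / (1 - alpha)`, which equals `t` when `alpha = 1` and is
#' bounded by `1 / (1 - alpha)` when `alpha < 1`. Trends are therefore
#' weakly monotone and cannot extrapolate to unreasonable levels.
#'
#' @param baseline transformed-scale intercept.
#' @param slope transformed-scale change per year.
#' @param damping `alpha` in (0, 1].
#' @param scale transform used to map back to the natural scale.
#' @return Object of class `trend_spec`.
#' @export
trend_spec <- function(baseline, slope, damping = 1, scale = "logit") {
  .check_scale(scale)
  stopifnot(is.numeric(baseline), is.numeric(slope), length(damping) == 1L)
  if (!is.finite(damping) || damping <= 0 || damping > 1) {
    stop("`damping` must lie in (0, 1]", call. = FALSE)
  }
  n <- max(length(baseline), length(slope))
  structure(
    list(baseline = rep_len(as.numeric(baseline), n),
         slope = rep_len(as.numeric(slope), n),
         damping = as.numeric(damping), scale = scale),
    class = "trend_spec"
  )
}

#' Evaluate a damped trend
#'
#' @param trend a [trend_spec()].
#' @param t years since the trend reference year (>= 0); vectorised.
#' @return Natural-scale value(s); for a vector-valued trend and vector `t`,
#'   a matrix with one row per trend element.
#' @export
trend_value <- function(trend, t) {
  stopifnot(inherits(trend, "trend_spec"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0",
                                             call. = FALSE)
  a <- trend$damping
  t_eff <- if (a == 1) t else (1 - a^t) / (1 - a)
  if (length(trend$baseline) == 1L) {
    .inv(trend$baseline + trend$slope * t_eff, trend$scale)
  } else {
    .inv(outer(trend$baseline, rep(1, length(t_eff))) +
           outer(trend$slope, t_eff), trend$scale)
  }
}

#' Read / write a prior catalogue as JSON
#'
#' `priors.json` is a list of records `{name, scale, level_means, level_sds,
#' bounds}` on the transformed scale.
#'
#' @param priors named list of [parameter_prior()] objects.
#' @param path file path.
#' @return `read_priors()` returns a named list of priors.
#' @export
write_priors <- function(priors, path) {
  recs <- lapply(priors, function(p) {
    list(name = p$name, scale = p$scale,
         level_means = unname(p$level_means),
         level_sds = unname(p$level_sds),
         bounds = if (is.null(p$bounds)) NULL else p$bounds)
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(recs)), function(i) {
    b <- recs$bounds[[i]]
    parameter_prior(recs$name[i], recs$scale[i],
                    recs$level_means[[i]], recs$level_sds[[i]],
                    bounds = if (all(is.na(b)) || is.null(b)) NULL else b)
  })
  stats::setNames(out, recs$name)
}
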