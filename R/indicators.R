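#' Cause-of-death groups
#'
#' The eight grouped maternal causes tracked by the simulator and used for
#' calibration targets. The first six direct/abortive causes double as the
#' fixed priority order used when a woman draws more than one fatal
#' complication in the same delivery (at most one maternal death is
#' recorded, attributed to the first fatal cause in this order).
#' @export
maternal_causes <- c("hemorrhage", "sepsis", "hypertensive",
                     "obstructed_labor", "other_direct", "abortive",
                     "indirect", "late")

.report_sources <- c("CRVS", "survey")
.lr_ages <- 15:49 # ages entering rate denominators and lifetime risk

#' Create an empty event tally
#'
#' An event tally holds per country-year counts accumulated by the engine:
#' live births, maternal deaths by the eight grouped causes, maternal deaths
#' by single age 15--49 (excluding late deaths), pregnancy-related deaths
#' (any cause during pregnancy or the 42-day window), all-cause deaths at
#' ages 15--49, person-years by single age 15--49, and reported maternal
#' deaths by cause and source (CRVS / survey) after underreporting.
#'
#' @param countries character vector of country ids.
#' @param years integer vector of calendar years.
#' @return Object of class `event_tally` (a list of count arrays).
#' @export
new_event_tally <- function(countries, years) {
  C <- length(countries); Y <- length(years)
  dn2 <- list(countries, as.character(years))
  structure(list(
    countries = countries, years = as.integer(years),
    live_births = matrix(0, C, Y, dimnames = dn2),
    deaths_cause = array(0, c(C, Y, 8L),
                         dimnames = c(dn2, list(maternal_causes))),
    mat_deaths_age = array(0, c(C, Y, length(.lr_ages)),
                           dimnames = c(dn2, list(as.character(.lr_ages)))),
    preg_related = matrix(0, C, Y, dimnames = dn2),
    deaths_all_1549 = matrix(0, C, Y, dimnames = dn2),
    py_age = array(0, c(C, Y, length(.lr_ages)),
                   dimnames = c(dn2, list(as.character(.lr_ages)))),
    reported = array(0, c(C, Y, 8L, 2L),
                     dimnames = c(dn2, list(maternal_causes, .report_sources)))
  ), class = "event_tally")
}

#' Aggregate a tally over countries
#'
#' Counts are additive, so regional or global tallies are exact sums of
#' their member countries' tallies.
#'
#' @param tally an `event_tally`.
#' @param countries subset of country ids to sum over (default all).
#' @param id label for the aggregate scope.
#' @return An `event_tally` with a single aggregated "country".
#' @export
aggregate_tally <- function(tally, countries = tally$countries, id = "ALL") {
  stopifnot(inherits(tally, "event_tally"), all(countries %in% tally$countries))
  i <- match(countries, tally$countries)
  agg <- new_event_tally(id, tally$years)
  agg$live_births[1, ] <- colSums(tally$live_births[i, , drop = FALSE])
  agg$preg_related[1, ] <- colSums(tally$preg_related[i, , drop = FALSE])
  agg$deaths_all_1549[1, ] <- colSums(tally$deaths_all_1549[i, , drop = FALSE])
  agg$deaths_cause[1, , ] <- apply(tally$deaths_cause[i, , , drop = FALSE],
                                   c(2, 3), sum)
  agg$mat_deaths_age[1, , ] <- apply(tally$mat_deaths_age[i, , , drop = FALSE],
                                     c(2, 3), sum)
  agg$py_age[1, , ] <- apply(tally$py_age[i, , , drop = FALSE], c(2, 3), sum)
  agg$reported[1, , , ] <- apply(tally$reported[i, , , , drop = FALSE],
                                 c(2, 3, 4), sum)
  agg
}

# maternal deaths within the 42-day window (direct + indirect, excluding late)
.maternal_deaths <- function(tally) {
  apply(tally$deaths_cause[, , maternal_causes != "late", drop = FALSE], c(1, 2), sum)
}

.py_1549 <- function(tally) apply(tally$py_age, c(1, 2), sum)

#' Maternal mortality ratio
#'
#' Maternal deaths (direct and indirect, within 42 days of the end of
#' pregnancy, excluding late maternal deaths) per 100,000 live births.
#'
#' @param tally an `event_tally`.
#' @return Matrix (country x year) of MMR values.
#' @export
mmr <- function(tally) {
  stopifnot(inherits(tally, "event_tally"))
  lb <- tally$live_births
  if (any(lb <= 0)) {
    stop("MMR undefined: zero live births in some country-year", call. = FALSE)
  }
  .maternal_deaths(tally) / lb * 1e5
}

#' Companion maternal mortality indicators
#'
#' * `pregnancy_mortality_ratio`: pregnancy-related deaths (any cause during
#'   pregnancy or the 42-day window) per 100,000 live births.
#' * `proportional_mortality_ratio`: maternal deaths as a percentage of all
#'   deaths among women aged 15--49.
#' * `maternal_mortality_rate`: maternal deaths per 100,000 women aged
#'   15--49 (person-years).
#' * `total_maternal_deaths`: maternal deaths plus late maternal deaths.
#'
#' Each indicator validates only its own denominator, so an empty
#' denominator (for example, no all-cause deaths in a small country-year)
#' makes only the affected indicator error.
#'
#' @param tally an `event_tally`.
#' @param indicators which of the four indicators to compute.
#' @return Named list of country x year matrices.
#' @export
indicator_suite <- function(tally,
                            indicators = c("pregnancy_mortality_ratio",
                                           "proportional_mortality_ratio",
                                           "maternal_mortality_rate",
                                           "total_maternal_deaths")) {
  stopifnot(inherits(tally, "event_tally"))
  indicators <- match.arg(indicators, several.ok = TRUE)
  md <- .maternal_deaths(tally)
  out <- list()
  for (ind in indicators) {
    out[[ind]] <- switch(ind,
      pregnancy_mortality_ratio = {
        if (any(tally$live_births <= 0)) {
          stop("zero live births: pregnancy mortality ratio undefined",
               call. = FALSE)
        }
        tally$preg_related / tally$live_births * 1e5
      },
      proportional_mortality_ratio = {
        if (any(tally$deaths_all_1549 <= 0)) {
          stop("zero all-cause deaths 15-49: proportional mortality undefined",
               call. = FALSE)
        }
        md / tally$deaths_all_1549 * 100
      },
      maternal_mortality_rate = {
        py <- .py_1549(tally)
        if (any(py <= 0)) {
          stop("zero person-years 15-49: mortality rate undefined",
               call. = FALSE)
        }
        md / py * 1e5
      },
      total_maternal_deaths = apply(tally$deaths_cause, c(1, 2), sum)
    )
  }
  out
}

#' Lifetime risk of maternal death
#'
#' The probability that a 15-year-old eventually dies of a maternal cause,
#' holding current fertility and mortality fixed: the sum over single ages
#' 15--49 of age-specific maternal mortality rates (maternal deaths at age
#' `a` divided by person-years lived at age `a`).
#'
#' @param tally an `event_tally`.
#' @return Matrix (country x year) of probabilities.
#' @export
lifetime_risk <- function(tally) {
  stopifnot(inherits(tally, "event_tally"))
  if (any(tally$py_age <= 0)) {
    stop("lifetime risk undefined: zero exposure at some age 15-49",
         call. = FALSE)
  }
  apply(tally$mat_deaths_age / tally$py_age, c(1, 2), sum)
}

#' Restrict a tally to a subset of years
#'
#' Typically used to drop burn-in years before computing indicators.
#'
#' @param tally an `event_tally`.
#' @param years years to keep (must be present in the tally).
#' @return An `event_tally` over `years`.
#' @export
restrict_tally <- function(tally, years) {
  stopifnot(inherits(tally, "event_tally"), all(years %in% tally$years))
  yi <- match(years, tally$years)
  out <- new_event_tally(tally$countries, years)
  out$live_births <- tally$live_births[, yi, drop = FALSE]
  out$preg_related <- tally$preg_related[, yi, drop = FALSE]
  out$deaths_all_1549 <- tally$deaths_all_1549[, yi, drop = FALSE]
  out$deaths_cause <- tally$deaths_cause[, yi, , drop = FALSE]
  out$mat_deaths_age <- tally$mat_deaths_age[, yi, , drop = FALSE]
  out$py_age <- tally$py_age[, yi, , drop = FALSE]
  out$reported <- tally$reported[, yi, , , drop = FALSE]
  out
}

#' Mean and 95% uncertainty interval across simulation iterations
#'
#' Uncertainty intervals are the 2.5 and 97.5 empirical percentiles of the
#' per-iteration values, using the linear-interpolation percentile
#' convention (`stats::quantile` type 7). Order-invariant in the input.
#'
#' @param values numeric vector of per-iteration values (length >= 2).
#' @return Named numeric: `mean`, `ui_lo`, `ui_hi`.
#' @export
uncertainty <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(values), ui_lo = q[1], ui_hi = q[2])
}

#' Derived comparison scalars
#'
#' Small arithmetic helpers for dashboard-style statements: percentage
#' decline between two values, percentage share of a total, and a plain
#' ratio.
#'
#' @param a,b,x,total,y finite numerics; denominators must be nonzero.
#' @return Numeric scalar (percent for `pct_decline` and `pct_share`).
#' @export
pct_decline <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (a == 0) stop("zero denominator", call. = FALSE)
  100 * (1 - b / a)
}

#' @rdname pct_decline
#' @export
pct_share <- function(x, total) {
  stopifnot(is.finite(x), is.finite(total))
  if (total == 0) stop("zero denominator", call. = FALSE)
  100 * x / total
}

#' @rdname pct_decline
#' @export
ratio_of <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  if (y == 0) stop("zero denominator", call. = FALSE)
  x / y
}

#' Summarise indicators across iterations as a long table
#'
#' @param tallies list of `event_tally` objects (one per iteration) sharing
#'   countries and years.
#' @param scope `"country"` or `"global"` (global sums all countries first).
#' @return data.frame with columns scope, scope_id, year, indicator, mean,
#'   ui_lo, ui_hi.
#' @export
indicator_table <- function(tallies, scope = c("country", "global")) {
  scope <- match.arg(scope)
  stopifnot(length(tallies) >= 2L)
  if (scope == "global") {
    tallies <- lapply(tallies, aggregate_tally, id = "GLOBAL")
  }
  t0 <- tallies[[1L]]
  suite_names <- c("pregnancy_mortality_ratio",
                   "proportional_mortality_ratio",
                   "maternal_mortality_rate", "total_maternal_deaths")
  inds <- lapply(tallies, function(tl) {
    out <- list(mmr = tryCatch(mmr(tl), error = function(e) NULL),
                lifetime_risk = tryCatch(lifetime_risk(tl),
                                         error = function(e) NULL))
    for (nm in suite_names) {
      out[[nm]] <- tryCatch(indicator_suite(tl, nm)[[nm]],
                            error = function(e) NULL)
    }
    out[!vapply(out, is.null, logical(1))]
  })
  keep <- Reduce(intersect, lapply(inds, names))
  if (length(keep) < 6L) {
    warning("indicator(s) undefined on this tally (zero denominators): ",
            paste(setdiff(c("mmr", "lifetime_risk",
                            "pregnancy_mortality_ratio",
                            "proportional_mortality_ratio",
                            "maternal_mortality_rate",
                            "total_maternal_deaths"), keep),
                  collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (nm in keep) {
    for (ci in seq_along(t0$countries)) {
      for (yi in seq_along(t0$years)) {
        v <- vapply(inds, function(x) x[[nm]][ci, yi], numeric(1))
        u <- uncertainty(v)
        rows[[length(rows) + 1L]] <- data.frame(
          scope = scope, scope_id = t0$countries[ci], year = t0$years[yi],
          indicator = nm, mean = u[["mean"]], ui_lo = u[["ui_lo"]],
          ui_hi = u[["ui_hi"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
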