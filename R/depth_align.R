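#' Construct a depth profile
#'
#' A depth profile is a continuous CTD cast: a strictly increasing depth grid
#' (metres below surface, positive down) plus one numeric column per measured
#' physicochemical parameter (conductivity, temperature, pressure, optionally
#' turbidity, ...). Rows containing any missing value are dropped with a
#' warning rather than imputed.
#'
#' @param depth numeric vector of depths in metres, strictly increasing after
#'   removal of incomplete rows.
#' @param ... named numeric vectors, one per parameter, each the same length
#'   as `depth`.
#' @return a `data.frame` of class `depth_profile` with a `depth_m` column
#'   followed by the parameter columns.
#' @export
#' @examples
#' depth_profile(depth = c(13, 14, 15), conductivity = c(120, 160, 200),
#'               temperature = c(8, 6, 5), pressure = c(1.3, 1.4, 1.5))
depth_profile <- function(depth, ...) {
  cols <- list(...)
  if (length(cols) == 0L) stop("a depth profile needs at least one parameter column")
  if (is.null(names(cols)) || any(names(cols) == ""))
    stop("all parameter columns must be named")
  lens <- vapply(cols, length, integer(1))
  if (any(lens != length(depth)))
    stop("all parameter columns must have the same length as depth")
  df <- data.frame(depth_m = as.numeric(depth), lapply(cols, as.numeric),
                   check.names = FALSE)
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    warning(sprintf("dropping %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows in profile")
  if (is.unsorted(df$depth_m, strictly = TRUE))
    stop("depth must be strictly increasing")
  rownames(df) <- NULL
  class(df) <- c("depth_profile", "data.frame")
  df
}

profile_params <- function(profile) setdiff(names(profile), "depth_m")

#' Construct a station record
#'
#' One stationary upcast sampling window, summarised as the mean of each
#' physicochemical parameter over the window, attached to the nominal bottle
#' depth.
#'
#' @param nominal_depth depth at which the bottle was nominally taken, m.
#' @param ... named scalar parameter means (at minimum conductivity,
#'   temperature and pressure for the default matching set).
#' @return an object of class `station_record`.
#' @export
station_record <- function(nominal_depth, ...) {
  means <- list(...)
  if (length(means) == 0L) stop("a station record needs at least one parameter mean")
  if (is.null(names(means)) || any(names(means) == ""))
    stop("all parameter means must be named")
  structure(list(nominal_depth = as.numeric(nominal_depth),
                 parameter_means = lapply(means, as.numeric)),
            class = "station_record")
}

#' @export
print.station_record <- function(x, ...) {
  cat(sprintf("station at %.2f m: %s\n", x$nominal_depth,
              paste(sprintf("%s=%.4g", names(x$parameter_means),
                            unlist(x$parameter_means)), collapse = ", ")))
  invisible(x)
}

#' Compute per-parameter normalization ranges
#'
#' Min/max per parameter over the union of the downcast values and the station
#' means, so that station values never clamp during normalization.
#'
#' @param downcast a [depth_profile()].
#' @param stations a list of [station_record()]s (may be empty).
#' @return named list of `c(min, max)` per shared parameter.
#' @export
compute_ranges <- function(downcast, stations = list()) {
  params <- profile_params(downcast)
  if (length(stations) > 0L) {
    station_params <- Reduce(union, lapply(stations, function(s) names(s$parameter_means)))
    params <- intersect(params, station_params)
  }
  if (length(params) == 0L) stop("no parameters shared between downcast and stations")
  ranges <- lapply(params, function(p) {
    vals <- downcast[[p]]
    for (s in stations)
      if (p %in% names(s$parameter_means)) vals <- c(vals, s$parameter_means[[p]])
    range(vals)
  })
  names(ranges) <- params
  ranges
}

#' Normalize a profile to a 0-100 percent scale
#'
#' Maps each parameter value v to 100 * (v - min) / (max - min). Values outside
#' the supplied range clamp to 0/100 with a warning. Parameters with a
#' degenerate range (max == min) are excluded from the returned profile with a
#' warning, because they carry no matching information.
#'
#' @param profile a [depth_profile()].
#' @param ranges named list of `c(min, max)` per parameter, as returned by
#'   [compute_ranges()].
#' @return a `depth_profile` on the percent scale, possibly with fewer
#'   parameter columns.
#' @export
normalize_profile <- function(profile, ranges) {
  params <- intersect(profile_params(profile), names(ranges))
  if (length(params) == 0L) stop("no parameter of the profile has a supplied range")
  out <- profile[, "depth_m", drop = FALSE]
  for (p in params) {
    r <- ranges[[p]]
    if (r[2] < r[1]) stop(sprintf("invalid range for %s: max < min", p))
    if (r[2] == r[1]) {
      warning(sprintf("parameter '%s' has a degenerate range and is excluded", p))
      next
    }
    v <- 100 * (profile[[p]] - r[1]) / (r[2] - r[1])
    n_clamp <- sum(v < 0 | v > 100)
    if (n_clamp > 0L) {
      warning(sprintf("parameter '%s': %d value(s) outside range clamped", p, n_clamp))
      v <- pmin(pmax(v, 0), 100)
    }
    out[[p]] <- v
  }
  if (length(profile_params(out)) == 0L)
    stop("all parameters had degenerate ranges")
  class(out) <- c("depth_profile", "data.frame")
  out
}

normalize_station <- function(station, ranges) {
  params <- intersect(names(station$parameter_means), names(ranges))
  pct <- list()
  for (p in params) {
    r <- ranges[[p]]
    if (r[2] == r[1]) next
    v <- 100 * (station$parameter_means[[p]] - r[1]) / (r[2] - r[1])
    pct[[p]] <- min(max(v, 0), 100)
  }
  pct
}

#' Match one station to the downcast water mass
#'
#' Finds the downcast row whose normalized physicochemical parameters are
#' closest to the station's normalized means, by minimizing the sum over
#' parameters of absolute percent differences. Ties are broken towards the
#' shallowest candidate depth.
#'
#' @param station a [station_record()] (raw, not normalized).
#' @param downcast_norm the downcast already normalized with
#'   [normalize_profile()].
#' @param ranges the same ranges used to normalize the downcast.
#' @param params parameters to use for matching; defaults to the conductivity,
#'   temperature, pressure trio intersected with what is available.
#' @return list with `corrected_depth` (m), `score` (minimal percent-difference
#'   sum) and `params_used`.
#' @export
match_depth <- function(station, downcast_norm, ranges,
                        params = c("conductivity", "temperature", "pressure")) {
  if (nrow(downcast_norm) == 0L) stop("empty downcast profile")
  station_pct <- normalize_station(station, ranges)
  use <- intersect(params, names(station_pct))
  use <- intersect(use, profile_params(downcast_norm))
  if (length(use) == 0L)
    stop("no usable parameters shared between station and downcast")
  score <- rep(0, nrow(downcast_norm))
  for (p in use)
    score <- score + abs(station_pct[[p]] - downcast_norm[[p]])
  best <- which(score == min(score))
  best <- best[which.min(downcast_norm$depth_m[best])]   # shallowest on ties
  list(corrected_depth = downcast_norm$depth_m[best],
       score = score[best], params_used = use)
}

#' Align upcast stations to the downcast profile
#'
#' Full depth-correction pass: normalization ranges are computed over the
#' union of downcast and station values, both sides are normalized to percent,
#' and each station is assigned the downcast depth with the most similar
#' physicochemical parameters. Internal waves shift water masses vertically
#' between casts, so the corrected depth is the depth the sampled water mass
#' occupied during the downcast.
#'
#' @param stations list of [station_record()]s.
#' @param downcast a [depth_profile()].
#' @param params matching parameter set, see [match_depth()].
#' @param ranges optional pre-computed ranges; defaults to [compute_ranges()].
#' @return data.frame with columns `nominal_depth_m`, `corrected_depth_m`,
#'   `score` and `shift_m` (corrected minus nominal; the audit trail of the
#'   applied correction).
#' @export
align_stations <- function(stations, downcast,
                           params = c("conductivity", "temperature", "pressure"),
                           ranges = NULL) {
  if (length(stations) == 0L) stop("no stations to align")
  if (is.null(ranges)) ranges <- compute_ranges(downcast, stations)
  downcast_norm <- normalize_profile(downcast, ranges)
  rows <- lapply(stations, function(s) {
    m <- match_depth(s, downcast_norm, ranges, params = params)
    data.frame(nominal_depth_m = s$nominal_depth,
               corrected_depth_m = m$corrected_depth,
               score = m$score,
               shift_m = m$corrected_depth - s$nominal_depth)
  })
  do.call(rbind, rows)
}
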