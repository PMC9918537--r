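# Threshold light-level geolocation: longitude from the sunrise/sunset
# midpoint, latitude from day length via the sunrise equation, and an arrival
# date extracted from the resulting track. A twilight simulator (the inverse
# model) supports closed-loop testing.

DEG <- pi / 180

#' Solar declination and equation of time
#'
#' Low-precision Fourier approximations (Spencer 1971): declination accurate
#' to well under 0.5 degrees and equation of time to under 1 minute, which is
#' ample for threshold geolocation.
#'
#' @param day_of_year ordinal day in `[1, 366]`.
#' @return A list with `declination_deg` and `eot_minutes` (apparent solar
#'   time minus mean solar time).
#' @export
solar_geometry <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop_bad_arg("day_of_year must lie in [1, 366]")
  }
  g <- 2 * pi * (day_of_year - 1) / 365
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) / DEG
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                   - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  list(declination_deg = decl, eot_minutes = eot)
}

# Day length (hours) at latitude phi (deg) for declination decl (deg) and sun
# elevation threshold a0 (deg). NA where the sun never crosses the threshold.
day_length_hours <- function(phi, decl, a0) {
  x <- (sin(a0 * DEG) - sin(phi * DEG) * sin(decl * DEG)) /
    (cos(phi * DEG) * cos(decl * DEG))
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & abs(x) <= 1
  out[ok] <- 2 * acos(x[ok]) / DEG / 15
  out
}

#' Estimate one daily position from a twilight pair
#'
#' Longitude comes from the twilight midpoint: solar noon at longitude
#' \eqn{\lambda} occurs at `12 - eot/60 - lambda/15` UTC, so
#' `lambda = 15 * (12 - eot/60 - midpoint)`. Latitude is solved from day
#' length through the sunrise equation at the configured sun-elevation
#' threshold (default -6 degrees, civil twilight). The day is flagged
#' `equinox_unreliable` when the latitude solution's sensitivity
#' `|dphi/d(day length)|` exceeds 35 degrees/hour: ordinary days sit at
#' 3-27 degrees/hour across the breeding range while the weeks around an
#' equinox explode past 40, so the bound isolates the genuine degeneracy.
#'
#' @param rise_utc,set_utc sunrise and sunset times, fractional hours UTC;
#'   `set_utc` may exceed 24 when sunset follows UTC midnight.
#' @param day_of_year ordinal day.
#' @param sun_elevation_threshold degrees; default -6 (civil twilight).
#' @return A list with `latitude`, `longitude`, `quality` (one of `"ok"`,
#'   `"equinox_unreliable"`), or an error for polar day/night (day length
#'   outside the solvable range at every latitude).
#' @export
estimate_daily_position <- function(rise_utc, set_utc, day_of_year,
                                    sun_elevation_threshold = -6) {
  if (!is.finite(rise_utc) || !is.finite(set_utc) || rise_utc >= set_utc) {
    stop_bad_arg("need finite twilight times with rise < set")
  }
  sg <- solar_geometry(day_of_year)
  midpoint <- (rise_utc + set_utc) / 2
  lon <- 15 * (12 - sg$eot_minutes / 60 - midpoint)
  lon <- ((lon + 180) %% 360) - 180
  if (lon == -180) lon <- 180

  target <- set_utc - rise_utc
  grid <- seq(-89.5, 89.5, by = 0.25)
  dl <- day_length_hours(grid, sg$declination_deg, sun_elevation_threshold)
  f <- dl - target
  ok <- which(!is.na(f))
  if (!length(ok)) {
    stop_bad_arg("polar conditions: no latitude yields a twilight crossing")
  }
  br <- NULL
  for (i in seq_along(ok)[-1]) {
    a <- ok[i - 1L]; b <- ok[i]
    if (b - a == 1L && !is.na(f[a]) && !is.na(f[b]) && f[a] * f[b] <= 0) {
      br <- c(grid[a], grid[b]); break
    }
  }
  if (is.null(br)) {
    stop_bad_arg("polar day/night: observed day length (", round(target, 2),
                 " h) has no latitude solution on this date")
  }
  phi <- stats::uniroot(function(x) {
    day_length_hours(x, sg$declination_deg, sun_elevation_threshold) - target
  }, lower = br[1], upper = br[2], tol = 1e-8)$root

  # sensitivity of latitude to day length, deg per hour
  h <- 0.25
  dl2 <- day_length_hours(c(phi - h, phi + h), sg$declination_deg,
                          sun_elevation_threshold)
  slope <- (dl2[2] - dl2[1]) / (2 * h)  # hours per degree
  sens <- if (is.na(slope) || abs(slope) < 1e-12) Inf else abs(1 / slope)
  quality <- if (sens > 35) "equinox_unreliable" else "ok"
  list(latitude = phi, longitude = lon, quality = quality)
}

#' Estimate a daily position track from a twilight series
#'
#' Applies [estimate_daily_position()] per day; days whose twilight pair has
#' no latitude solution (or missing times) are flagged rather than dropped.
#'
#' @param twilights data.frame with columns `day_of_year`, `rise_utc`,
#'   `set_utc` (and optionally `sample_id`).
#' @param sun_elevation_threshold degrees, default -6.
#' @return A data.frame (`position_track`): day_of_year, latitude, longitude,
#'   quality in `{ok, equinox_unreliable, missing}`.
#' @export
estimate_track <- function(twilights, sun_elevation_threshold = -6) {
  n <- nrow(twilights)
  out <- data.frame(day_of_year = twilights$day_of_year,
                    latitude = NA_real_, longitude = NA_real_,
                    quality = "missing", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- twilights$rise_utc[i]; s <- twilights$set_utc[i]
    if (is.na(r) || is.na(s)) next
    est <- tryCatch(
      estimate_daily_position(r, s, twilights$day_of_year[i],
                              sun_elevation_threshold),
      error = function(e) NULL)
    if (is.null(est)) next
    out$latitude[i] <- est$latitude
    out$longitude[i] <- est$longitude
    out$quality[i] <- est$quality
  }
  out
}

#' Colony-site arrival criterion
#'
#' @param latitude,longitude colony coordinates, degrees.
#' @param radius_km detection radius around the colony (> 0).
#' @param persistence_days number of consecutive good days within the radius
#'   required to call arrival (>= 1).
#' @return A list of class `colony_site`.
#' @export
colony_site <- function(latitude, longitude, radius_km = 200,
                        persistence_days = 3L) {
  stopifnot(radius_km > 0, persistence_days >= 1)
  structure(list(latitude = latitude, longitude = longitude,
                 radius_km = radius_km,
                 persistence_days = as.integer(persistence_days)),
            class = "colony_site")
}

#' Derive the spring arrival date from a position track
#'
#' Arrival is the first ordinal date from which the great-circle distance to
#' the colony stays within `radius_km` for `persistence_days` consecutive
#' calendar days, all with `ok` quality. Returns `NA` (with attribute
#' `found = FALSE`) when no date qualifies -- never a sentinel number.
#'
#' @param track a position track from [estimate_track()].
#' @param site a [colony_site()].
#' @return Integer ordinal date, or `NA_integer_` if no qualifying date.
#' @export
derive_arrival_date <- function(track, site) {
  stopifnot(inherits(site, "colony_site"))
  d_km <- geosphere::distHaversine(
    cbind(track$longitude, track$latitude),
    c(site$longitude, site$latitude)) / 1000
  good <- track$quality == "ok" & !is.na(d_km) & d_km <= site$radius_km
  k <- site$persistence_days
  n <- nrow(track)
  days <- track$day_of_year
  for (i in seq_len(n)) {
    if (!good[i]) next
    j <- i + k - 1L
    if (j > n) break
    run <- i:j
    if (all(good[run]) && all(diff(days[run]) == 1)) {
      return(structure(as.integer(days[i]), found = TRUE))
    }
  }
  structure(NA_integer_, found = FALSE)
}

#' Simulate twilight times for a known track (inverse model)
#'
#' Inverts the sunrise equation at each position/date to get sunrise and
#' sunset UTC, then adds independent Gaussian noise. Days under polar
#' conditions (no threshold crossing) get `NA` times and `polar = TRUE`.
#'
#' @param track data.frame with `day_of_year`, `latitude`, `longitude`.
#' @param noise_sd_minutes twilight timing noise, minutes.
#' @param seed RNG seed.
#' @param sun_elevation_threshold degrees, default -6.
#' @return A data.frame: day_of_year, rise_utc, set_utc, polar.
#' @export
simulate_twilights <- function(track, noise_sd_minutes = 0, seed = 1L,
                               sun_elevation_threshold = -6) {
  with_seed(seed, {
    n <- nrow(track)
    sg <- solar_geometry(track$day_of_year)
    dl <- day_length_hours(track$latitude, sg$declination_deg,
                           sun_elevation_threshold)
    noon <- 12 - sg$eot_minutes / 60 - track$longitude / 15
    rise <- noon - dl / 2
    set <- noon + dl / 2
    if (noise_sd_minutes > 0) {
      rise <- rise + stats::rnorm(n, 0, noise_sd_minutes / 60)
      set <- set + stats::rnorm(n, 0, noise_sd_minutes / 60)
    }
    data.frame(day_of_year = track$day_of_year, rise_utc = rise,
               set_utc = set, polar = is.na(dl))
  })
}

#' Read a twilight CSV
#'
#' Expects columns `sample_id`, `date` (ISO date or ordinal day), `rise_utc`,
#' `set_utc`.
#'
#' @param path CSV path.
#' @return data.frame with `sample_id`, `day_of_year`, `rise_utc`, `set_utc`.
#' @export
read_twilights <- function(path) {
  tw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "date", "rise_utc", "set_utc")
  if (!all(need %in% names(tw))) {
    stop_bad_arg("twilight CSV needs columns: ", paste(need, collapse = ", "))
  }
  doy <- suppressWarnings(as.integer(tw$date))
  if (anyNA(doy)) doy <- as.POSIXlt(as.Date(tw$date))$yday + 1L
  data.frame(sample_id = tw$sample_id, day_of_year = doy,
             rise_utc = tw$rise_utc, set_utc = tw$set_utc,
             stringsAsFactors = FALSE)
}
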