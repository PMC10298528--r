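#' Solar model constants
#'
#' Constants used by the sunshine-fraction to solar-radiation model: the solar
#' constant, the world-average clear-sky clearness index, the two empirical
#' coefficients of the sunshine--clearness relationship, and the representative
#' day-of-year for each month (Klein's set) used to form annual means from
#' monthly values.
#'
#' @param Gsc Solar constant in W/m^2. Default 1361.
#' @param K_clear Clear-sky clearness index. Default 0.7191.
#' @param beta,gamma Empirical coefficients of the sunshine--clearness
#'   relationship. Defaults 0.1930 and 0.7283.
#' @param representative_days Integer vector of 12 day-of-year values, one per
#'   month, at which the daily extraterrestrial radiation is taken as the
#'   monthly average.
#' @param clearness_form Either `"multiplicative"` (default),
#'   \eqn{\bar K = \bar K_{clear} (\beta + (1-\beta) S^\gamma)}, or
#'   `"exponent"`, \eqn{\bar K = \bar K_{clear}^{\,\beta + (1-\beta) S^\gamma}}.
#'   Both coincide at S = 1.
#'
#' @return A list of class `solar_constants`.
#' @export
#' @examples
#' solar_constants()
solar_constants <- function(Gsc = 1361,
                            K_clear = 0.7191,
                            beta = 0.1930,
                            gamma = 0.7283,
                            representative_days = c(17L, 47L, 75L, 105L, 135L,
                                                    162L, 198L, 228L, 258L,
                                                    288L, 318L, 344L),
                            clearness_form = c("multiplicative", "exponent")) {
  clearness_form <- match.arg(clearness_form)
  stopifnot(Gsc > 0, K_clear > 0, K_clear < 1, beta > 0, beta < 1, gamma > 0,
            length(representative_days) == 12L,
            all(representative_days >= 1), all(representative_days <= 365))
  structure(list(Gsc = Gsc, K_clear = K_clear, beta = beta, gamma = gamma,
                 representative_days = as.integer(representative_days),
                 clearness_form = clearness_form),
            class = "solar_constants")
}

#' Solar declination
#'
#' Declination of the sun for a day of the year,
#' \eqn{\Delta = 23.45 (\pi/180) \sin(2\pi (284+n)/365)}.
#'
#' @param n Day of year, 1--365 (vectorised).
#' @return Declination in radians.
#' @export
declination <- function(n) {
  if (any(n < 1 | n > 365)) {
    stop("day of year `n` must be in [1, 365]", call. = FALSE)
  }
  23.45 * (pi / 180) * sin(2 * pi * (284 + n) / 365)
}

#' Sunset hour angle
#'
#' \eqn{\omega_s = \arccos(-\tan\Phi \tan\Delta)}, with the argument clamped to
#' \eqn{[-1, 1]} so polar day maps to \eqn{\pi} and polar night to 0.
#'
#' @param phi Latitude in radians, `abs(phi) < pi/2`.
#' @param delta Declination in radians.
#' @return Sunset hour angle in radians, in \eqn{[0, \pi]}.
#' @export
sunset_hour_angle <- function(phi, delta) {
  if (any(abs(phi) >= pi / 2)) {
    stop("latitude must satisfy |phi| < pi/2 radians", call. = FALSE)
  }
  arg <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  acos(arg)
}

#' Daily extraterrestrial solar radiation
#'
#' Daily total extraterrestrial radiation on a horizontal surface,
#' \deqn{H_o = \frac{86400\, G_{sc}}{\pi} \left(1 + 0.033 \cos\frac{2\pi n}{365}\right)
#'       (\cos\Phi \cos\Delta \sin\omega_s + \omega_s \sin\Phi \sin\Delta),}
#' reported in MJ/m^2/day.
#'
#' @param phi Latitude in radians.
#' @param n Day of year.
#' @param consts A [solar_constants()] list.
#' @return Daily extraterrestrial radiation, MJ/m^2/day (never negative).
#' @export
extraterrestrial_daily <- function(phi, n, consts = solar_constants()) {
  delta <- declination(n)
  ws <- sunset_hour_angle(phi, delta)
  bracket <- cos(phi) * cos(delta) * sin(ws) + ws * sin(phi) * sin(delta)
  joules <- 86400 * consts$Gsc / pi * (1 + 0.033 * cos(2 * pi * n / 365)) * bracket
  pmax(0, joules / 1e6)
}

#' Annual mean extraterrestrial radiation
#'
#' Mean over the 12 monthly representative days of [extraterrestrial_daily()].
#'
#' @inheritParams extraterrestrial_daily
#' @return Annual mean extraterrestrial radiation, MJ/m^2/day.
#' @export
annual_mean_ho <- function(phi, consts = solar_constants()) {
  vapply(phi, function(p) {
    mean(extraterrestrial_daily(p, consts$representative_days, consts))
  }, numeric(1))
}

#' Annual clearness index from sunshine fraction
#'
#' Relates the annual sunshine fraction S (fraction of maximum possible bright
#' sunshine, in `[0, 1]`) to the annual clearness index. The default
#' multiplicative form is
#' \eqn{\bar K = \bar K_{clear} (\beta + (1-\beta) S^\gamma)}; at S = 1 it
#' returns the clear-sky value itself.
#'
#' @param S Sunshine fraction in `[0, 1]` (vectorised).
#' @param consts A [solar_constants()] list.
#' @return Clearness index \eqn{\bar K}.
#' @export
#' @examples
#' clearness_index(1)      # clear-sky value 0.7191
#' clearness_index(0.5)
clearness_index <- function(S, consts = solar_constants()) {
  if (any(S < 0 | S > 1)) {
    stop("sunshine fraction `S` must be in [0, 1]", call. = FALSE)
  }
  inner <- consts$beta + (1 - consts$beta) * S^consts$gamma
  switch(consts$clearness_form,
         multiplicative = consts$K_clear * inner,
         exponent = consts$K_clear^inner)
}

#' Annual average daily solar radiation for sampling sites
#'
#' Computes, for each site, the annual mean extraterrestrial radiation
#' \eqn{\bar H_o} from latitude, the clearness index \eqn{\bar K} from the
#' annual sunshine fraction, and the surface radiation
#' \eqn{\bar H = \bar K \times \bar H_o}.
#'
#' @param sites Data frame with columns `site`, `latitude` (degrees, north
#'   positive) and `sun` (annual sunshine fraction in `[0, 1]`).
#' @param consts A [solar_constants()] list.
#' @return A tibble: the input columns plus `Ho`, `K` and `H`
#'   (MJ/m^2/day for `Ho` and `H`).
#' @export
estimate_solar <- function(sites, consts = solar_constants()) {
  stopifnot(is.data.frame(sites),
            all(c("site", "latitude", "sun") %in% names(sites)))
  if (any(abs(sites$latitude) > 90)) {
    stop("latitudes must be within [-90, 90] degrees", call. = FALSE)
  }
  out <- tibble::as_tibble(sites)
  out$Ho <- annual_mean_ho(out$latitude * pi / 180, consts)
  out$K <- clearness_index(out$sun, consts)
  out$H <- out$K * out$Ho
  class(out) <- c("cnvclim_solar", class(out))
  out
}

#' Annual radiation for a single latitude/sunshine pair
#'
#' Convenience scalar form of [estimate_solar()].
#'
#' @param latitude Latitude in degrees.
#' @param S Annual sunshine fraction.
#' @param consts A [solar_constants()] list.
#' @return Annual average daily solar radiation, MJ/m^2/day.
#' @export
annual_radiation <- function(latitude, S, consts = solar_constants()) {
  clearness_index(S, consts) * annual_mean_ho(latitude * pi / 180, consts)
}
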