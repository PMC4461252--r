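#' Chick-rearing window for a model year
#'
#' The model year runs from the start of the breeding season, 1 October, to
#' 30 September of the following calendar year; year `y` denotes the season
#' starting 1 October of calendar year `y`. Environmental covariates are
#' aggregated over the chick-rearing window, by default the four months
#' 1 February to 31 May of calendar year `y + 1`.
#'
#' @param year Model year(s).
#' @param start_month,start_day,end_month,end_day Window bounds within the
#'   calendar year following the season start (defaults Feb 1 to May 31).
#' @return A tibble with `year`, `season_start`, `window_start`, `window_end`.
#' @export
season_window <- function(year, start_month = 2, start_day = 1,
                          end_month = 5, end_day = 31) {
  stopifnot(end_month >= start_month)
  tibble(
    year = year,
    season_start = as.Date(sprintf("%d-10-01", year)),
    window_start = as.Date(sprintf("%d-%02d-%02d", year + 1, start_month, start_day)),
    window_end = as.Date(sprintf("%d-%02d-%02d", year + 1, end_month, end_day))
  )
}

window_dates <- function(year, ...) {
  w <- season_window(year, ...)
  seq(w$window_start, w$window_end, by = "day")
}

#' Total chick-window rainfall for model years
#'
#' Sums daily rainfall over the chick-rearing window. Days with no reading
#' are allocated the average rainfall for that day of the year computed over
#' the whole available series.
#'
#' @param weather Daily weather tibble with columns `date` (Date) and
#'   `rain_mm`.
#' @param years Model year(s).
#' @param ... Passed to [season_window()].
#' @return Numeric vector of window rainfall totals (mm), one per year.
#' @export
rainfall_total <- function(weather, years, ...) {
  stopifnot(all(c("date", "rain_mm") %in% names(weather)))
  date <- as.Date(weather$date)
  ok <- !is.na(weather$rain_mm)
  # day-of-year climatology (keyed by month-day, robust to leap years) over
  # the whole dataset, used to impute gaps
  doy <- format(date, "%m-%d")
  doy_mean <- tapply(weather$rain_mm[ok], doy[ok], mean)
  grand_mean <- mean(weather$rain_mm[ok])
  vapply(years, function(y) {
    dd <- window_dates(y, ...)
    vals <- weather$rain_mm[match(as.integer(dd), as.integer(date))]
    miss <- is.na(vals)
    if (any(miss)) {
      imp <- doy_mean[format(dd[miss], "%m-%d")]
      imp[is.na(imp)] <- grand_mean
      vals[miss] <- imp
    }
    sum(vals)
  }, numeric(1))
}

#' Count of hot chick-rearing days for model years
#'
#' Number of days in the chick-rearing window whose maximum temperature
#' strictly exceeds the threshold (default 23 degrees C). Days with no
#' temperature reading do not count.
#'
#' @param weather Daily weather tibble with columns `date` and `tmax_c`.
#' @param years Model year(s).
#' @param threshold Temperature threshold in degrees C.
#' @param ... Passed to [season_window()].
#' @return Integer vector of exceedance-day counts, one per year.
#' @export
threshold_days <- function(weather, years, threshold = 23, ...) {
  stopifnot(all(c("date", "tmax_c") %in% names(weather)))
  date_i <- as.integer(as.Date(weather$date))
  vapply(years, function(y) {
    vals <- weather$tmax_c[match(as.integer(window_dates(y, ...)), date_i)]
    sum(vals > threshold, na.rm = TRUE)
  }, integer(1))
}

#' Standardize an annual covariate series
#'
#' Centres and scales a raw annual series by its mean and sample (n - 1)
#' standard deviation over a reference period, so the standardized values
#' have mean 0 and sd 1 over that period. Future scenario series should be
#' standardized with the historical centre/scale via `center`/`scale`.
#'
#' @param series Tibble with columns `year` and `value` (or `raw`).
#' @param name Covariate name to record.
#' @param ref_years Years defining the reference period (default: all).
#' @param center,scale Optional externally supplied centre and scale
#'   (e.g. from the historical series) overriding the reference period.
#' @return Tibble `name`, `year`, `raw`, `standardized`, with attributes
#'   `center` and `scale`.
#' @export
standardize_covariate <- function(series, name = "covariate", ref_years = NULL,
                                  center = NULL, scale = NULL) {
  if ("raw" %in% names(series) && !"value" %in% names(series)) {
    series$value <- series$raw
  }
  stopifnot(all(c("year", "value") %in% names(series)))
  if (is.null(center) || is.null(scale)) {
    ref <- if (is.null(ref_years)) series$value else series$value[series$year %in% ref_years]
    ref <- ref[!is.na(ref)]
    center <- mean(ref)
    scale <- sd(ref)
    if (!is.finite(scale) || scale <= 0) {
      abort("covariate series has zero variance over the reference period")
    }
  }
  out <- tibble(
    name = name, year = series$year, raw = series$value,
    standardized = (series$value - center) / scale
  )
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Environmental effect on chick mortality
#'
#' Bundles the per-covariate slopes theta and the fixed power b of the
#' exponential chick-mortality response f(x) = exp(theta * sgn(x) |x|^b).
#' The sign-preserving power keeps f monotone in x for every b (including
#' b = 0.5 and b = 2) and continuous at x = 0, where f(0) = 1.
#'
#' @param theta Named numeric vector of slopes; names are covariate names
#'   (subset of those present in the covariate table). An empty vector gives
#'   the covariate-free model (modifier identically 1).
#' @param b Power, one of 0.5, 1, 2 (fixed, not estimated).
#' @return An object of class `env_effect`.
#' @export
env_effect <- function(theta = c(rainfall = 0, threshold_days = 0, ssha = 0),
                       b = 1) {
  stopifnot(b %in% c(0.5, 1, 2))
  if (length(theta) > 0 && is.null(names(theta))) {
    abort("theta must be a named vector")
  }
  structure(list(theta = theta, b = b), class = "env_effect")
}

#' Combined environmental multiplier on chick mortality
#'
#' Evaluates the product over included covariates of
#' f(x_i) = exp(theta_i * sgn(x_i) |x_i|^b) at standardized covariate values
#' x. With all x = 0 (covariates at their historical means) or all theta = 0
#' the multiplier is exactly 1.
#'
#' @param effect An [env_effect()].
#' @param x Named numeric vector of standardized covariate values; must
#'   contain every name in `effect$theta`.
#' @return Positive scalar multiplier.
#' @export
env_multiplier <- function(effect, x) {
  th <- effect$theta
  if (length(th) == 0) return(1)
  if (!all(names(th) %in% names(x))) {
    abort("x is missing values for some covariates in the effect")
  }
  xv <- x[names(th)]
  exp(sum(th * sign(xv) * abs(xv)^effect$b))
}

#' Bias-correct modelled chick-window rainfall totals
#'
#' Climate-model rainfall over the chick-rearing window runs wet relative to
#' station observations over the overlap period; modelled totals are shifted
#' down by a fixed offset (default 61.5 mm) and floored at zero.
#'
#' @param x Modelled rainfall totals (mm).
#' @param offset Downward adjustment in mm.
#' @return Corrected totals, non-negative.
#' @export
bias_correct_rainfall <- function(x, offset = 61.5) {
  pmax(x - offset, 0)
}

#' Calibrate modelled daily average temperature to observed daily maxima
#'
#' Climate models supply daily average temperature; the population model
#' needs daily maxima. Percentiles 5, 6, ..., 95 of both series are computed
#' over the overlap period and observed-maximum percentiles are regressed
#' (OLS) on modelled-average percentiles; the fitted affine map is then
#' applied to every modelled value. Exact whenever the two series differ by
#' an affine transform.
#'
#' @param model_avg Tibble with `date` and `tavg_c` (modelled daily average).
#' @param observed_max Tibble with `date` and `tmax_c` (observed daily max).
#' @param overlap Optional vector of dates defining the overlap period;
#'   default is the intersection of the two series' dates.
#' @param probs Percentile probabilities (default 5:95 / 100, 91 points).
#' @return Tibble `date`, `tmax_c` (calibrated maxima for the whole modelled
#'   series), with attribute `calibration` = c(intercept, slope).
#' @export
avg_to_max_temperature <- function(model_avg, observed_max, overlap = NULL,
                                   probs = (5:95) / 100) {
  md <- as.Date(model_avg$date)
  od <- as.Date(observed_max$date)
  if (is.null(overlap)) overlap <- as.Date(intersect(md, od), origin = "1970-01-01")
  if (length(overlap) < 365) {
    abort("overlap period between modelled and observed series is shorter than one year")
  }
  qm <- quantile(model_avg$tavg_c[md %in% overlap], probs, na.rm = TRUE, names = FALSE)
  qo <- quantile(observed_max$tmax_c[od %in% overlap], probs, na.rm = TRUE, names = FALSE)
  fit <- lm(qo ~ qm)
  co <- coef(fit)
  out <- tibble(date = md, tmax_c = co[[1]] + co[[2]] * model_avg$tavg_c)
  attr(out, "calibration") <- c(intercept = co[[1]], slope = co[[2]])
  out
}

#' Assemble a future covariate scenario
#'
#' Builds a year-indexed future series of the three covariates (chick-window
#' rainfall total, hot-day count, SSHA). The climate-neutral source draws
#' rainfall and threshold days i.i.d. normal with the historical mean and
#' variance (rainfall floored at 0; threshold days rounded to the nearest
#' non-negative integer). A climate-model source passes through supplied
#' rainfall/threshold-day series (already bias-corrected / calibrated).
#' SSHA: by default the historic mean every year; with `ssha_multiplier` m
#' the anomaly is scaled to (1 + m) times the historic mean, i.e. pushed
#' toward stronger upwelling when the historic mean anomaly is negative.
#'
#' @param historical Tibble of historical raw covariates with columns
#'   `year`, `rainfall`, `threshold_days`, `ssha`.
#' @param years Future model years.
#' @param source `"climate_neutral"` or `"climate_model"`.
#' @param model_series For `source = "climate_model"`: tibble with `year`,
#'   `rainfall`, `threshold_days` covering `years`.
#' @param ssha_multiplier Optional m >= 0; future SSHA = (1 + m) x historic
#'   mean anomaly.
#' @param seed Optional integer seed for the climate-neutral draws.
#' @return Tibble `year`, `rainfall`, `threshold_days`, `ssha` with
#'   attribute `source`.
#' @export
build_scenario <- function(historical, years, source = c("climate_neutral", "climate_model"),
                           model_series = NULL, ssha_multiplier = NULL, seed = NULL) {
  source <- match.arg(source)
  stopifnot(all(c("year", "rainfall", "threshold_days", "ssha") %in% names(historical)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(years)
  hm <- function(v) mean(v, na.rm = TRUE)
  hs <- function(v) sd(v, na.rm = TRUE)
  if (source == "climate_neutral") {
    rain <- pmax(rnorm(n, hm(historical$rainfall), hs(historical$rainfall)), 0)
    hot <- pmax(round(rnorm(n, hm(historical$threshold_days), hs(historical$threshold_days))), 0)
  } else {
    if (is.null(model_series)) abort("model_series required for climate_model source")
    ms <- model_series[match(years, model_series$year), ]
    if (anyNA(ms$year)) abort("model_series does not cover the requested years")
    rain <- ms$rainfall
    hot <- ms$threshold_days
  }
  ssha_mean <- hm(historical$ssha)
  ssha <- rep(if (is.null(ssha_multiplier)) ssha_mean else (1 + ssha_multiplier) * ssha_mean, n)
  out <- tibble(year = years, rainfall = rain, threshold_days = hot, ssha = ssha)
  attr(out, "source") <- source
  out
}

#' Build the standardized covariate table from raw weather and SSHA series
#'
#' Aggregates daily weather into the three annual covariates over the
#' chick-rearing window and standardizes each by its mean and sample sd over
#' the reference years (default: the years requested). Use
#' `centers`/`scales` to standardize a future scenario on the historical
#' scale.
#'
#' @param weather Daily weather tibble (`date`, `rain_mm`, `tmax_c`), or
#'   `NULL` if `raw` is supplied.
#' @param ssha Annual SSHA tibble (`year`, `ssha_m`), or `NULL` if `raw` is
#'   supplied.
#' @param years Model years to cover.
#' @param raw Optional pre-aggregated raw tibble (`year`, `rainfall`,
#'   `threshold_days`, `ssha`), e.g. from [build_scenario()]; bypasses
#'   aggregation.
#' @param ref_years Reference period for standardization.
#' @param centers,scales Optional named vectors (names `rainfall`,
#'   `threshold_days`, `ssha`) overriding the reference-period statistics.
#' @param ... Window options passed to [season_window()].
#' @return Tibble `year`, `rainfall`, `threshold_days`, `ssha` (raw) and
#'   `x_rainfall`, `x_threshold_days`, `x_ssha` (standardized), with
#'   attributes `centers` and `scales`.
#' @export
build_covariates <- function(weather = NULL, ssha = NULL, years = NULL, raw = NULL,
                             ref_years = NULL, centers = NULL, scales = NULL, ...) {
  if (is.null(raw)) {
    stopifnot(!is.null(weather), !is.null(ssha), !is.null(years))
    raw <- tibble(
      year = years,
      rainfall = rainfall_total(weather, years, ...),
      threshold_days = as.numeric(threshold_days(weather, years, ...)),
      ssha = ssha$ssha_m[match(years, ssha$year)]
    )
  }
  nm <- c("rainfall", "threshold_days", "ssha")
  ctr <- numeric(0); scl <- numeric(0)
  out <- raw[, c("year", nm)]
  for (v in nm) {
    std <- standardize_covariate(
      tibble(year = raw$year, value = raw[[v]]), name = v, ref_years = ref_years,
      center = if (is.null(centers)) NULL else centers[[v]],
      scale = if (is.null(scales)) NULL else scales[[v]]
    )
    out[[paste0("x_", v)]] <- std$standardized
    ctr[v] <- attr(std, "center")
    scl[v] <- attr(std, "scale")
  }
  attr(out, "centers") <- ctr
  attr(out, "scales") <- scl
  out
}
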