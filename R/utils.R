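# internal helpers shared across modules

# stop with a classed condition so tests can match on class
stop_sharknet <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "sharknet_error"), ...)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_sharknet(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "sharknet_schema_error"
    )
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop_sharknet(
      sprintf("configuration field '%s' must be a single number in [%s, %s]",
              name, format(lower), format(upper)),
      class = "sharknet_config_error"
    )
  }
  invisible(x)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

# calendar date of an instant in a reporting timezone (default UTC)
detection_date <- function(timestamp, tz = "UTC") {
  as.Date(format(timestamp, tz = tz, format = "%Y-%m-%d"))
}

# great-circle distance in km (haversine); small helper, station scale only
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

habitat_classes <- function() c("coral reef", "deep wall", "sand", "seagrass")
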