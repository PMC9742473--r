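# Preprocessing: reference-join merge, two imputation rules, quarterly
# weather features, per-county yield trend.

meta_cols <- c("geoid", "year", "state", "crd", "cropland_ratio", "yield",
               "shock_flag")

#' Classify every column of a feature panel by source
#'
#' The manifest drives the expert filter: weekly weather and planting
#' columns carry their week-of-year; quarterly, auxiliary, soil, crop-model
#' and trend columns carry `week = NA`.
#'
#' @param panel a merged feature panel (or any table using the package's
#'   column naming).
#' @return data.table with `column`, `source`, `week`.
#' @export
column_manifest <- function(panel) {
  cols <- names(panel)
  src <- character(length(cols)); wk <- rep(NA_integer_, length(cols))
  for (i in seq_along(cols)) {
    cl <- cols[i]
    if (cl %in% meta_cols) {
      src[i] <- if (cl == "yield") "target" else "key"
    } else if (grepl("^wx_[a-z]+_wk\\d{2}$", cl)) {
      src[i] <- "weather"; wk[i] <- as.integer(sub(".*_wk", "", cl))
    } else if (grepl("^aux_", cl)) {
      src[i] <- "weather_aux"
    } else if (grepl("^wxq_", cl)) {
      src[i] <- "quarterly"
    } else if (grepl("^soil_", cl)) {
      src[i] <- "soil"
    } else if (grepl("^plant_wk\\d{2}$", cl)) {
      src[i] <- "planting"; wk[i] <- as.integer(sub("^plant_wk", "", cl))
    } else if (cl %in% apsim_cols()) {
      src[i] <- "apsim"
    } else if (cl == "yield_trend") {
      src[i] <- "trend"
    } else {
      src[i] <- "other"
    }
  }
  data.table::data.table(column = cols, source = src, week = wk)
}

#' Write the column manifest as JSON
#' @param manifest from [column_manifest()].
#' @param path output file.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", na = "null")
  invisible(path)
}

check_unique_key <- function(x, key, what) {
  if (anyDuplicated(x, by = key))
    stop_config("integrity error: duplicate ", paste(key, collapse = "/"),
                " in ", what)
}

#' Merge the five sources onto the yield reference
#'
#' Left-joins everything onto the yield table: weather and crop-model
#' outputs on (geoid, year), soil on geoid (replicated across years),
#' planting on (state, year) broadcast to counties through the geography.
#' Every yield row is preserved; county-years absent from the yield
#' reference are dropped.
#'
#' @param yields,weather,soil,planting,apsim,geography the six tables.
#' @return a feature panel keyed by (geoid, year).
#' @export
merge_sources <- function(yields, weather, soil, planting, apsim, geography) {
  if (nrow(yields) == 0) stop_config("yield reference is empty")
  yields <- data.table::as.data.table(yields)
  check_unique_key(yields, c("geoid", "year"), "yields")
  check_unique_key(weather, c("geoid", "year"), "weather")
  check_unique_key(soil, "geoid", "soil")
  check_unique_key(planting, c("state", "year"), "planting")
  check_unique_key(apsim, c("geoid", "year"), "apsim")
  if (!all(yields$geoid %in% geography$geoid))
    stop_config("join error: county with no state mapping in geography")

  panel <- merge(yields, geography, by = "geoid", all.x = TRUE, sort = FALSE)
  panel <- merge(panel, weather, by = c("geoid", "year"), all.x = TRUE,
                 sort = FALSE)
  panel <- merge(panel, soil, by = "geoid", all.x = TRUE, sort = FALSE)
  panel <- merge(panel, planting, by = c("state", "year"), all.x = TRUE,
                 sort = FALSE)
  panel <- merge(panel, apsim, by = c("geoid", "year"), all.x = TRUE,
                 sort = FALSE)
  stopifnot(nrow(panel) == nrow(yields))
  data.table::setcolorder(panel, intersect(meta_cols, names(panel)))
  data.table::setkey(panel, geoid, year)
  panel[]
}

#' Impute missing planting and crop-model values
#'
#' Planting-progress gaps are filled with the mean of that state's observed
#' values for the same week across years. Crop-model gaps are filled with
#' the county-level median of the variable (median is robust to outliers);
#' counties with no observed value fall back to the state median, then the
#' global median. Idempotent, and the identity on complete panels.
#'
#' @param panel a merged feature panel.
#' @return the panel with no missing planting / crop-model values; the
#'   number of filled cells is recorded in `attr(, "imputed_cells")`.
#' @export
impute_missing <- function(panel) {
  panel <- data.table::copy(panel)
  filled <- 0L
  pl <- intersect(planting_cols(), names(panel))
  for (cl in pl) {
    if (!anyNA(panel[[cl]])) next
    filled <- filled + sum(is.na(panel[[cl]]))
    panel[, (cl) := {
      x <- get(cl)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    }, by = state]
    if (anyNA(panel[[cl]]))  # state fully unobserved: global mean
      panel[is.na(get(cl)), (cl) := mean(panel[[cl]], na.rm = TRUE)]
  }
  ap <- intersect(apsim_cols(), names(panel))
  for (cl in ap) {
    if (!anyNA(panel[[cl]])) next
    filled <- filled + sum(is.na(panel[[cl]]))
    panel[, (cl) := {
      x <- get(cl)
      x[is.na(x)] <- median(x, na.rm = TRUE)
      x
    }, by = geoid]
    if (anyNA(panel[[cl]]))
      panel[, (cl) := {
        x <- get(cl)
        x[is.na(x)] <- median(x, na.rm = TRUE)
        x
      }, by = state]
    if (anyNA(panel[[cl]]))
      panel[is.na(get(cl)), (cl) := median(panel[[cl]], na.rm = TRUE)]
  }
  data.table::setattr(panel, "imputed_cells", filled)
  panel[]
}

#' Add the 20 quarterly weather features
#'
#' Quarters are the four 13-week blocks. Precipitation, radiation and
#' growing degree days are summed within a quarter; minimum and maximum
#' temperature are averaged. New columns are `wxq_<var>_q<1..4>`.
#'
#' @param panel a feature panel with the weekly weather columns.
#' @return the panel with 20 additional columns.
#' @export
add_quarterly_features <- function(panel) {
  need <- weekly_weather_cols()
  if (!all(need %in% names(panel)))
    stop_config("schema error: weekly weather columns missing")
  panel <- data.table::copy(panel)
  for (v in wx_vars) {
    agg <- if (v %in% c("prcp", "rad", "gdd")) rowSums else rowMeans
    for (q in 1:4) {
      wks <- ((q - 1) * 13 + 1):(q * 13)
      m <- as.matrix(panel[, sprintf("wx_%s_wk%02d", v, wks), with = FALSE])
      panel[, (sprintf("wxq_%s_q%d", v, q)) := agg(m)]
    }
  }
  panel[]
}

#' Fit the per-county yield trend on training years only
#'
#' Ordinary least squares of yield on calendar year, one fit per county,
#' using only `train_years`; the fitted line extrapolates to any year
#' (including held-out test years), so the trend feature never sees test
#' yields. Counties with fewer than 2 training observations inherit the
#' pooled state-level fit (requires `geography`).
#'
#' @param yields a yield panel (geoid, year, yield).
#' @param train_years integer years to fit on.
#' @param geography optional geography table enabling the state fallback.
#' @return a `yc_trend` data.table: `geoid`, `b0`, `b1`, `n_train`, `source`.
#' @export
compute_trend_feature <- function(yields, train_years, geography = NULL) {
  yields <- data.table::as.data.table(yields)
  tr <- yields[year %in% train_years]
  if (nrow(tr) == 0) stop_config("no training years with yields")

  ols <- function(x, y) {
    if (length(unique(x)) < 2)
      stop_config("singular-fit error: constant year regressor")
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(b0 = mean(y) - b1 * mean(x), b1 = b1)
  }

  counts <- tr[, .(n_train = .N), by = geoid]
  ok <- counts[n_train >= 2, geoid]
  fits <- tr[geoid %in% ok,
             { f <- ols(year, yield)
               .(b0 = f[["b0"]], b1 = f[["b1"]], n_train = .N,
                 source = "county") },
             by = geoid]

  short <- setdiff(unique(yields$geoid), ok)
  if (length(short) > 0) {
    if (is.null(geography))
      stop_config(length(short), " counties have < 2 training years and no ",
                  "geography was supplied for the state fallback")
    g <- data.table::as.data.table(geography)
    trs <- merge(tr, g[, .(geoid, state)], by = "geoid")
    sfit <- trs[, { f <- ols(year, yield)
                    .(b0 = f[["b0"]], b1 = f[["b1"]]) }, by = state]
    fb <- data.table::data.table(geoid = short,
                                 state = g$state[match(short, g$geoid)])
    fb <- merge(fb, sfit, by = "state")[, .(geoid, b0, b1)]
    fb[, `:=`(n_train = 0L, source = "state")]
    message(length(short), " counties fell back to the state-level trend")
    fits <- rbind(fits, fb)
  }
  data.table::setkey(fits, geoid)
  structure(fits[], class = c("yc_trend", class(fits)))
}

#' Evaluate the trend feature for given county-years
#' @param trend a `yc_trend` object.
#' @param geoid,year vectors of equal length.
#' @return numeric `b0 + b1 * year` per element.
#' @export
predict_trend <- function(trend, geoid, year) {
  i <- match(geoid, trend$geoid)
  if (anyNA(i)) stop_config("unknown geoid in trend prediction")
  trend$b0[i] + trend$b1[i] * year
}

#' Attach the `yield_trend` column to a panel
#' @param panel feature panel with `geoid`, `year`.
#' @param trend a `yc_trend` object.
#' @return panel with `yield_trend` added.
#' @export
add_trend_feature <- function(panel, trend) {
  panel <- data.table::copy(panel)
  panel[, yield_trend := predict_trend(trend, geoid, year)]
  panel[]
}

#' Full preprocessing for one train/test configuration
#'
#' Merge, impute, add quarterly features, fit the county trend on training
#' years only and attach `yield_trend` to all rows.
#'
#' @param panels named list of the six tables.
#' @param train_years years the trend may learn from.
#' @return list `panel` (feature panel) and `trend` (`yc_trend`).
#' @export
preprocess_panels <- function(panels, train_years) {
  panel <- merge_sources(panels$yield, panels$weather, panels$soil,
                         panels$planting, panels$apsim, panels$geography)
  panel <- impute_missing(panel)
  panel <- add_quarterly_features(panel)
  trend <- compute_trend_feature(panels$yield, train_years, panels$geography)
  panel <- add_trend_feature(panel, trend)
  list(panel = panel, trend = trend)
}
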