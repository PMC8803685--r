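# Track ingestion, quality filtering and biological annotation.

CLASS_LEVELS <- c("juvenile_female", "adult_female",
                  "juvenile_male", "adult_male")

# Sex-specific maturation sizes for this east-coast population: females
# mature at 326 cm TL, males at 297 cm TL; the threshold itself maps to
# adult.
MATURITY_CM <- c(female = 326, male = 297)

# Latitude of the coast centroid separating the northern (tropical) and
# southern (temperate) marine regions; 24.5 S, signed.
REGION_SPLIT_LAT <- -24.5

#' Classify animals into sex-by-maturity biological classes
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param total_length_cm total length in cm, positive.
#' @return factor with levels `juvenile_female`, `adult_female`,
#'   `juvenile_male`, `adult_male`. An animal exactly at its sex's
#'   maturation length is classed adult.
#' @export
#' @examples
#' classify_class(c("female", "female", "male"), c(330, 325.9, 250))
classify_class <- function(sex, total_length_cm) {
  n <- max(length(sex), length(total_length_cm))
  sex <- rep_len(as.character(sex), n)
  total_length_cm <- rep_len(total_length_cm, n)
  stop_if_not(all(sex %in% c("female", "male")),
              "'sex' must be 'female' or 'male'")
  stop_if_not(all(total_length_cm > 0),
              "'total_length_cm' must be positive")
  adult <- total_length_cm >= MATURITY_CM[sex]
  cls <- ifelse(adult, paste0("adult_", sex), paste0("juvenile_", sex))
  factor(cls, levels = CLASS_LEVELS)
}

#' Assign locations to the North or South marine region
#'
#' The boundary at 24.5 S belongs to the South region: with signed
#' latitudes, North means `lat > -24.5` and South means `lat <= -24.5`.
#'
#' @param lat signed latitude in decimal degrees.
#' @return factor with levels `North`, `South`.
#' @export
assign_region <- function(lat) {
  stop_if_not(all(lat >= -90 & lat <= 90), "invalid latitude")
  factor(ifelse(lat > REGION_SPLIT_LAT, "North", "South"),
         levels = c("North", "South"))
}

#' Reduce raw fixes to one quality-controlled position per day
#'
#' Per animal: fixes are collapsed to a daily representative position
#' (median latitude and median longitude of the day's fixes), then days
#' implying a travel speed above `speed_cap_km_day` from the previously
#' retained day are dropped in a forward scan. This simple QC stands in
#' for tag-specific location processing; any reasonable scheme yields the
#' daily positions that all downstream stages consume.
#'
#' @param raw data frame with columns `animal_id`, `date` (or a POSIXct
#'   `timestamp`), `lat`, `lon`, and optionally `sex`, `tl_cm`, `source`,
#'   `max_depth_m`.
#' @param speed_cap_km_day maximum plausible speed (default 150 km/day).
#' @return data frame with one row per animal per retained day, ordered
#'   by animal and date; zero rows when `raw` is empty.
#' @export
daily_positions <- function(raw, speed_cap_km_day = 150) {
  if (nrow(raw) == 0L) return(raw)
  if (!"date" %in% names(raw)) raw$date <- as.Date(raw$timestamp)
  raw$date <- as.Date(raw$date)
  keep_first <- function(x) x[1]
  per_animal <- function(df) {
    agg <- stats::aggregate(df[, c("lat", "lon")],
                            by = list(date = df$date), FUN = stats::median)
    agg <- agg[order(agg$date), ]
    extra <- setdiff(names(df), c("date", "lat", "lon", "timestamp"))
    for (col in extra) agg[[col]] <- keep_first(df[[col]])
    # forward speed filter against the last retained day
    keep <- logical(nrow(agg)); keep[1] <- TRUE
    last <- 1L
    if (nrow(agg) > 1L) for (i in 2:nrow(agg)) {
      dt <- as.numeric(agg$date[i] - agg$date[last])
      dist_km <- geosphere::distHaversine(
        c(agg$lon[last], agg$lat[last]), c(agg$lon[i], agg$lat[i])) / 1000
      if (dist_km / dt <= speed_cap_km_day) {
        keep[i] <- TRUE; last <- i
      }
    }
    agg[keep, ]
  }
  parts <- lapply(split(raw, raw$animal_id), per_animal)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$animal_id, out$date), ]
}

#' Thin a daily track to locations at least `min_sep_deg` apart
#'
#' Greedy forward scan: a location is retained only if its Euclidean
#' distance in degrees from the last *retained* location is at least
#' `min_sep_deg` (boundary inclusive); the first location is always
#' retained. Used to reduce pseudo-replication and residual spatial
#' autocorrelation before model fitting.
#'
#' @param track daily-resolved track data frame (per animal) with `lat`,
#'   `lon` columns; multiple animals are handled per `animal_id`.
#' @param min_sep_deg separation threshold in degrees (default 0.25).
#' @return the thinned track. Idempotent.
#' @export
spacing_filter <- function(track, min_sep_deg = 0.25) {
  if (nrow(track) == 0L) return(track)
  per_animal <- function(df) {
    keep <- logical(nrow(df)); keep[1] <- TRUE
    last <- 1L
    if (nrow(df) > 1L) for (i in 2:nrow(df)) {
      d <- sqrt((df$lat[i] - df$lat[last])^2 + (df$lon[i] - df$lon[last])^2)
      if (d >= min_sep_deg) {
        keep[i] <- TRUE; last <- i
      }
    }
    df[keep, ]
  }
  if ("animal_id" %in% names(track)) {
    out <- do.call(rbind, lapply(split(track, track$animal_id), per_animal))
    rownames(out) <- NULL
    out[order(out$animal_id, out$date), ]
  } else {
    per_animal(track)
  }
}

#' Annotate a daily track table with class, region and tagging region
#'
#' @param track daily track data frame with `sex`, `tl_cm`, `lat`.
#' @return the track with columns `class`, `region` (per location) and
#'   `tagging_region` (region of each animal's first location) added.
#' @export
annotate_track <- function(track) {
  track$class <- classify_class(track$sex, track$tl_cm)
  track$region <- assign_region(track$lat)
  first <- !duplicated(track$animal_id)
  tag_reg <- stats::setNames(as.character(track$region[first]),
                             track$animal_id[first])
  track$tagging_region <- factor(tag_reg[as.character(track$animal_id)],
                                 levels = c("North", "South"))
  track
}

#' Read / write track tables
#'
#' CSV schema: `animal_id, sex, tl_cm, date, lon, lat, source,
#' max_depth_m` (extra columns pass through).
#'
#' @param path file path.
#' @param track track data frame.
#' @return `read_tracks_csv()` returns the track data frame.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}
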