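# Ingestion, validation, windowing and phase annotation of metabolic-cage
# recordings.

# Channel vocabulary of the metabolic cage export.
.KNOWN_CHANNELS <- c("VO2", "VCO2", "RER", "EE", "XT", "YT", "Z",
                     "DistD", "Speed", "Drink", "Feed", "SumR", "SumL")
# Channels that are instantaneous rates (daily value = arithmetic mean) vs
# cumulative/event channels (daily value = total per 24 h).
.RATE_CHANNELS       <- c("VO2", "VCO2", "RER", "EE", "Speed")
.CUMULATIVE_CHANNELS <- c("XT", "YT", "Z", "DistD", "Drink", "Feed",
                          "SumR", "SumL")
.COUNT_CHANNELS <- c("VO2", "VCO2", "XT", "YT", "Z", "DistD", "Speed",
                     "Drink", "Feed", "SumR", "SumL")

#' Construct a metabolic-cage recording
#'
#' A `cage_recording` holds one animal's time-stamped multi-channel
#' indirect-calorimetry trace plus its metadata. Samples are taken at a
#' uniform step of `interval_min` minutes; sample i covers the half-open
#' interval `[start_time + (i-1)*dt, start_time + i*dt)` and all per-sample
#' properties (light/dark phase in particular) are decided by the interval's
#' start time.
#'
#' @param animal_id single string identifying the animal.
#' @param group group label (e.g. `"Young"`, `"Aged"`, `"Treated"`).
#' @param age_weeks chronological age in weeks (> 0).
#' @param body_weight_g body weight in grams (> 0).
#' @param start_time `POSIXct` timestamp of the first sample.
#' @param interval_min sampling step in minutes (> 0), default 18.
#' @param channels named list of equal-length numeric vectors; recognised
#'   names are `VO2`, `VCO2` (ml/h), `RER`, `EE` (kcal/h), `XT`, `YT`, `Z`
#'   (beam-break counts), `DistD` (cm), `Speed` (cm/s), `Drink` (ml),
#'   `Feed` (g), `SumR`, `SumL` (wheel turns).
#' @param lights_on_hour clock hour at which lights switch on (default 7,
#'   i.e. 07:00).
#' @param photoperiod_h numeric pair (light hours, dark hours), default
#'   `c(12, 12)`.
#' @param extra pass-through data (unknown columns from the source table).
#' @return an object of class `cage_recording`.
#' @export
recording <- function(animal_id, group, age_weeks, body_weight_g,
                      start_time, interval_min = 18, channels,
                      lights_on_hour = 7, photoperiod_h = c(12, 12),
                      extra = list()) {
  rec <- structure(
    list(animal_id = as.character(animal_id),
         group = as.character(group),
         age_weeks = as.numeric(age_weeks),
         body_weight_g = as.numeric(body_weight_g),
         start_time = as.POSIXct(start_time, tz = "UTC"),
         interval_min = as.numeric(interval_min),
         channels = lapply(channels, as.numeric),
         lights_on_hour = as.numeric(lights_on_hour),
         photoperiod_h = as.numeric(photoperiod_h),
         extra = extra),
    class = "cage_recording")
  validate_recording(rec)
}

#' Validate a cage recording's invariants
#'
#' Checks equal channel lengths, non-negativity of gas-exchange and count
#' channels, positivity of the sampling step and age, and consistency of a
#' recorded RER channel with VCO2/VO2 wherever VO2 > 0.
#'
#' @param rec a `cage_recording`.
#' @return `rec`, invisibly-validated (errors on violation).
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "cage_recording"))
  if (rec$interval_min <= 0) stop("interval_min must be > 0")
  if (rec$age_weeks <= 0) stop("age_weeks must be > 0")
  if (rec$body_weight_g <= 0) stop("body_weight_g must be > 0")
  lens <- vapply(rec$channels, length, 1L)
  if (length(lens) == 0 || any(lens < 1))
    stop("recording must hold at least one sample in at least one channel")
  if (length(unique(lens)) != 1)
    stop("all channel series must have identical length")
  for (ch in intersect(names(rec$channels), .COUNT_CHANNELS)) {
    v <- rec$channels[[ch]]
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("channel %s must be non-negative", ch))
  }
  chs <- rec$channels
  if (all(c("VO2", "VCO2", "RER") %in% names(chs))) {
    i <- which(!is.na(chs$VO2) & chs$VO2 > 0 & !is.na(chs$RER) &
                 !is.na(chs$VCO2))
    if (length(i)) {
      err <- abs(chs$RER[i] - chs$VCO2[i] / chs$VO2[i])
      tol <- 1e-6 * pmax(1, abs(chs$RER[i]))
      if (any(err > tol))
        stop("RER channel inconsistent with VCO2/VO2 where VO2 > 0")
    }
  }
  rec
}

#' @export
print.cage_recording <- function(x, ...) {
  cat(sprintf(
    "<cage_recording> %s  group=%s  age=%gw  weight=%gg\n  %d samples @ %g min (%.1f h) from %s; channels: %s\n",
    x$animal_id, x$group, x$age_weeks, x$body_weight_g,
    n_samples(x), x$interval_min, n_samples(x) * x$interval_min / 60,
    format(x$start_time, "%Y-%m-%d %H:%M"),
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `cage_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

# Minutes-of-day of each sample start (0..1439).
sample_minutes_of_day <- function(rec) {
  lt <- as.POSIXlt(rec$start_time)
  start_m <- lt$hour * 60 + lt$min + lt$sec / 60
  (start_m + (seq_len(n_samples(rec)) - 1) * rec$interval_min) %% 1440
}

#' Minutes elapsed since the reference lights-on at the first sample
#'
#' The phase reference used for adjusted-phase values: minutes from the most
#' recent lights-on (default 07:00) to the recording's first sample.
#'
#' @param rec a `cage_recording`.
#' @return minutes in `[0, 1440)`.
#' @export
minutes_after_lights_on <- function(rec) {
  sample_minutes_of_day(rec)[1] %% 1440 -> m0
  (m0 - rec$lights_on_hour * 60) %% 1440
}

#' Annotate every sample with its photoperiod phase
#'
#' A sample is `light` iff its start time falls within
#' `[lights_on, lights_on + light hours)` of the day, otherwise `dark`.
#'
#' @param rec a `cage_recording`.
#' @return factor of length `n_samples(rec)` with levels `light`, `dark`.
#' @export
annotate_phases <- function(rec) {
  m <- sample_minutes_of_day(rec)
  rel <- (m - rec$lights_on_hour * 60) %% 1440
  factor(ifelse(rel < rec$photoperiod_h[1] * 60, "light", "dark"),
         levels = c("light", "dark"))
}

#' Trim a recording to the analysis window
#'
#' Discards an initial acclimation span and returns the contiguous analysis
#' window that follows, per the standard cage protocol (48 h adaptation,
#' then 72 h of analysed data).
#'
#' @param rec a `cage_recording`.
#' @param adaptation_h hours to discard from the start (default 48).
#' @param window_h length of the retained window in hours (default 72).
#' @return a `cage_recording` covering `window_h` hours (to within one
#'   sampling step), starting `adaptation_h` after the original start.
#' @export
trim_to_analysis_window <- function(rec, adaptation_h = 48, window_h = 72) {
  dt <- rec$interval_min
  n <- n_samples(rec)
  avail_h <- n * dt / 60
  if (avail_h < adaptation_h + window_h - dt / 60 * 0.5)
    stop(sprintf(
      "insufficient data: recording spans %.1f h but %g h adaptation + %g h window are required",
      avail_h, adaptation_h, window_h))
  skip <- round(adaptation_h * 60 / dt)
  take <- round(window_h * 60 / dt)
  if (skip + take > n) take <- n - skip
  idx <- seq.int(skip + 1, skip + take)
  out <- rec
  out$start_time <- rec$start_time + skip * dt * 60
  out$channels <- lapply(rec$channels, `[`, idx)
  if (is.data.frame(rec$extra) && nrow(rec$extra) == n)
    out$extra <- rec$extra[idx, , drop = FALSE]
  validate_recording(out)
}

#' Derive energy expenditure and RER from gas exchange
#'
#' Computes energy expenditure with the abbreviated Weir equation,
#' `EE (kcal/h) = (3.941 VO2 + 1.106 VCO2) / 1000` for VO2/VCO2 in ml/h,
#' and fills the respiratory exchange ratio `RER = VCO2/VO2` wherever
#' VO2 > 0 (RER is left missing, not zero, where VO2 <= 0). RER near 1
#' indicates pure carbohydrate oxidation, near 0.7 pure fat oxidation.
#'
#' @param rec a `cage_recording` with `VO2` and `VCO2` channels.
#' @param method currently only `"weir"`.
#' @param coef named numeric pair of Weir coefficients, overridable.
#' @return the recording with `EE` and `RER` channels (re)computed.
#' @export
derive_ee <- function(rec, method = c("weir"),
                      coef = c(vo2 = 3.941, vco2 = 1.106)) {
  method <- match.arg(method)
  chs <- rec$channels
  if (!all(c("VO2", "VCO2") %in% names(chs)))
    stop("derive_ee requires VO2 and VCO2 channels")
  vo2 <- chs$VO2; vco2 <- chs$VCO2
  rec$channels$EE <- (coef[["vo2"]] * vo2 + coef[["vco2"]] * vco2) / 1000
  rer <- rep(NA_real_, length(vo2))
  ok <- !is.na(vo2) & vo2 > 0 & !is.na(vco2)
  rer[ok] <- vco2[ok] / vo2[ok]
  rec$channels$RER <- rer
  validate_recording(rec)
}

#' Describe a cage-table dialect
#'
#' Maps a vendor export's column names onto the canonical schema and fixes
#' the delimiter and decimal mark.
#'
#' @param sep field separator (default `","`).
#' @param dec decimal mark (default `"."`; set `","` for continental
#'   exports).
#' @param timestamp_col,id_col names of the timestamp and animal-id columns.
#' @param aliases named character vector mapping file column names to
#'   canonical names (channels or the metadata columns `group`,
#'   `age_weeks`, `body_weight_g`); e.g. `c(Weight = "body_weight_g")`.
#' @return a `cage_dialect` list.
#' @export
cage_dialect <- function(sep = ",", dec = ".", timestamp_col = "timestamp",
                         id_col = "animal_id", aliases = character()) {
  structure(list(sep = sep, dec = dec, timestamp_col = timestamp_col,
                 id_col = id_col, aliases = aliases),
            class = "cage_dialect")
}

.parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y/%m/%d %H:%M:%OS"))
  if (anyNA(out)) stop("format error: unparseable values in timestamp column")
  out
}

#' Read a long-format metabolic-cage table into recordings
#'
#' Expects one row per (animal, timestamp) with a header naming the
#' timestamp column, the animal-id column, and at least one known channel.
#' Per-animal metadata (`group`, `age_weeks`, `body_weight_g`) may be
#' supplied as in-table columns or via the `metadata` sidecar. Unknown
#' columns are preserved per-sample in each recording's `extra` slot.
#'
#' @param source path to a delimited file, or a `data.frame` already read.
#' @param metadata optional `data.frame` keyed by `animal_id` carrying
#'   `group`, `age_weeks`, `body_weight_g` (and optionally
#'   `lights_on_hour`).
#' @param dialect a [cage_dialect()].
#' @param default_interval_min sampling step assumed when an animal has a
#'   single row (the step cannot be inferred), default 18.
#' @param lights_on_hour default lights-on hour when absent from metadata.
#' @return named list of `cage_recording`, one per animal, rows sorted by
#'   time.
#' @export
read_cage_table <- function(source, metadata = NULL,
                            dialect = cage_dialect(),
                            default_interval_min = 18, lights_on_hour = 7) {
  df <- if (is.data.frame(source)) source else
    utils::read.table(source, header = TRUE, sep = dialect$sep,
                      dec = dialect$dec, check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (length(dialect$aliases)) {
    hit <- names(df) %in% names(dialect$aliases)
    names(df)[hit] <- unname(dialect$aliases[names(df)[hit]])
  }
  for (col in c(dialect$timestamp_col, dialect$id_col))
    if (!col %in% names(df))
      stop(sprintf("format error: missing mandatory column '%s'", col))
  known <- intersect(names(df), .KNOWN_CHANNELS)
  if (length(known) == 0)
    stop("format error: no known channel column present")
  meta_cols <- intersect(names(df), c("group", "age_weeks", "body_weight_g"))
  ts <- .parse_timestamps(df[[dialect$timestamp_col]])
  ids <- as.character(df[[dialect$id_col]])

  out <- list()
  for (id in unique(ids)) {
    sub <- df[ids == id, , drop = FALSE]
    tsub <- ts[ids == id]
    o <- order(tsub)
    sub <- sub[o, , drop = FALSE]; tsub <- tsub[o]
    if (anyDuplicated(tsub))
      stop(sprintf("duplication error: duplicate (animal, timestamp) rows for '%s'", id))
    if (length(tsub) > 1) {
      steps <- diff(as.numeric(tsub)) / 60
      dt <- stats::median(steps)
      if (any(abs(steps - dt) > 1e-3 * dt))
        stop(sprintf("sampling error: non-uniform timestamps for '%s'", id))
    } else dt <- default_interval_min

    meta <- list(group = "unknown", age_weeks = NA_real_,
                 body_weight_g = NA_real_, lights_on_hour = lights_on_hour)
    for (mc in meta_cols) meta[[mc]] <- sub[[mc]][1]
    if (!is.null(metadata)) {
      mrow <- metadata[as.character(metadata$animal_id) == id, , drop = FALSE]
      if (nrow(mrow) == 1)
        for (mc in intersect(names(mrow),
                             c("group", "age_weeks", "body_weight_g",
                               "lights_on_hour")))
          meta[[mc]] <- mrow[[mc]][1]
    }
    if (is.na(meta$age_weeks) || is.na(meta$body_weight_g))
      stop(sprintf(
        "format error: metadata (age_weeks, body_weight_g) missing for '%s'; supply in-table or via `metadata`", id))

    drop_cols <- c(dialect$timestamp_col, dialect$id_col, known, meta_cols)
    extra <- sub[, setdiff(names(sub), drop_cols), drop = FALSE]
    out[[id]] <- recording(
      animal_id = id, group = meta$group, age_weeks = meta$age_weeks,
      body_weight_g = meta$body_weight_g, start_time = tsub[1],
      interval_min = dt,
      channels = as.list(sub[, known, drop = FALSE]),
      lights_on_hour = meta$lights_on_hour,
      extra = extra)
  }
  out
}

#' Write recordings back to the canonical long-format table
#'
#' Inverse of [read_cage_table()]; numeric channels are written with 17
#' significant digits so a read/write/read round trip is bit-identical.
#'
#' @param recordings list of `cage_recording`.
#' @param file output path (CSV).
#' @return `file`, invisibly.
#' @export
write_cage_table <- function(recordings, file) {
  blocks <- lapply(recordings, function(rec) {
    n <- n_samples(rec)
    tt <- rec$start_time + (seq_len(n) - 1) * rec$interval_min * 60
    cbind(
      data.frame(animal_id = rec$animal_id,
                 timestamp = format(tt, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 group = rec$group,
                 age_weeks = sprintf("%.17g", rec$age_weeks),
                 body_weight_g = sprintf("%.17g", rec$body_weight_g),
                 stringsAsFactors = FALSE),
      as.data.frame(lapply(rec$channels, function(v) sprintf("%.17g", v)),
                    optional = TRUE))
  })
  df <- do.call(rbind, blocks)
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
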