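#' Construct an annotated sensor-event stream
#'
#' An `event_stream` is an ordered table of binary ambient-sensor firings, the
#' basic data structure of the package. Each event carries the calendar day,
#' an absolute clock in seconds counted from the first day's midnight (so
#' intervals that straddle midnight, e.g. during sleep, are correct), the
#' seconds since midnight of its own day, an integer sensor index, a binary
#' value (1 = ON/OPEN, 0 = OFF/CLOSE) and an optional activity annotation
#' (`activity` name plus a `begin`/`end` marker) as found in CASAS-style
#' smart-home logs. Activity labels (integer indices) are attached by
#' [assign_labels()].
#'
#' @param events data.frame with columns `date` (character, `yyyy-mm-dd`),
#'   `time_of_day` (numeric seconds since midnight), `sensor` (integer index),
#'   `value` (0/1), and optionally `activity`, `marker` (character or `NA`)
#'   and `label` (integer). `time_abs` is derived, never supplied free-form.
#' @param sensor_catalog named integer vector mapping sensor name to index.
#' @param activity_catalog named integer vector mapping activity name to index
#'   (may be empty and grow in [assign_labels()]).
#' @return An object of class `event_stream` (a data.frame with catalog
#'   attributes), sorted nondecreasing in `time_abs` with ties keeping input
#'   order.
#' @seealso [read_casas()], [write_casas()], [assign_labels()]
#' @export
event_stream <- function(events,
                         sensor_catalog,
                         activity_catalog = integer()) {
  req <- c("date", "time_of_day", "sensor", "value")
  miss <- setdiff(req, names(events))
  if (length(miss)) stopf("event_stream: missing columns: %s", paste(miss, collapse = ", "))
  n <- nrow(events)
  if (is.null(events$activity)) events$activity <- rep(NA_character_, n)
  if (is.null(events$marker)) events$marker <- rep(NA_character_, n)
  if (is.null(events$label)) events$label <- rep(NA_integer_, n)
  if (n && !all(events$value %in% c(0L, 1L)))
    stopf("event_stream: sensor values must be 0 or 1")
  if (n && !all(events$sensor %in% sensor_catalog))
    stopf("event_stream: sensor index not present in sensor_catalog")
  # absolute clock: whole days since the stream's first calendar day, plus
  # the within-day timestamp
  if (n) {
    d <- as.Date(events$date)
    day0 <- min(d)
    events$time_abs <- as.numeric(d - day0) * 86400 + events$time_of_day
  } else {
    events$time_abs <- numeric()
  }
  o <- order(events$time_abs, method = "radix") # stable: ties keep input order
  events <- events[o, c("date", "time_abs", "time_of_day", "sensor", "value",
                        "activity", "marker", "label")]
  rownames(events) <- NULL
  structure(events,
            sensor_catalog = sensor_catalog,
            activity_catalog = activity_catalog,
            class = c("event_stream", "data.frame"))
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events, %d sensors, %d catalogued activities\n",
              nrow(x), length(attr(x, "sensor_catalog")),
              length(attr(x, "activity_catalog"))))
  if (nrow(x)) {
    cat(sprintf("  span: %s .. %s (%.1f h)\n", x$date[1], x$date[nrow(x)],
                (x$time_abs[nrow(x)] - x$time_abs[1]) / 3600))
    utils::head(as.data.frame(x), 5) |> print()
  }
  invisible(x)
}

sensor_catalog <- function(stream) attr(stream, "sensor_catalog")
activity_catalog <- function(stream) attr(stream, "activity_catalog")

#' Default catalogs and functional-area maps for the Aruba testbed
#'
#' The Aruba smart home has 31 ceiling motion sensors (`M001`--`M031`, indices
#' 1--31) and four door sensors (`D001`--`D004`, indices 32--35); temperature
#' sensors are excluded because they carry no motion information. Eleven
#' activity classes (ten annotated activities of daily living plus
#' "Other Activity" for untagged events) map to indices 1--11. Functional
#' areas cluster to five zones (1 Kitchen+Dining, 2 Bedroom+Bathroom,
#' 3 Living, 4 Office, 5 Home Entrance); the activity-to-area assignments
#' below follow the dominant firing areas of each activity. The
#' sensor-to-area map depends on the physical floorplan and must be supplied
#' by the user for this testbed; `Housekeeping` and `Other Activity` have no
#' dominant area and are resolved by the majority-event-area rule in
#' [compute_mts()].
#'
#' @return list with `sensor_catalog`, `activity_catalog`, `activity_area`
#'   (named integer vector, activity name to area index) and `n_areas`.
#' @export
aruba_config <- function() {
  sensors <- c(sprintf("M%03d", 1:31), sprintf("D%03d", 1:4))
  acts <- c("Meal_Preparation", "Relax", "Eating", "Work", "Sleeping",
            "Wash_Dishes", "Bed_to_Toilet", "Enter_Home", "Leave_Home",
            "Housekeeping", "Other Activity")
  list(
    sensor_catalog = stats::setNames(seq_along(sensors), sensors),
    activity_catalog = stats::setNames(seq_along(acts), acts),
    activity_area = c(Meal_Preparation = 1L, Eating = 1L, Wash_Dishes = 1L,
                      Sleeping = 2L, Bed_to_Toilet = 2L, Relax = 3L,
                      Work = 4L, Enter_Home = 5L, Leave_Home = 5L),
    n_areas = 5L
  )
}

parse_time_of_day <- function(s, lineno) {
  p <- strsplit(s, ":", fixed = TRUE)
  bad <- lengths(p) != 3L
  if (any(bad))
    stopf("parse error at line %d: malformed time '%s'", lineno[bad][1], s[bad][1])
  p <- matrix(as.numeric(unlist(p)), ncol = 3, byrow = TRUE)
  if (anyNA(p))
    stopf("parse error at line %d: malformed time", lineno[which(is.na(rowSums(p)))[1]])
  p[, 1] * 3600 + p[, 2] * 60 + p[, 3]
}

#' Read a CASAS-style annotated sensor-event log
#'
#' Parses whitespace-delimited lines of the form
#' `date time sensorID value [activity begin|end]` and digitizes them: sensor
#' names become integer indices, `ON`/`OPEN` become 1 and `OFF`/`CLOSE`
#' become 0, and the timestamp becomes seconds since midnight plus an
#' absolute clock counted from the first day's midnight.
#'
#' @param path file to read.
#' @param catalogs optional list with `sensor_catalog` and (optionally)
#'   `activity_catalog` as in [aruba_config()]. When given, the sensor
#'   catalog is fixed: lines whose sensor is not catalogued (for instance
#'   temperature sensors) are skipped with one summary warning. When `NULL`,
#'   sensors are indexed in first-seen order.
#' @param on_unsorted what to do when timestamps are not nondecreasing:
#'   `"sort"` (stable sort with a warning) or `"error"`.
#' @return an [event_stream()]; annotations are preserved verbatim, labels
#'   are not assigned (see [assign_labels()]).
#' @examples
#' f <- tempfile()
#' writeLines("2010-11-04 02:36:35 M002 ON", f)
#' read_casas(f)
#' @export
read_casas <- function(path, catalogs = NULL,
                       on_unsorted = c("sort", "error")) {
  on_unsorted <- match.arg(on_unsorted)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(event_stream(
      data.frame(date = character(), time_of_day = numeric(),
                 sensor = integer(), value = integer()),
      sensor_catalog = catalogs$sensor_catalog %||% integer(),
      activity_catalog = catalogs$activity_catalog %||% integer()))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- !(nf %in% c(4L, 6L))
  if (any(bad))
    stopf("parse error at line %d: expected 4 or 6 whitespace-delimited fields, found %d",
          lineno[bad][1], nf[bad][1])
  m <- matrix("", nrow = length(toks), ncol = 6)
  for (k in 1:4) m[, k] <- vapply(toks, `[[`, "", k)
  has_ann <- nf == 6L
  if (any(has_ann)) {
    m[has_ann, 5] <- vapply(toks[has_ann], `[[`, "", 5)
    m[has_ann, 6] <- vapply(toks[has_ann], `[[`, "", 6)
  }
  badmark <- has_ann & !(m[, 6] %in% c("begin", "end"))
  if (any(badmark))
    stopf("parse error at line %d: annotation marker must be 'begin' or 'end', found '%s'",
          lineno[badmark][1], m[badmark, 6][1])

  vmap <- c(ON = 1L, OPEN = 1L, OFF = 0L, CLOSE = 0L, `1` = 1L, `0` = 0L)
  value <- vmap[m[, 4]]
  if (anyNA(value))
    stopf("parse error at line %d: unknown sensor value '%s'",
          lineno[is.na(value)][1], m[is.na(value), 4][1])

  scat <- catalogs$sensor_catalog
  fixed <- !is.null(scat)
  if (!fixed) {
    nm <- unique(m[, 3])
    scat <- stats::setNames(seq_along(nm), nm)
  }
  sensor <- scat[m[, 3]]
  drop <- is.na(sensor)
  if (any(drop)) {
    warnf("read_casas: skipped %d lines with uncatalogued sensors (e.g. '%s')",
          sum(drop), m[drop, 3][1])
    m <- m[!drop, , drop = FALSE]
    value <- value[!drop]
    sensor <- sensor[!drop]
    lineno <- lineno[!drop]
  }
  if (!nrow(m))
    return(event_stream(
      data.frame(date = character(), time_of_day = numeric(),
                 sensor = integer(), value = integer()),
      sensor_catalog = scat,
      activity_catalog = catalogs$activity_catalog %||% integer()))

  tod <- parse_time_of_day(m[, 2], lineno)
  d <- as.Date(m[, 1])
  if (anyNA(d))
    stopf("parse error at line %d: malformed date '%s'",
          lineno[is.na(d)][1], m[is.na(d), 1][1])
  tabs <- as.numeric(d - min(d)) * 86400 + tod
  if (is.unsorted(tabs)) {
    if (on_unsorted == "error") stopf("read_casas: timestamps are not nondecreasing")
    warnf("read_casas: timestamps not nondecreasing; stable-sorted by time")
  }
  ev <- data.frame(date = format(d, "%Y-%m-%d"), time_of_day = tod,
                   sensor = unname(sensor), value = unname(value),
                   activity = ifelse(nzchar(m[, 5]), m[, 5], NA_character_),
                   marker = ifelse(nzchar(m[, 6]), m[, 6], NA_character_),
                   stringsAsFactors = FALSE)
  event_stream(ev, sensor_catalog = scat,
               activity_catalog = catalogs$activity_catalog %||% integer())
}

fmt_tod <- function(tod) {
  h <- tod %/% 3600
  mn <- (tod - h * 3600) %/% 60
  s <- tod - h * 3600 - mn * 60
  ifelse(abs(s - round(s)) < 1e-9,
         sprintf("%02d:%02d:%02d", h, mn, round(s)),
         sprintf("%02d:%02d:%09.6f", h, mn, s))
}

#' Write an event stream back to the CASAS text format
#'
#' Inverse of [read_casas()]: `read_casas(write_casas(s), catalogs)` recovers
#' `s` field for field (sensor names taken from the catalog; annotations in
#' columns 5--6).
#'
#' @param stream an [event_stream()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_casas <- function(stream, path) {
  scat <- sensor_catalog(stream)
  sname <- names(scat)[match(stream$sensor, scat)]
  val <- ifelse(stream$value == 1L, "ON", "OFF")
  ln <- paste(stream$date, fmt_tod(stream$time_of_day), sname, val)
  ann <- !is.na(stream$activity) & !is.na(stream$marker)
  ln[ann] <- paste(ln[ann], stream$activity[ann], stream$marker[ann])
  writeLines(ln, path)
  invisible(path)
}

#' Label every event with its enclosing activity
#'
#' Walks the begin/end annotation markers and assigns each event the integer
#' index of the activity span that contains it; the events carrying the
#' markers themselves belong to the span. Untagged events get the
#' "Other Activity" index. When spans overlap or nest (which the annotation
#' format permits but rarely exhibits) the innermost, i.e. most recently
#' opened, span wins and a warning is raised once.
#'
#' @param stream an [event_stream()] whose annotations use matched
#'   begin/end markers.
#' @param other name of the catch-all class for untagged events.
#' @return the stream with the `label` column filled and the activity catalog
#'   extended (first-seen order) to cover all annotated activities plus
#'   `other`. Idempotent; event count and order unchanged.
#' @export
assign_labels <- function(stream, other = "Other Activity") {
  acat <- activity_catalog(stream)
  n <- nrow(stream)
  lab <- integer(n)
  open <- character(0) # stack of open activity names, innermost last
  overlap_seen <- FALSE
  name_of <- function(a) {
    if (!a %in% names(acat)) acat[[a]] <<- length(acat) + 1L
    acat[[a]]
  }
  act <- stream$activity
  mk <- stream$marker
  for (i in seq_len(n)) {
    if (!is.na(mk[i]) && mk[i] == "begin") {
      if (act[i] %in% open)
        warnf("assign_labels: 'begin' for already-open activity '%s' at event %d", act[i], i)
      open <- c(open, act[i])
      if (length(open) > 1L) overlap_seen <- TRUE
      lab[i] <- name_of(act[i])
    } else if (!is.na(mk[i]) && mk[i] == "end") {
      if (!act[i] %in% open)
        stopf("assign_labels: 'end' without matching 'begin' for activity '%s' at event %d",
              act[i], i)
      lab[i] <- name_of(act[i])
      # close the most recent matching span
      open <- open[-max(which(open == act[i]))]
    } else if (length(open)) {
      lab[i] <- name_of(open[length(open)])
    } else {
      lab[i] <- name_of(other)
    }
  }
  if (length(open))
    warnf("assign_labels: %d activity span(s) left open at end of stream (%s)",
          length(open), paste(unique(open), collapse = ", "))
  if (overlap_seen)
    warnf("assign_labels: overlapping annotation spans; innermost span wins")
  if (!other %in% names(acat)) acat[[other]] <- length(acat) + 1L
  stream$label <- lab
  attr(stream, "activity_catalog") <- acat
  stream
}

# activity instances (begin..end spans) from annotations:
# data.frame(activity, begin, end, duration) with begin/end as event indices
activity_instances <- function(stream) {
  ann <- which(!is.na(stream$marker))
  open <- list()
  out <- list()
  for (i in ann) {
    a <- stream$activity[i]
    if (stream$marker[i] == "begin") {
      open[[a]] <- c(open[[a]], i)
    } else {
      if (is.null(open[[a]]) || !length(open[[a]]))
        stopf("activity_instances: 'end' without 'begin' for '%s' at event %d", a, i)
      b <- open[[a]][length(open[[a]])]
      open[[a]] <- open[[a]][-length(open[[a]])]
      out[[length(out) + 1L]] <- data.frame(
        activity = a, begin = b, end = i,
        duration = stream$time_abs[i] - stream$time_abs[b])
    }
  }
  if (!length(out))
    return(data.frame(activity = character(), begin = integer(),
                      end = integer(), duration = numeric()))
  res <- do.call(rbind, out)
  res[order(res$begin), , drop = FALSE]
}
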