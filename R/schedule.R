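#' Build a night sampling schedule
#'
#' One daytime profile at 16:00 CET, then half-hourly night profiles starting
#' 30 minutes before (geometric) sunset. On new-moon dates the series runs
#' for five hours after its start; on full-moon dates it stops once the Moon
#' reaches an altitude of 50 degrees, falling back to 5.5 hours with a
#' warning if the Moon never gets there that night.
#'
#' @param dates Date vector (one sampling night each).
#' @param lat,lon site coordinates, degrees.
#' @param moonCondition "new" or "full", recycled along `dates`.
#' @param cadenceMin minutes between night profiles (default 30).
#' @return data.frame with columns date, profile_id, time (POSIXct UTC),
#'   label ("day" or "night"), moon_condition; times strictly increasing
#'   within a date.
#' @examples
#' sched <- scheduleProfiles(as.Date("2022-08-25"), 53.15, 13.03, "new")
#' table(sched$label)
#' @export
scheduleProfiles <- function(dates, lat, lon,
                             moonCondition = c("new", "full"),
                             cadenceMin = 30) {
  moonCondition <- rep(match.arg(moonCondition,
                                 c("new", "full"), several.ok = TRUE),
                       length.out = length(dates))
  out <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    d <- dates[i]
    # 16:00 CET = 15:00 UTC
    dayTime <- as.POSIXct(paste(format(d), "15:00:00"), tz = "UTC")
    sunset <- .sunsetUtc(d, lat, lon)
    start <- sunset - 30 * 60
    if (moonCondition[i] == "new") {
      # the five-hour window is counted from sunset; the series begins 30
      # minutes earlier, giving 12 half-hourly night profiles
      times <- seq(start, sunset + 5 * 3600, by = cadenceMin * 60)
    } else {
      times <- start
      repeat {
        nxt <- times[length(times)] + cadenceMin * 60
        if (nxt > start + 5.5 * 3600) {
          warning("moon never reached 50 degrees on ", format(d),
                  "; stopping after 5.5 h")
          break
        }
        times <- c(times, nxt)
        alt <- lunarState(nxt, lat, lon)@lunarAltitude
        if (alt >= 50) break
      }
      times <- as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
    }
    prof <- data.frame(
      date = format(d),
      profile_id = c(sprintf("%s_day", format(d, "%Y%m%d")),
                     sprintf("%s_n%02d", format(d, "%Y%m%d"),
                             seq_along(times))),
      time = c(dayTime, times),
      label = c("day", rep("night", length(times))),
      moon_condition = moonCondition[i])
    out[[i]] <- prof
  }
  res <- do.call(rbind, out)
  attr(res$time, "tzone") <- "UTC"
  rownames(res) <- NULL
  res
}
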