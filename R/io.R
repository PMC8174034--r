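#' @include accessors.R
NULL

SESSION_COLS <- c("session_id", "mouse_id", "group", "criterion_ms",
                  "press_index", "onset_ms", "offset_ms", "rewarded",
                  "session_end_ms")
SPIKE_COLS <- c("unit_id", "session_id", "spike_time_ms")

checkCols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("format error in %s table: missing column(s) %s",
          what, paste(missing, collapse = ", "))
}

#' Read a behavioral-session and spike-time table pair
#'
#' Reads the package's tab-delimited dialects: a session table with one row
#' per press (columns `session_id, mouse_id, group, criterion_ms,
#' press_index, onset_ms, offset_ms, rewarded, session_end_ms`) and a spike
#' table (`unit_id, session_id, spike_time_ms`). Row order is irrelevant;
#' presses are ordered by `press_index`. Every invariant of
#' [BehavioralSession-class], [UnitRecording-class] and [HoldDataset-class]
#' is checked and violations raise errors naming the offending session or
#' unit.
#'
#' @param sessionPath,spikePath file paths to the two tables.
#' @param provenance free-text origin note stored in the dataset.
#' @param maxRewards,maxSessionMs session termination bounds (defaults 60
#'   rewards / 90 min); raise these when loading non-standard sessions.
#' @return A validated [HoldDataset-class].
#' @seealso [writeDataset()] for the inverse.
#' @export
loadDataset <- function(sessionPath, spikePath,
                        provenance = paste("loaded from", sessionPath),
                        maxRewards = 60, maxSessionMs = 90 * 60 * 1000) {
  for (p in c(sessionPath, spikePath))
    if (!file.exists(p)) stopf("file not found: %s", p)
  st <- read.delim(sessionPath, sep = "\t", stringsAsFactors = FALSE)
  sp <- read.delim(spikePath, sep = "\t", stringsAsFactors = FALSE)
  checkCols(st, SESSION_COLS, "session")
  checkCols(sp, SPIKE_COLS, "spike")

  sessions <- lapply(split(st, st$session_id), function(d) {
    d <- d[order(d$press_index), , drop = FALSE]
    tryCatch(
      BehavioralSession(
        sessionId = d$session_id[1], mouseId = d$mouse_id[1],
        group = d$group[1], criterionMs = d$criterion_ms[1],
        pressOnsets = d$onset_ms, pressOffsets = d$offset_ms,
        rewardTimes = d$offset_ms[d$rewarded == 1],
        sessionEndMs = d$session_end_ms[1],
        maxRewards = maxRewards, maxSessionMs = maxSessionMs),
      error = function(e)
        stopf("validation error in session %s: %s",
              d$session_id[1], conditionMessage(e)))
  })

  unitList <- lapply(split(sp, sp$unit_id), function(d) {
    tryCatch(
      UnitRecording(unitId = d$unit_id[1], sessionId = d$session_id[1],
                    spikeTimes = sort(d$spike_time_ms)),
      error = function(e)
        stopf("validation error in unit %s: %s",
              d$unit_id[1], conditionMessage(e)))
  })

  tryCatch(HoldDataset(unname(sessions), unname(unitList), provenance),
           error = function(e)
             stopf("validation error: %s", conditionMessage(e)))
}

#' Write a dataset in the package's table dialects
#'
#' Emits the same tab-delimited session/spike dialects read by
#' [loadDataset()]; spike times are written with six decimal places so that
#' load-after-write reproduces the dataset exactly for times representable
#' at microsecond precision.
#'
#' @param dataset a [HoldDataset-class].
#' @param sessionPath,spikePath output paths.
#' @return Invisibly, the two paths.
#' @export
writeDataset <- function(dataset, sessionPath, spikePath) {
  rows <- lapply(sessions(dataset), function(s) {
    n <- nPresses(s)
    data.frame(
      session_id = rep(sessionId(s), n), mouse_id = rep(mouseId(s), n),
      group = rep(groupLabel(s), n),
      criterion_ms = rep(criterionMs(s), n),
      press_index = seq_len(n), onset_ms = pressOnsets(s),
      offset_ms = pressOffsets(s),
      rewarded = as.integer(pressOffsets(s) %in% rewardTimes(s)),
      session_end_ms = rep(sessionEnd(s), n),
      stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(st, sessionPath, sep = "\t", quote = FALSE, row.names = FALSE)

  srows <- lapply(units(dataset), function(u) {
    data.frame(unit_id = rep(unitId(u), nSpikes(u)),
               session_id = rep(sessionId(u), nSpikes(u)),
               spike_time_ms = sprintf("%.6f", spikeTimes(u)),
               stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, c(srows, list(make.row.names = FALSE)))
  write.table(sp, spikePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sessionPath, spikePath))
}
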