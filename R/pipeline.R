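#' @include simulate.R peth.R press-dynamics.R decoding.R behavior-metrics.R io.R sessions.R
NULL

# Recursive default merge: values in `user` override `defaults`.
mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !inherits(user[[nm]], c("BehaviorParams", "UnitPrior", "GroupEffect")))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Pipeline run configuration
#'
#' Assembles the full configuration of a pipeline run, with every analysis
#' parameter defaulting to the study value where one exists: 20-ms PETH
#' bins over -10,000..+10,000 ms, baseline -10,000..-2,000 ms, 4-bin
#' modulation rule over -2,000..+3,000 ms, 250-ms epoch bins, 100-ms step /
#' 200-ms width decoder with 10 cross-validation splits, 500 resampling
#' runs and 5 shuffled-label nulls, 10-success session filter, 1000-spike
#' unit filter. Overrides may be supplied as named nested lists and/or a
#' YAML file (`file`); explicit arguments win over the file.
#'
#' @param ... named overrides of the sections `seed`, `input`, `simulation`,
#'   `filters`, `peth`, `decoding`, `outDir`.
#' @param file optional YAML configuration file.
#' @return A classed nested list (`RunConfig`).
#' @export
runConfig <- function(..., file = NULL) {
  defaults <- list(
    seed = 1,
    outDir = file.path(tempdir(), "holddown_run"),
    input = list(sessionTable = NULL, spikeTable = NULL),
    simulation = list(nMicePerGroup = 9, unitsPerMouse = 8,
                      behavior = behaviorParams(), prior = unitPrior(),
                      effects = list(air = groupEffect(),
                                     CIE = groupEffect(1.5, 0.5)),
                      rateCeiling = 500),
    filters = list(minSpikes = 1000),
    peth = list(binWidthMs = 20, windowMs = c(-10000, 10000),
                baselineWindowMs = c(-10000, -2000),
                detectWindowMs = c(-2000, 3000), minRun = 4,
                ciMethod = "percentile", smoothSigmaBins = 0.4),
    decoding = list(enabled = TRUE, alignment = "press_offset",
                    windowMs = c(-2000, 10000), stepMs = 100, widthMs = 200,
                    nRuns = 500, nSplits = 10, nNulls = 5, cost = 1,
                    minSuccesses = 10, nPerClass = NULL))
  cfg <- defaults
  if (!is.null(file)) cfg <- mergeConfig(cfg, yaml::read_yaml(file))
  user <- list(...)
  if (length(user)) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stopf("unknown config section(s): %s",
                           paste(bad, collapse = ", "))
    cfg <- mergeConfig(cfg, user)
  }
  structure(cfg, class = "RunConfig")
}

writeTsv <- function(df, dir, name) {
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

# Subset a dataset to one treatment group.
subsetGroup <- function(dataset, group) {
  keepS <- vapply(sessions(dataset), function(s) groupLabel(s) == group,
                  logical(1))
  dataset@sessions <- dataset@sessions[keepS]
  keepU <- vapply(units(dataset),
                  function(u) u@sessionId %in% names(dataset@sessions),
                  logical(1))
  dataset@units <- dataset@units[keepU]
  dataset
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate, validate and label,
#' unit filtering, PETH/modulation, within-press dynamics, decoding,
#' behavioral metrics — and writes every tidy output table, a
#' machine-readable `summary.json`, the resolved `effective_config.json`, a
#' seed/exclusion `log.txt` and a `MANIFEST` marking stage completion into
#' the run directory. Re-running with the same configuration reproduces all
#' outputs bit-identically.
#'
#' @param config a [runConfig()].
#' @return The run directory path, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- config$outDir
  manifest <- character(0)
  logLines <- character(0)
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  finish <- function(stage, status) {
    manifest <<- c(manifest, sprintf("%s\t%s", stage, status))
    writeLines(manifest, file.path(out, "MANIFEST"))
  }
  runStage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      finish(stage, paste0("failed: ", conditionMessage(e)))
      writeLines(logLines, file.path(out, "log.txt"))
      stopf("stage %s failed: %s", stage, conditionMessage(e))
    })
    finish(stage, "ok")
    res
  }

  ## stage: load or simulate ------------------------------------------------
  ds <- runStage("input", {
    if (!is.null(config$input$sessionTable)) {
      note("loading dataset from %s", config$input$sessionTable)
      loadDataset(config$input$sessionTable, config$input$spikeTable)
    } else {
      sim <- config$simulation
      note("simulating cohort: seed %d, %d mice/group, %d units/mouse",
           config$seed, sim$nMicePerGroup, sim$unitsPerMouse)
      res <- simulateCohort(sim$nMicePerGroup, sim$unitsPerMouse,
                            sim$behavior, sim$prior, sim$effects,
                            seed = config$seed,
                            rateCeiling = sim$rateCeiling)
      writeTsv(res$groundTruth$kernels, out, "ground_truth.tsv")
      res$dataset
    }
  })
  runStage("validate", {
    validObject(ds)
    ds <<- labelPressOutcomes(ds)
    writeDataset(ds, file.path(out, "sessions.tsv"),
                 file.path(out, "spikes.tsv"))
    nBefore <- length(units(ds))
    ds <<- filterUnits(ds, config$filters$minSpikes)
    note("unit filter (>= %d spikes): %d of %d retained",
         config$filters$minSpikes, length(units(ds)), nBefore)
    invisible(NULL)
  })

  groupsOf <- vapply(units(ds),
                     function(u) groupLabel(sessionOf(ds, u)), character(1))

  ## stage: peth -------------------------------------------------------------
  pethTables <- runStage("peth", {
    pcfg <- config$peth
    modRows <- list(); zRows <- list(); epochRows <- list()
    catRows <- list(); onsetZs <- list()
    for (u in units(ds)) {
      ses <- sessionOf(ds, u)
      onsetPeth <- smoothPeth(binSpikes(u, pressOnsets(ses), pcfg$windowMs,
                                        pcfg$binWidthMs, "press_onset"),
                              pcfg$smoothSigmaBins)
      bl <- baselineStats(onsetPeth, pcfg$baselineWindowMs, pcfg$ciMethod)
      mods <- list()
      for (et in EVENT_TYPES) {
        ev <- eventTimesFor(ses, et)
        if (!length(ev)) {
          note("unit %s: no %s events", unitId(u), et)
          mods[[et]] <- new("ModulationResult", unitId = unitId(u),
                            eventType = et, direction = "none",
                            onsetLatencyMs = NA_real_, upOnsetMs = NA_real_,
                            downOnsetMs = NA_real_,
                            windowMs = pcfg$detectWindowMs)
          next
        }
        p <- if (et == "press_onset") onsetPeth else
          smoothPeth(binSpikes(u, ev, pcfg$windowMs, pcfg$binWidthMs, et),
                     pcfg$smoothSigmaBins)
        mods[[et]] <- detectModulation(p, bl, pcfg$detectWindowMs,
                                       pcfg$minRun)
        z <- suppressWarnings(zscorePeth(p, bl))
        if (et == "press_onset") onsetZs[[unitId(u)]] <- z
        zRows[[paste(unitId(u), et)]] <- data.frame(
          unit_id = unitId(u), event_type = et, group = groupLabel(ses),
          bin_center_ms = binCenters(z), z = zScores(z),
          stringsAsFactors = FALSE)
        epoch <- switch(et, press_onset = "pre_onset",
                        press_offset = "post_offset", reward = "post_reward")
        es <- epochSummary(z, epoch)
        epochRows[[paste(unitId(u), et)]] <- data.frame(
          unit_id = unitId(u), group = groupLabel(ses), epoch = epoch,
          bin_index = 1:4, mean_z = unname(es), stringsAsFactors = FALSE)
      }
      modRows[[unitId(u)]] <- do.call(rbind, lapply(mods, function(m)
        data.frame(unit_id = m@unitId, event_type = m@eventType,
                   group = groupLabel(ses), direction = m@direction,
                   onset_ms = m@onsetLatencyMs, stringsAsFactors = FALSE)))
      catRows[[unitId(u)]] <- data.frame(
        unit_id = unitId(u), group = groupLabel(ses),
        category = classifyUnitEvents(mods$press_onset, mods$press_offset,
                                      mods$reward),
        stringsAsFactors = FALSE)
    }
    modTab <- do.call(rbind, c(unname(modRows), list(make.row.names = FALSE)))
    writeTsv(modTab, out, "modulation.tsv")
    writeTsv(do.call(rbind, c(unname(zRows), list(make.row.names = FALSE))),
             out, "ztrace.tsv")
    writeTsv(do.call(rbind, c(unname(epochRows),
                              list(make.row.names = FALSE))),
             out, "epoch_summary.tsv")
    writeTsv(do.call(rbind, c(unname(catRows), list(make.row.names = FALSE))),
             out, "unit_categories.tsv")
    if (length(onsetZs)) {
      grp <- vapply(names(onsetZs), function(uid)
        groupLabel(sessionOf(ds, ds@units[[uid]])), character(1))
      ok <- !vapply(onsetZs, function(z) z@degenerate, logical(1))
      ga <- groupAverage(onsetZs[ok], grp[ok])
      writeTsv(ga, out, "group_average.tsv")
    }
    list(mod = modTab)
  })

  ## stage: press dynamics ----------------------------------------------------
  runStage("press_dynamics", {
    qRows <- list(); sRows <- list(); pRows <- list()
    qas <- list()
    for (s in sessions(ds)) {
      if (nPresses(s) >= 4) {
        qa <- assignQuartiles(s)
        qas[[sessionId(s)]] <- qa
        qRows[[sessionId(s)]] <- data.frame(
          session_id = sessionId(s), press_index = seq_len(nPresses(s)),
          duration_ms = pressDurations(s), quartile = qa$quartile,
          stringsAsFactors = FALSE)
      } else note("session %s: <4 presses, no quartiles", sessionId(s))
    }
    for (u in units(ds)) {
      ses <- sessionOf(ds, u)
      if (!nPresses(ses)) next
      sp <- segmentSpikeProportions(u, ses)
      sRows[[unitId(u)]] <- data.frame(
        unit_id = unitId(u), group = groupLabel(ses),
        presence_fraction = spikePresenceFraction(u, ses),
        seg1 = sp$unitMean[1], seg2 = sp$unitMean[2],
        seg3 = sp$unitMean[3], seg4 = sp$unitMean[4],
        n_included = sp$nIncluded, stringsAsFactors = FALSE)
      qa <- qas[[sessionId(ses)]]
      if (!is.null(qa)) {
        prof <- quartileSegmentProfiles(u, ses, qa)
        pRows[[unitId(u)]] <- do.call(rbind, lapply(prof, function(pr)
          data.frame(unit_id = pr$unitId, group = groupLabel(ses),
                     quartile = pr$quartile, segment = 1:4,
                     mean_z = pr$meanZ, n_presses = pr$nPresses,
                     valid = pr$valid, stringsAsFactors = FALSE)))
      }
    }
    if (length(qRows))
      writeTsv(do.call(rbind, c(unname(qRows), list(make.row.names = FALSE))),
               out, "press_quartiles.tsv")
    if (length(sRows))
      writeTsv(do.call(rbind, c(unname(sRows), list(make.row.names = FALSE))),
               out, "segment_proportions.tsv")
    if (length(pRows))
      writeTsv(do.call(rbind, c(unname(pRows), list(make.row.names = FALSE))),
               out, "quartile_profiles.tsv")
    invisible(NULL)
  })

  ## stage: decoding -----------------------------------------------------------
  decSummary <- NULL
  if (isTRUE(config$decoding$enabled)) {
    decSummary <- runStage("decoding", {
      dcfg <- config$decoding
      rows <- list()
      for (g in unique(groupsOf)) {
        dsg <- subsetGroup(ds, g)
        ok <- any(vapply(sessions(dsg), sessionInclusion,
                         logical(1), minSuccesses = dcfg$minSuccesses))
        if (!ok) { note("group %s: no session passes the %d-success filter",
                        g, dcfg$minSuccesses); next }
        res <- decodeTimecourse(dsg, dcfg$alignment, dcfg$nPerClass,
                                dcfg$windowMs, dcfg$stepMs, dcfg$widthMs,
                                dcfg$nRuns, dcfg$nSplits, dcfg$cost,
                                nNulls = dcfg$nNulls,
                                seed = mixSeed(config$seed, 9000, match(g, GROUPS)),
                                minSuccesses = dcfg$minSuccesses)
        hasNull <- dcfg$nNulls > 0
        if (hasNull) res <- significanceMask(res)
        nullMean <- if (hasNull)
          apply(res@nullAccuracies, 3, mean, na.rm = TRUE)
          else rep(NA_real_, length(res@timeCenters))
        rows[[g]] <- data.frame(
          group = g, alignment = dcfg$alignment,
          time_center_ms = res@timeCenters, mean_accuracy = res@accuracy,
          null_mean = nullMean,
          p_raw = if (hasNull) res@pRaw else NA_real_,
          p_bh = if (hasNull) res@pBH else NA_real_,
          stringsAsFactors = FALSE)
      }
      if (length(rows)) {
        tab <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
        writeTsv(tab, out, "accuracy_curve.tsv")
        tab
      } else NULL
    })
  } else finish("decoding", "skipped")

  ## stage: behavior metrics ----------------------------------------------------
  runStage("behavior_metrics", {
    rows <- lapply(sessions(ds), function(s) {
      m <- sessionMetrics(s)
      data.frame(session_id = m$sessionId, mouse_id = mouseId(s),
                 group = groupLabel(s), total_presses = m$totalPresses,
                 percent_rewarded = m$percentRewarded,
                 response_rate_per_min = m$responseRatePerMin,
                 stringsAsFactors = FALSE)
    })
    writeTsv(do.call(rbind, c(unname(rows), list(make.row.names = FALSE))),
             out, "session_metrics.tsv")
    invisible(NULL)
  })

  ## summary + bookkeeping -------------------------------------------------------
  runStage("summary", {
    mod <- pethTables$mod
    modulated <- mod$direction != "none"
    summary <- list(
      seed = config$seed,
      n_sessions = length(sessions(ds)),
      n_units = length(units(ds)),
      fraction_modulated_any =
        mean(tapply(modulated, mod$unit_id, any)),
      fraction_modulated_by_event = lapply(
        split(modulated, mod$event_type), mean),
      decoding = if (!is.null(decSummary)) lapply(
        split(decSummary, decSummary$group), function(d)
          list(peak_accuracy = max(d$mean_accuracy),
               peak_time_ms = d$time_center_ms[which.max(d$mean_accuracy)]))
        else NULL)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stripClasses <- function(x)
      if (is.list(x)) lapply(unclass(x), stripClasses) else x
    cfgOut <- stripClasses(config)
    jsonlite::write_json(cfgOut, file.path(out, "effective_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(logLines, file.path(out, "log.txt"))
    invisible(NULL)
  })
  invisible(out)
}

readRunTable <- function(runDir, name, required = TRUE) {
  p <- file.path(runDir, name)
  if (!file.exists(p)) {
    if (required) stopf("missing table: %s", name)
    return(NULL)
  }
  read.delim(p, sep = "\t", stringsAsFactors = FALSE)
}

#' Render a summary report from a run directory
#'
#' Draws the five standard panels — group-averaged z traces, modulation
#' category counts, epoch summaries, quartile segment profiles, and the
#' decoding accuracy curve with its null band — from the tidy tables alone.
#' A missing decoding table downgrades to a warning and the panel is
#' skipped; any other missing table is an error naming it. Regeneration is
#' idempotent.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @param file output PDF path (default `report.pdf` inside `runDir`).
#' @return The report path, invisibly.
#' @export
makeReport <- function(runDir, file = file.path(runDir, "report.pdf")) {
  ga <- readRunTable(runDir, "group_average.tsv")
  cats <- readRunTable(runDir, "unit_categories.tsv")
  ep <- readRunTable(runDir, "epoch_summary.tsv")
  qp <- readRunTable(runDir, "quartile_profiles.tsv", required = FALSE)
  acc <- readRunTable(runDir, "accuracy_curve.tsv", required = FALSE)
  if (is.null(acc)) warnf("accuracy_curve.tsv absent; decoding panel skipped")

  grDevices::pdf(file, width = 8, height = 10)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
  cols <- c(air = "black", CIE = "firebrick")

  plot(NA, xlim = range(ga$time_ms), ylim = range(ga$mean_z, na.rm = TRUE),
       xlab = "time from press onset (ms)", ylab = "mean z",
       main = "group-averaged z traces")
  for (g in unique(ga$group)) {
    d <- ga[ga$group == g, ]
    graphics::lines(d$time_ms, d$mean_z, col = cols[[g]])
  }
  graphics::legend("topleft", legend = unique(ga$group),
                   col = cols[unique(ga$group)], lty = 1, bty = "n")

  tab <- table(cats$category)
  graphics::barplot(sort(tab, decreasing = TRUE), las = 2,
                    main = "task-event membership", ylab = "units")

  for (epo in unique(ep$epoch)) {
    d <- ep[ep$epoch == epo, ]
    agg <- aggregate(mean_z ~ bin_index + group, d, mean)
    plot(NA, xlim = c(1, 4), ylim = range(agg$mean_z), xlab = "250-ms bin",
         ylab = "mean z", main = epo)
    for (g in unique(agg$group)) {
      a <- agg[agg$group == g, ]
      graphics::lines(a$bin_index, a$mean_z, type = "b", col = cols[[g]])
    }
  }

  if (!is.null(qp)) {
    d <- qp[qp$valid, ]
    agg <- aggregate(mean_z ~ segment + quartile, d, mean)
    plot(NA, xlim = c(1, 4), ylim = range(agg$mean_z), xlab = "segment",
         ylab = "mean z", main = "quartile segment profiles")
    for (q in 1:4) {
      a <- agg[agg$quartile == q, ]
      if (nrow(a)) graphics::lines(a$segment, a$mean_z, type = "b",
                                   col = grDevices::gray(q / 5))
    }
  }

  if (!is.null(acc)) {
    plot(NA, xlim = range(acc$time_center_ms), ylim = c(0.3, 1),
         xlab = sprintf("time from %s (ms)", acc$alignment[1]),
         ylab = "accuracy", main = "decoding accuracy")
    graphics::abline(h = 0.5, lty = 3)
    for (g in unique(acc$group)) {
      d <- acc[acc$group == g, ]
      graphics::lines(d$time_center_ms, d$mean_accuracy, col = cols[[g]])
      if (!all(is.na(d$null_mean)))
        graphics::lines(d$time_center_ms, d$null_mean, col = cols[[g]],
                        lty = 2)
    }
  }
  invisible(file)
}
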