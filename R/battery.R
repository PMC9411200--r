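# End-to-end battery: simulate (or receive) a cohort, run the per-assay
# pipelines, collect group tables and statistics, and optionally write the
# full report bundle to disk.

ldScheduleDays <- function(nDays, on = 6, off = 18, originClock = 0)
  lightSchedule(list(list(type = "LD", on = on, off = off, days = nDays)),
                originClock = originClock)

ddScheduleDays <- function(nDays, priorOffClock = 18, originClock = 0)
  lightSchedule(list(list(type = "DD", days = nDays)),
                originClock = originClock,
                referenceLightsOff = (priorOffClock - originClock) - 24)

stageMeasure <- function(tab, measure, subject, group, value)
  rbind(tab, data.frame(measure = measure, subject_id = subject,
                        group_label = group, value = value))

pairwiseStats <- function(tab) {
  out <- list()
  for (msr in unique(tab$measure)) {
    sub <- tab[tab$measure == msr & is.finite(tab$value), ]
    sub <- sub[, c("subject_id", "group_label", "value")]
    if (nrow(sub) < 4) next
    ex <- excludeOutliers(sub, k = 3)
    groups <- unique(ex$table$group_label)
    if (length(groups) < 2) next
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      a <- ex$table$value[ex$table$group_label == groups[i]]
      b <- ex$table$value[ex$table$group_label == groups[j]]
      if (length(a) < 2 || length(b) < 2) next
      st <- twoSampleTest(a, b,
                          excludedIds = as.character(ex$excluded$subject_id))
      out[[length(out) + 1]] <- data.frame(
        measure = msr, group_a = groups[i], group_b = groups[j],
        mean_a = mean(a), mean_b = mean(b), t = st@statistic, df = st@df,
        p = st@pValue, hedges_g = st@effectSizeG,
        n_excluded = nrow(ex$excluded))
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Run the full circadian analysis battery on simulated cohorts
#'
#' Executes the configured assay stages on cohorts simulated from named
#' presets: entrained LD (alpha, onset variability, periodogram power,
#' non-parametric amplitude, phase-specific Tb), free-running DD (tau,
#' onset error, alpha of activity and Tb), and restricted feeding (FAA
#' with the retention probe).  Group tables pass through the 3-SD outlier
#' rule before pooled t tests between every pair of groups.  A stage
#' failure for one subject is recorded and the battery continues.
#'
#' @param config a list (or path to a YAML file) with entries `seed`,
#'   `presets` (character), `nPerGroup`, and a `stages` list with any of
#'   `ld` (list(days)), `dd` (list(days)), `rf` (list(trainingDays)).
#' @param outDir optional directory; when given, measure tables, stats,
#'   episode tables and a run log are written as CSVs.
#' @return list with one element per executed stage (`measures`, `stats`,
#'   `episodes`, `errors`) plus `log`.
#' @export
runBattery <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed), !is.null(config$presets),
            !is.null(config$nPerGroup))
  presets <- unlist(config$presets)
  n <- config$nPerGroup
  res <- list()
  log <- c(sprintf("chronotel %s",
                   as.character(utils::packageVersion("chronotel"))),
           sprintf("seed %d", config$seed),
           sprintf("presets %s, n %d", paste(presets, collapse = "/"), n))
  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfgFile)
  log <- c(log, sprintf("config md5 %s", unname(tools::md5sum(cfgFile))))
  unlink(cfgFile)

  runStage <- function(name, days, feeding = NULL, schedule, assay) {
    cohort <- simulateCohort(presets, n,
                             baseSeed = config$seed + match(name,
                               c("ld", "dd", "rf")),
                             light = schedule, feeding = feeding)
    tab <- data.frame(); eps <- data.frame(); errs <- character(0)
    for (s in cohort) {
      r <- tryCatch(assay(s, schedule, feeding), error = function(e) e)
      if (inherits(r, "error")) {
        errs <- c(errs, sprintf("%s: %s", subjectId(s$series),
                                conditionMessage(r)))
        next
      }
      for (m in names(r$measures))
        tab <- stageMeasure(tab, m, subjectId(s$series),
                            groupLabel(s$series), r$measures[[m]])
      if (!is.null(r$episodes)) {
        r$episodes$subject <- subjectId(s$series)
        eps <- rbind(eps, r$episodes)
      }
    }
    list(measures = tab, stats = pairwiseStats(tab), episodes = eps,
         errors = errs)
  }

  if (!is.null(config$stages$ld)) {
    days <- config$stages$ld$days %||% 12
    sched <- ldScheduleDays(days)
    res$ld <- runStage("ld", days, NULL, sched, function(s, sched, feeding) {
      ep <- detectEpisodes(s$series, sched)
      asum <- alphaSummary(ep)
      ps <- phaseSummary(s$series, sched)
      lsp <- lombScargle(rebin(s$series, 6))
      amp <- npcraAmplitude(rebin(s$series, 6))
      list(measures = list(alpha_lma_h = asum$mean_h,
                           onset_sd_h = onsetVariabilityLD(ep),
                           lsp_pn = peakPower(lsp),
                           rel_amplitude = relativeAmplitude(amp),
                           mean_tb_c = ps@meanTb,
                           dark_counts = ps@darkCounts,
                           light_counts = ps@lightCounts),
           episodes = ep)
    })
    log <- c(log, sprintf("ld stage: %d days", days))
  }
  if (!is.null(config$stages$dd)) {
    days <- config$stages$dd$days %||% 11
    sched <- ddScheduleDays(days + 1)
    res$dd <- runStage("dd", days, NULL, sched, function(s, sched, feeding) {
      ep <- detectEpisodes(s$series, sched)
      fit <- fitTau(ep)
      eptb <- detectTbElevation(s$series, sched)
      ps <- phaseSummary(s$series, sched, episodes = ep)
      list(measures = list(tau_h = tauHours(fit),
                           onset_rms_h = onsetErrorDD(ep, fit),
                           alpha_lma_h = alphaSummary(ep)$mean_h,
                           alpha_tb_h = alphaSummary(eptb)$mean_h,
                           mean_tb_c = ps@meanTb),
           episodes = rbind(ep, eptb))
    })
    log <- c(log, sprintf("dd stage: %d days", days))
  }
  if (!is.null(config$stages$rf)) {
    tr <- config$stages$rf$trainingDays %||% 12
    feeding <- rfSchedule(tr)
    nDays <- tr + 4 + 1
    sched <- ldScheduleDays(nDays)
    res$rf <- runStage("rf", nDays, feeding, sched,
                       function(s, sched, feeding) {
      fa <- faa(s$series, sched, feeding)
      ret <- fa$faa_fraction[fa$day_type == "retention"]
      trn <- fa$faa_fraction[fa$day_type == "training"]
      list(measures = list(
        faa_retention2 = if (length(ret) >= 2) ret[2] else NA_real_,
        faa_training_mean = mean(trn, na.rm = TRUE)),
        episodes = NULL)
    })
    log <- c(log, sprintf("rf stage: %d training days", tr))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      write.csv(res[[nm]]$measures,
                file.path(outDir, paste0(nm, "_measures.csv")),
                row.names = FALSE)
      if (!is.null(res[[nm]]$stats))
        write.csv(res[[nm]]$stats,
                  file.path(outDir, paste0(nm, "_stats.csv")),
                  row.names = FALSE)
      if (!is.null(res[[nm]]$episodes) && nrow(res[[nm]]$episodes) > 0)
        write.csv(res[[nm]]$episodes,
                  file.path(outDir, paste0(nm, "_episodes.csv")),
                  row.names = FALSE)
    }
    writeLines(log, file.path(outDir, "battery_log.txt"))
  }
  res$log <- log
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
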