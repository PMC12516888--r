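# Cohort construction from raw bedside time series.
#
# Time is represented internally as hours from ICU admission. Long-format
# signal tables carry one row per (stay_id, signal, time_h, value); stay
# metadata carries demographics, comorbidity flags and admission /
# discharge / death times. Signal names are free-form but the canonical
# names used by the built-in generators are lowercase snake_case
# ("peep", "pf_ratio", "lactate", ...).

HOURS_PER_DAY <- 24

#' Mechanical-ventilation onset for one stay
#'
#' MV onset is defined as the time of the first recorded positive
#' end-expiratory pressure (PEEP) value. A stay with no PEEP record carries
#' no MV signal and is excluded from the cohort; this is signalled by `NA`,
#' not an error.
#'
#' @param signals data.frame with columns `signal` and `time_h` for a
#'   single stay.
#' @param peep_signal name of the PEEP signal (default `"peep"`).
#' @return onset time in hours from admission, or `NA_real_` if no PEEP
#'   sample exists.
#' @export
mv_onset <- function(signals, peep_signal = "peep") {
  t <- signals$time_h[signals$signal == peep_signal]
  if (length(t) == 0L) return(NA_real_)
  min(t)
}

#' Apply cohort inclusion and exclusion criteria
#'
#' Retains adult stays (age >= 18) ventilated for at least `min_vent_h`
#' hours from the first PEEP value, excluding deaths within the first ICU
#' day (counted from ICU admission, not MV onset). Ventilation duration is
#' the span from MV onset to the last record of any ventilation-associated
#' signal. Stays with missing age are routed to an `unevaluable` count,
#' never silently kept. Criteria are applied in a fixed order (unevaluable,
#' no MV, age, early death, short ventilation) so the counts partition the
#' input, as in a consort diagram.
#'
#' @param stays data.frame with columns `stay_id`, `age`, and optionally
#'   `death_h` (hours from admission, `NA` for survivors).
#' @param signals long-format signal data.frame with `stay_id`, `signal`,
#'   `time_h`.
#' @param vent_signals signal names whose records count as
#'   ventilation-associated (default `"peep"`).
#' @param min_age inclusion age in years.
#' @param min_vent_h minimum ventilation span in hours.
#' @param early_death_h early-death exclusion horizon in hours from
#'   admission.
#' @return list with `included` (stay ids), `disposition` (data.frame of
#'   stay_id, status, mv_onset_h), and `counts` (named list: total,
#'   unevaluable, excluded_no_mv, excluded_age, excluded_early_death,
#'   excluded_short_mv, included).
#' @export
apply_cohort_criteria <- function(stays, signals, vent_signals = "peep",
                                  min_age = 18, min_vent_h = 24,
                                  early_death_h = 24) {
  status <- character(nrow(stays))
  onset <- rep(NA_real_, nrow(stays))
  sig_split <- split(signals, signals$stay_id)
  for (i in seq_len(nrow(stays))) {
    id <- stays$stay_id[i]
    sig <- sig_split[[as.character(id)]]
    if (is.null(sig)) sig <- signals[0, ]
    onset[i] <- mv_onset(sig)
    death_h <- if ("death_h" %in% names(stays)) stays$death_h[i] else NA_real_
    if (is.na(stays$age[i])) {
      status[i] <- "unevaluable"
    } else if (is.na(onset[i])) {
      status[i] <- "excluded_no_mv"
    } else if (stays$age[i] < min_age) {
      status[i] <- "excluded_age"
    } else if (!is.na(death_h) && death_h < early_death_h) {
      status[i] <- "excluded_early_death"
    } else {
      vt <- sig$time_h[sig$signal %in% vent_signals]
      span <- if (length(vt)) max(vt) - onset[i] else 0
      status[i] <- if (span < min_vent_h) "excluded_short_mv" else "included"
    }
  }
  counts <- list(
    total = nrow(stays),
    unevaluable = sum(status == "unevaluable"),
    excluded_no_mv = sum(status == "excluded_no_mv"),
    excluded_age = sum(status == "excluded_age"),
    excluded_early_death = sum(status == "excluded_early_death"),
    excluded_short_mv = sum(status == "excluded_short_mv"),
    included = sum(status == "included")
  )
  list(
    included = stays$stay_id[status == "included"],
    disposition = data.frame(stay_id = stays$stay_id, status = status,
                             mv_onset_h = onset, stringsAsFactors = FALSE),
    counts = counts
  )
}

#' Observation-window summary statistics for one signal
#'
#' Five statistics (mean, median, min, max, sd) over samples falling in
#' `[start, start + duration_h)`. No samples gives five missing values; a
#' single sample gives sd missing and the other four equal to the value.
#'
#' @param times,values sample times (hours) and values.
#' @param start window start (MV onset), hours.
#' @param duration_h window length, hours (default 24).
#' @return named numeric vector `c(mean, median, min, max, sd)`.
#' @export
aggregate_window <- function(times, values, start, duration_h = 24) {
  keep <- times >= start & times < start + duration_h & is.finite(values)
  v <- values[keep]
  if (length(v) == 0L) {
    return(c(mean = NA_real_, median = NA_real_, min = NA_real_,
             max = NA_real_, sd = NA_real_))
  }
  c(mean = mean(v), median = median(v), min = min(v), max = max(v),
    sd = if (length(v) > 1L) sd(v) else NA_real_)
}

# Step-function (LOCF) value pieces of a signal over [start, end).
# The carried value at time t is the most recent sample at or before t
# (samples before the window start seed the initial value); before any
# sample the signal is undefined and contributes no pieces.
.locf_pieces <- function(times, values, start, end) {
  o <- order(times)
  times <- times[o]; values <- values[o]
  pieces <- data.frame(from = numeric(0), to = numeric(0), value = numeric(0))
  prior <- which(times <= start)
  t0 <- if (length(prior)) start else if (any(times < end)) min(times[times >= start]) else return(pieces)
  cur <- if (length(prior)) values[max(prior)] else NA_real_
  bounds <- sort(unique(c(t0, times[times > t0 & times < end], end)))
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    at <- which(times <= a)
    cur <- if (length(at)) values[max(at)] else NA_real_
    if (!is.na(cur)) {
      pieces <- rbind(pieces, data.frame(from = a, to = b, value = cur))
    }
  }
  pieces
}

#' ARDS criteria flag over the observation window
#'
#' Returns 1 when a PaO2/FiO2 ratio of 300 or less together with PEEP of
#' 5 cmH2O or higher is sustained for at least `min_span_h` consecutive
#' hours inside the window, under last-observation-carried-forward
#' step-function interpolation. Thresholds are closed (ratio exactly 300
#' and PEEP exactly 5 qualify) and a span of exactly `min_span_h` hours
#' qualifies.
#'
#' @param pf data.frame with `time_h`, `value` for the PaO2/FiO2 ratio.
#' @param peep data.frame with `time_h`, `value` for PEEP.
#' @param start window start (MV onset), hours.
#' @param duration_h window length (default 24).
#' @param min_span_h required sustained span (default 8).
#' @return 1, 0, or `NA` when either series has no samples.
#' @export
ards_flag <- function(pf, peep, start, duration_h = 24, min_span_h = 8) {
  if (nrow(pf) == 0L || nrow(peep) == 0L) return(NA_real_)
  end <- start + duration_h
  p1 <- .locf_pieces(pf$time_h, pf$value, start, end)
  p2 <- .locf_pieces(peep$time_h, peep$value, start, end)
  if (nrow(p1) == 0L || nrow(p2) == 0L) return(0)
  bounds <- sort(unique(c(p1$from, p1$to, p2$from, p2$to)))
  run <- 0
  best <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    v1 <- p1$value[p1$from <= a & p1$to >= b]
    v2 <- p2$value[p2$from <= a & p2$to >= b]
    ok <- length(v1) == 1L && length(v2) == 1L && v1 <= 300 && v2 >= 5
    if (ok) run <- run + (b - a) else run <- 0
    best <- max(best, run)
  }
  as.numeric(best >= min_span_h)
}

#' Organ-dysfunction criteria flag
#'
#' 1 when platelet count falls below 100 x 10^9/L, lactate exceeds
#' 2 mmol/L, or INR exceeds 1.5 (strict inequalities), as a disjunction
#' over whichever inputs are available; all inputs missing gives `NA`.
#'
#' @param platelet_min window minimum platelet count (10^9/L).
#' @param lactate_max window maximum lactate (mmol/L).
#' @param inr_max window maximum INR.
#' @return 1, 0, or `NA`.
#' @export
organ_dysfunction_flag <- function(platelet_min, lactate_max, inr_max) {
  checks <- c(
    if (!is.na(platelet_min)) platelet_min < 100,
    if (!is.na(lactate_max)) lactate_max > 2,
    if (!is.na(inr_max)) inr_max > 1.5
  )
  if (length(checks) == 0L) return(NA_real_)
  as.numeric(any(checks))
}

#' Race-free CKD-EPI (2021) estimated glomerular filtration rate
#'
#' eGFR = 142 x min(Scr/kappa, 1)^alpha x max(Scr/kappa, 1)^-1.200
#' x 0.9938^age x 1.012 (if female), with kappa 0.7 (female) / 0.9 (male)
#' and alpha -0.241 (female) / -0.302 (male). Creatinine may be supplied in
#' mg/dL (default) or umol/L (divided by 88.42).
#'
#' @param creatinine serum creatinine (> 0).
#' @param age age in years (>= 18).
#' @param sex `"female"` or `"male"`.
#' @param units `"mg_dl"` (default) or `"umol_l"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(creatinine, age, sex, units = c("mg_dl", "umol_l")) {
  units <- match.arg(units)
  if (any(!is.na(creatinine) & creatinine <= 0)) {
    stop("creatinine must be positive", call. = FALSE)
  }
  scr <- if (units == "umol_l") creatinine / 88.42 else creatinine
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.200) *
    0.9938^age * ifelse(female, 1.012, 1)
}

#' BMI category
#'
#' Six left-closed, right-open bins at 18.5 / 25 / 30 / 35 / 40 kg/m^2:
#' 0 underweight, 1 normal, 2 overweight, 3 stage 1 obesity,
#' 4 stage 2 obesity, 5 morbid obesity.
#'
#' @param bmi body-mass index (> 0), kg/m^2.
#' @return integer category 0-5 (`NA` passes through).
#' @export
bmi_category <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  cuts <- c(0, 18.5, 25, 30, 35, 40, Inf)
  as.integer(cut(bmi, cuts, right = FALSE, labels = FALSE)) - 1L
}

#' Seven-day mortality outcome label
#'
#' 1 when death occurred in the ICU (death time at or before discharge)
#' within `horizon_days` days after MV onset.
#'
#' @param death_h death time in hours from admission (`NA` for survivors).
#' @param discharge_h ICU discharge time in hours from admission.
#' @param mv_onset_h MV onset in hours from admission.
#' @param horizon_days outcome horizon (default 7).
#' @return 0 or 1.
#' @export
outcome_label <- function(death_h, discharge_h, mv_onset_h, horizon_days = 7) {
  as.numeric(!is.na(death_h) &
               death_h <= discharge_h &
               death_h - mv_onset_h <= horizon_days * HOURS_PER_DAY)
}

#' Build the per-stay feature table from raw time series
#'
#' Applies the cohort criteria, aggregates every signal over the 24-hour
#' observation window anchored at MV onset (mean/median/min/max/sd),
#' derives the criteria-based flags, eGFR from window-mean creatinine, BMI
#' category, demographic and comorbidity columns, and the 7-day outcome
#' label. Missing values are kept explicit (`NA`); the boosted-tree layer
#' consumes them natively, so no imputation is performed.
#'
#' @param stays stay metadata: `stay_id`, `age`, `sex`, optional
#'   `height_cm`, `weight_kg`, `discharge_h`, `death_h`, and any number of
#'   binary comorbidity columns prefixed `com_`.
#' @param signals long-format signals: `stay_id`, `signal`, `time_h`,
#'   `value`.
#' @param duration_h observation-window length in hours.
#' @param creatinine_units units of the creatinine signal for eGFR
#'   (`"mg_dl"` or `"umol_l"`).
#' @param vent_signals passed to [apply_cohort_criteria()].
#' @return list of class `feature_table`: `features` (data.frame, one row
#'   per included stay), `outcome` (0/1 vector), `stay_ids`, `consort`
#'   (criteria counts), `manifest` (data.frame mapping columns to source
#'   signal, statistic and units).
#' @export
build_feature_table <- function(stays, signals, duration_h = 24,
                                creatinine_units = "mg_dl",
                                vent_signals = "peep") {
  crit <- apply_cohort_criteria(stays, signals, vent_signals = vent_signals)
  keep <- crit$disposition$status == "included"
  ids <- crit$disposition$stay_id[keep]
  onsets <- crit$disposition$mv_onset_h[keep]
  st <- stays[match(ids, stays$stay_id), , drop = FALSE]

  signal_names <- sort(setdiff(unique(signals$signal), character(0)))
  stats_names <- c("mean", "median", "min", "max", "sd")
  sig_split <- split(signals, signals$stay_id)

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sig <- sig_split[[as.character(ids[i])]]
    start <- onsets[i]
    agg <- lapply(signal_names, function(sn) {
      s <- sig[sig$signal == sn, , drop = FALSE]
      aggregate_window(s$time_h, s$value, start, duration_h)
    })
    names(agg) <- signal_names
    row <- unlist(agg)  # names like "peep.mean"
    names(row) <- gsub("\\.", "_", names(row))

    pf <- sig[sig$signal == "pf_ratio", , drop = FALSE]
    pe <- sig[sig$signal == "peep", , drop = FALSE]
    row["ards_flag"] <- ards_flag(pf, pe, start, duration_h)
    row["organ_dysfunction_flag"] <- organ_dysfunction_flag(
      platelet_min = row["platelet_min"] %|na|% NA_real_,
      lactate_max = row["lactate_max"] %|na|% NA_real_,
      inr_max = row["inr_max"] %|na|% NA_real_
    )
    cr <- row["creatinine_mean"] %|na|% NA_real_
    row["egfr"] <- if (!is.na(cr) && cr > 0) {
      egfr_ckdepi(cr, st$age[i], st$sex[i], units = creatinine_units)
    } else NA_real_
    bun <- row["bun_mean"] %|na|% NA_real_
    alb <- row["albumin_mean"] %|na|% NA_real_
    row["bun_albumin_ratio"] <- if (!is.na(bun) && !is.na(alb) && alb != 0) bun / alb else NA_real_
    row["bun_creatinine_ratio"] <- if (!is.na(bun) && !is.na(cr) && cr != 0) bun / cr else NA_real_
    rows[[i]] <- row
  }
  feat <- as.data.frame(do.call(rbind, rows))

  feat$age <- st$age
  feat$sex_male <- as.numeric(st$sex == "male")
  if (all(c("height_cm", "weight_kg") %in% names(st))) {
    bmi <- st$weight_kg / (st$height_cm / 100)^2
    feat$bmi_category <- bmi_category(bmi)
  }
  for (cc in grep("^com_", names(st), value = TRUE)) {
    feat[[cc]] <- as.numeric(st[[cc]])
  }
  # drop columns that are entirely missing (signal never observed in window)
  feat <- feat[, colSums(!is.na(feat)) > 0, drop = FALSE]

  discharge <- if ("discharge_h" %in% names(st)) st$discharge_h else rep(Inf, nrow(st))
  death <- if ("death_h" %in% names(st)) st$death_h else rep(NA_real_, nrow(st))
  outcome <- outcome_label(death, discharge, onsets)

  manifest <- data.frame(
    column = names(feat),
    source = sub("_(mean|median|min|max|sd)$", "", names(feat)),
    statistic = ifelse(grepl("_(mean|median|min|max|sd)$", names(feat)),
                       sub("^.*_(mean|median|min|max|sd)$", "\\1", names(feat)),
                       "derived"),
    stringsAsFactors = FALSE
  )

  structure(list(features = feat, outcome = outcome, stay_ids = ids,
                 consort = crit$counts, manifest = manifest),
            class = "feature_table")
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Write a feature table, manifest and consort counts to disk
#'
#' @param ft a `feature_table`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_feature_table <- function(ft, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- cbind(stay_id = ft$stay_ids, ft$features, outcome = ft$outcome)
  write.csv(df, file.path(dir, "feature_table.csv"), row.names = FALSE)
  jsonlite::write_json(ft$manifest, file.path(dir, "column_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(ft$consort, file.path(dir, "consort_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
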