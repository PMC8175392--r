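#' Choi non-wear detection on minute-epoch counts
#'
#' Flags each minute of a single day's activity-count vector as worn or not
#' worn. A minute is non-wear when it lies inside a run of at least `window`
#' consecutive zero-count minutes; short artifactual spikes (runs of at most
#' `spike_tolerance` consecutive nonzero minutes) are absorbed into the zero
#' run provided they are flanked by at least `flank` consecutive zero minutes
#' on both sides. Spike minutes absorbed this way are themselves non-wear.
#'
#' @param counts Nonnegative integer vector of per-minute activity counts
#'   (counts per minute) for one day (length at most 1440).
#' @param window Minimum length, in minutes, of a zero run (including absorbed
#'   spikes) for it to be classified as non-wear. Default 90.
#' @param spike_tolerance Maximum length of a nonzero spike that can be
#'   absorbed into a surrounding zero run. Default 2.
#' @param flank Minimum number of consecutive zero minutes required on each
#'   side of a spike for it to be absorbed. Default 30.
#' @return Logical vector the same length as `counts`; `TRUE` = worn.
#' @examples
#' choi_wear_mask(c(rep(0, 120), rep(500, 60)))[1:5]
#' @export
choi_wear_mask <- function(counts, window = 90, spike_tolerance = 2,
                           flank = 30) {
  if (length(counts) == 0L) return(logical(0))
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be nonnegative and non-missing", call. = FALSE)
  }
  r <- rle(counts == 0)
  nruns <- length(r$lengths)
  is_zero <- r$values
  # a nonzero run is bridgeable when short enough and flanked by long zero runs
  bridge <- rep(FALSE, nruns)
  if (nruns >= 3L) {
    for (i in seq(2L, nruns - 1L)) {
      if (!is_zero[i] && r$lengths[i] <= spike_tolerance &&
          is_zero[i - 1L] && r$lengths[i - 1L] >= flank &&
          is_zero[i + 1L] && r$lengths[i + 1L] >= flank) {
        bridge[i] <- TRUE
      }
    }
  }
  candidate <- is_zero | bridge
  # group consecutive candidate runs into spans; span length counts all minutes
  span <- rle(candidate)
  wear <- rep(TRUE, length(counts))
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  idx <- 1L
  for (j in seq_along(span$lengths)) {
    runs_j <- seq(idx, idx + span$lengths[j] - 1L)
    idx <- idx + span$lengths[j]
    if (!span$values[j]) next
    total <- sum(r$lengths[runs_j])
    if (total >= window) {
      wear[run_starts[runs_j[1L]]:run_ends[runs_j[length(runs_j)]]] <- FALSE
    }
  }
  wear
}

#' Extract sitting bouts from posture labels
#'
#' A sitting bout is a maximal run of consecutive minutes labelled `"sit"`
#' during wear time, with no minimum duration and no tolerance: any non-sit
#' minute or non-wear minute terminates the bout. Bouts never bridge across
#' non-wear gaps.
#'
#' @param posture Character vector of per-minute posture labels, one of
#'   `"sit"`, `"stand"`, `"move"`, `"walk"`.
#' @param wear Logical wear mask of the same length (default: all worn).
#' @return Integer vector of bout durations in minutes (possibly empty).
#' @examples
#' sitting_bouts(c(rep("sit", 10), "stand", rep("sit", 5)))
#' @export
sitting_bouts <- function(posture, wear = rep(TRUE, length(posture))) {
  if (length(posture) != length(wear)) {
    stop("`posture` and `wear` must have equal length", call. = FALSE)
  }
  if (length(posture) == 0L) return(integer(0))
  sit <- posture == "sit" & wear
  r <- rle(sit)
  as.integer(r$lengths[r$values])
}

#' Moderate-to-vigorous physical activity minutes
#'
#' Counts wear minutes at or above the MVPA count threshold. The boundary is
#' inclusive: a minute at exactly `cutpoint` counts per minute is MVPA.
#'
#' @param counts Nonnegative per-minute activity counts.
#' @param wear Logical wear mask (default: all worn).
#' @param cutpoint MVPA threshold in counts per minute. Default 1952.
#' @return Number of MVPA minutes.
#' @export
mvpa_minutes <- function(counts, wear = rep(TRUE, length(counts)),
                         cutpoint = 1952) {
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be nonnegative and non-missing", call. = FALSE)
  }
  if (length(counts) != length(wear)) {
    stop("`counts` and `wear` must have equal length", call. = FALSE)
  }
  sum(counts >= cutpoint & wear)
}

#' Summarize minute-epoch records into per-participant activity metrics
#'
#' Computes, per participant, daily-mean total sitting time, mean sitting bout
#' duration, MVPA and walking minutes, wear days and mean wear time, using only
#' adherent days (days with at least `min_wear` worn minutes). Participants
#' with fewer than `min_days` adherent days are flagged non-adherent and their
#' summary metrics set to `NA`.
#'
#' Mean sitting bout duration defaults to the arithmetic mean of all bout
#' durations pooled across adherent days (`bout_mean = "pooled"`); the
#' per-day-then-averaged variant is available as `bout_mean = "daily"`.
#'
#' @param epochs Data frame of minute epochs with columns `participant_id`,
#'   `day_index`, `minute_index`, `counts`, `posture`.
#' @param min_wear Minimum worn minutes for a day to be adherent. Default 600
#'   (10 h).
#' @param min_days Minimum adherent days for a participant to be adherent.
#'   Default 4.
#' @param bout_mean `"pooled"` (default) or `"daily"`; see Details.
#' @param mvpa_cutpoint MVPA threshold in counts per minute. Default 1952.
#' @param choi Named list of Choi parameters (`window`, `spike_tolerance`,
#'   `flank`) passed to [choi_wear_mask()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `total_sitting`, `mean_sitting_bout`, `mvpa`, `walking`, `wear_days`,
#'   `mean_wear_time`, `adherent`.
#' @seealso [choi_wear_mask()], [sitting_bouts()], [mvpa_minutes()]
#' @export
summarize_activity <- function(epochs, min_wear = 600, min_days = 4,
                               bout_mean = c("pooled", "daily"),
                               mvpa_cutpoint = 1952, choi = list()) {
  bout_mean <- match.arg(bout_mean)
  need <- c("participant_id", "day_index", "counts", "posture")
  missing_cols <- setdiff(need, names(epochs))
  if (length(missing_cols)) {
    stop("`epochs` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  choi_args <- utils::modifyList(
    list(window = 90, spike_tolerance = 2, flank = 30), choi)

  ids <- unique(epochs$participant_id)
  pid_i <- match(epochs$participant_id, ids)
  # order rows so each participant-day is one contiguous block, then scan
  o <- order(pid_i, epochs$day_index, epochs$minute_index, method = "radix")
  day_mult <- max(epochs$day_index) + 1
  key <- pid_i[o] * day_mult + epochs$day_index[o]
  nr <- length(key)
  starts <- which(c(TRUE, key[-1L] != key[-nr]))
  ends <- c(starts[-1L] - 1L, nr)
  counts_o <- epochs$counts[o]
  sit_o <- epochs$posture[o] == "sit"
  walk_o <- epochs$posture[o] == "walk"
  if (anyNA(counts_o) || any(counts_o < 0)) {
    stop("`counts` must be nonnegative and non-missing", call. = FALSE)
  }

  per_day <- lapply(seq_along(starts), function(k) {
    ix <- starts[k]:ends[k]
    counts <- counts_o[ix]
    wear <- choi_wear_mask(counts, window = choi_args$window,
                           spike_tolerance = choi_args$spike_tolerance,
                           flank = choi_args$flank)
    sit <- sit_o[ix] & wear
    r <- rle(sit)
    list(id = ids[key[starts[k]] %/% day_mult],
         wear_min = sum(wear),
         sit_min = sum(sit),
         mvpa = sum(counts >= mvpa_cutpoint & wear),
         walking = sum(walk_o[ix] & wear),
         bouts = as.integer(r$lengths[r$values]))
  })

  pid_day <- key[starts] %/% day_mult
  out <- lapply(seq_along(ids), function(p) {
    id <- ids[p]
    days <- per_day[pid_day == p]
    wear_min <- vapply(days, `[[`, numeric(1), "wear_min")
    adh <- wear_min >= min_wear
    n_adh <- sum(adh)
    if (n_adh < min_days) {
      return(data.frame(participant_id = id, total_sitting = NA_real_,
                        mean_sitting_bout = NA_real_, mvpa = NA_real_,
                        walking = NA_real_, wear_days = n_adh,
                        mean_wear_time = if (n_adh) mean(wear_min[adh]) else NA_real_,
                        adherent = FALSE))
    }
    days <- days[adh]
    bouts <- unlist(lapply(days, `[[`, "bouts"), use.names = FALSE)
    mb <- if (bout_mean == "pooled") {
      if (length(bouts)) mean(bouts) else 0
    } else {
      daily <- vapply(days, function(d) {
        if (length(d$bouts)) mean(d$bouts) else NA_real_
      }, numeric(1))
      if (all(is.na(daily))) 0 else mean(daily, na.rm = TRUE)
    }
    data.frame(participant_id = id,
               total_sitting = mean(vapply(days, `[[`, numeric(1), "sit_min")),
               mean_sitting_bout = mb,
               mvpa = mean(vapply(days, `[[`, numeric(1), "mvpa")),
               walking = mean(vapply(days, `[[`, numeric(1), "walking")),
               wear_days = n_adh,
               mean_wear_time = mean(wear_min[adh]),
               adherent = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
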