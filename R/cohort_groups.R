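#' Quartile cut values
#'
#' 25th, 50th and 75th percentiles with linear interpolation between order
#' statistics (type 7 quantiles).
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Named numeric vector `c(q1, q2, q3)`.
#' @export
quartile_thresholds <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L) {
    stop("need at least 4 finite values to form quartiles", call. = FALSE)
  }
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], q2 = q[2], q3 = q[3])
}

#' Assign quartile memberships
#'
#' Values at or below the first cut are quartile 1, values in `(q1, q2]`
#' quartile 2, and so on; ties always go to the lower quartile. With a fully
#' degenerate vector (all values equal) every value lands in quartile 1.
#'
#' @param values Numeric vector.
#' @param thresholds Optional cut values as returned by
#'   [quartile_thresholds()]; computed from `values` when omitted.
#' @return Integer vector of quartile indices 1-4 (`NA` for non-finite input).
#' @export
assign_quartiles <- function(values, thresholds = quartile_thresholds(values)) {
  q <- as.numeric(thresholds)
  out <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  out[!is.finite(values)] <- NA_integer_
  as.integer(out)
}

#' Classify Interrupted Sitters and Super Sitters
#'
#' Cross-tabulates cohort-wide quartiles of mean sitting bout duration and of
#' MVPA. Interrupted Sitters (IS) occupy the shortest-bout, lowest-MVPA cell
#' (bout Q1 and MVPA Q1); Super Sitters (SS) the longest-bout, lowest-MVPA
#' cell (bout Q4 and MVPA Q1). Everyone else is `"none"`. Quartiles are
#' computed on the full adherent cohort; non-adherent participants are dropped.
#'
#' @param summaries Activity summary data frame from [summarize_activity()].
#' @return Data frame with `participant_id`, `group` (`"IS"`, `"SS"`,
#'   `"none"`), `bout_quartile`, `mvpa_quartile`.
#' @export
classify_groups <- function(summaries) {
  s <- summaries[summaries$adherent, , drop = FALSE]
  if (nrow(s) < 8L) {
    stop("need at least 8 adherent participants to classify sitter groups",
         call. = FALSE)
  }
  bq <- assign_quartiles(s$mean_sitting_bout)
  mq <- assign_quartiles(s$mvpa)
  group <- rep("none", nrow(s))
  group[bq == 1L & mq == 1L] <- "IS"
  group[bq == 4L & mq == 1L] <- "SS"
  data.frame(participant_id = s$participant_id, group = group,
             bout_quartile = bq, mvpa_quartile = mq,
             stringsAsFactors = FALSE)
}

#' Augment sitter groups with Hispanic women from the second MVPA quartile
#'
#' Forms the amended groups IS+ and SS+: IS+ is the union of IS with
#' Hispanic participants in MVPA quartile 2 and bout quartile 1; SS+ the union
#' of SS with Hispanic participants in MVPA quartile 2 and bout quartile 4.
#' Participants with a missing ethnicity indicator are skipped with a warning.
#'
#' @param assignments Group assignment data frame from [classify_groups()].
#' @param covariates Data frame with `participant_id` and logical/0-1
#'   `hispanic` column.
#' @return `assignments` with an added `group_plus` column (`"IS+"`, `"SS+"`,
#'   `"none"`).
#' @export
augment_hispanic <- function(assignments, covariates) {
  if (!"hispanic" %in% names(covariates)) {
    stop("`covariates` lacks a `hispanic` column", call. = FALSE)
  }
  hisp <- covariates$hispanic[match(assignments$participant_id,
                                    covariates$participant_id)]
  if (anyNA(hisp)) {
    warning(sum(is.na(hisp)),
            " participant(s) with missing ethnicity skipped in augmentation")
  }
  hisp_true <- !is.na(hisp) & hisp != 0
  gp <- rep("none", nrow(assignments))
  gp[assignments$group == "IS" |
       (hisp_true & assignments$mvpa_quartile == 2L &
          assignments$bout_quartile == 1L)] <- "IS+"
  gp[assignments$group == "SS" |
       (hisp_true & assignments$mvpa_quartile == 2L &
          assignments$bout_quartile == 4L)] <- "SS+"
  assignments$group_plus <- gp
  assignments
}

#' Plan RNA pools within a sitter group
#'
#' Partitions group members into pools of 3, drawing one member per parent
#' study where possible and filling remaining slots at random. When the group
#' size is not divisible by 3, one remainder pool is formed: a pool of 2 when
#' `size %% 3 == 2`; when `size %% 3 == 1` either one pool of 4 (default,
#' minimizes pool-count distortion) or two pools of 2 (`remainder = "pairs"`).
#'
#' @param ids Participant identifiers of the group members.
#' @param parent_study Parent-study label per member, same length as `ids`.
#' @param group Group label recorded on each pool.
#' @param seed Integer seed controlling the random fill.
#' @param remainder `"quad"` (one pool of 4) or `"pairs"` (two pools of 2)
#'   when the group size is 1 mod 3.
#' @return Data frame with one row per pooled member: `pool_id`, `group`,
#'   `participant_id`, `parent_study`.
#' @export
make_pools <- function(ids, parent_study, group = "group", seed = 1L,
                       remainder = c("quad", "pairs")) {
  remainder <- match.arg(remainder)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 members to pool", call. = FALSE)
  if (length(parent_study) != n) {
    stop("`parent_study` must match `ids` in length", call. = FALSE)
  }
  sizes <- rep(3L, n %/% 3L)
  if (n %% 3L == 2L) sizes <- c(sizes, 2L)
  if (n %% 3L == 1L) {
    if (remainder == "quad") {
      sizes[length(sizes)] <- 4L
    } else {
      sizes <- c(sizes[-length(sizes)], 2L, 2L)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  remaining <- seq_len(n)
  rows <- vector("list", length(sizes))
  for (p in seq_along(sizes)) {
    take <- integer(0)
    for (slot in seq_len(sizes[p])) {
      pool_studies <- parent_study[take]
      cand <- remaining[!(parent_study[remaining] %in% pool_studies)]
      if (!length(cand)) cand <- remaining
      # favour the study with most remaining members to keep later pools mixed
      tab <- table(parent_study[cand])
      best <- names(tab)[tab == max(tab)]
      cand <- cand[parent_study[cand] %in% best]
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      take <- c(take, pick)
      remaining <- setdiff(remaining, pick)
    }
    rows[[p]] <- data.frame(pool_id = sprintf("%s_pool_%02d", group, p),
                            group = group,
                            participant_id = ids[take],
                            parent_study = parent_study[take],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
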