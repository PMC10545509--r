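#' Score one trial at digit level
#'
#' Positional comparison of a response against a three-digit target: one
#' point per position (hundreds, tens, units) where the response digit
#' equals the target digit (target "587", response "585" scores 2).
#' Partial responses are left-aligned to the hundreds position — a
#' two-digit response is taken as hundreds + tens — and missing positions
#' score 0. Transpositions are scored strictly by position ("578" for
#' "587" scores 1).
#'
#' @param target Three-digit string.
#' @param response Digit string of length 0..3 (may be empty or partial).
#' @return Integer count of digits correct, 0..3.
#' @export
score_trial <- function(target, response) {
  if (!grepl("^[0-9]{3}$", target))
    stop("`target` must be exactly three digits", call. = FALSE)
  if (is.na(response)) response <- ""
  if (!grepl("^[0-9]{0,3}$", response))
    stop("`response` must be 0-3 digit characters (got \"", response,
         "\"): transcription error", call. = FALSE)
  if (nchar(response) == 0L) return(0L)
  tg <- strsplit(target, "")[[1]]
  rs <- strsplit(response, "")[[1]]
  m <- seq_along(rs)
  sum(tg[m] == rs)
}

#' Aggregate trials to per-level counts on the log2-channel axis
#'
#' Collapses one participant's trial table to per-level success counts for
#' psychometric fitting: at each vocoded level, `k` = total digits correct
#' and `n` = 3 x number of trials (12 under the standard 4-trials-per-level
#' design), with the stimulus axis `x = log2(channels)` (the perceptual
#' effect of adding channels is roughly logarithmic). Clear-speech trials
#' are summarized separately and never enter the fit: the channel axis is
#' undefined for unprocessed speech.
#'
#' @param trials A `trial_table` data frame (see [simulate_listener()]).
#' @param participant Optional participant id to filter on; required if
#'   `trials` holds several participants.
#' @return An object of class `psychometric_data`: a list with `data` (data
#'   frame `level`, `x`, `k`, `n`, one row per vocoded level, ascending),
#'   `clear_k`, `clear_n` and `participant`.
#' @export
aggregate_trials <- function(trials, participant = NULL) {
  stopifnot(is.data.frame(trials))
  if (!is.null(participant))
    trials <- trials[trials$participant_id == participant, , drop = FALSE]
  else if (length(unique(trials$participant_id)) > 1L)
    stop("several participants present: supply `participant`", call. = FALSE)
  voc <- trials[trials$level != "clear", , drop = FALSE]
  if (nrow(voc) == 0L)
    stop("participant has no vocoded trials", call. = FALSE)
  lev <- as.numeric(voc$level)
  if (length(unique(lev)) < 2L)
    stop("need trials at >= 2 distinct vocoded levels", call. = FALSE)
  agg <- stats::aggregate(cbind(k = voc$digits_correct,
                                n_trials = rep(1L, nrow(voc))),
                          by = list(level = lev), FUN = sum)
  agg <- agg[order(agg$level), ]
  clear <- trials[trials$level == "clear", , drop = FALSE]
  structure(list(
    data = data.frame(level = agg$level, x = log2(agg$level),
                      k = agg$k, n = 3L * agg$n_trials),
    clear_k = sum(clear$digits_correct),
    clear_n = 3L * nrow(clear),
    participant = if (is.null(participant))
      unique(trials$participant_id) else participant),
    class = "psychometric_data")
}

#' @export
print.psychometric_data <- function(x, ...) {
  cat(sprintf("<psychometric_data: %s, %d levels, clear %d/%d>\n",
              x$participant, nrow(x$data), x$clear_k, x$clear_n))
  print(utils::head(x$data, 4))
  if (nrow(x$data) > 4) cat("...\n")
  invisible(x)
}
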