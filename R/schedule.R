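# Event schedules for the event-related design: 12 runs over 2 sessions,
# 20 stimuli per run (10 possible, 10 impossible) repeated 3 times, plus 3
# target and 3 blank trials per run; inter-stimulus intervals of 2, 3 or 4
# TRs. Sessions share run content, so each stimulus appears 6 times.

#' Default stimulus identifier pool
#'
#' @param n_possible,n_impossible Class sizes (default 60 + 60).
#' @return Data.frame with columns `stimulus_id`, `plausibility`.
#' @export
stimulus_pool <- function(n_possible = 60, n_impossible = 60) {
  data.frame(
    stimulus_id = c(sprintf("pos_%02d", seq_len(n_possible)),
                    sprintf("imp_%02d", seq_len(n_impossible))),
    plausibility = rep(c("possible", "impossible"),
                       c(n_possible, n_impossible)),
    stringsAsFactors = FALSE
  )
}

#' Build an event schedule
#'
#' The pool is partitioned into `n_runs / sessions` run-sets of
#' `stimuli_per_run` stimuli (balanced between possible and impossible);
#' the second session repeats the first session's run content with a fresh
#' trial order. Each run presents every stimulus `reps` times interleaved
#' with target trials, plus blank trials, with onsets on the TR grid and
#' inter-stimulus intervals drawn from {2, 3, 4} TRs.
#'
#' @param pool Data.frame from [stimulus_pool()].
#' @param n_runs Total runs, default 12.
#' @param sessions Number of sessions sharing run content, default 2.
#' @param stimuli_per_run Unique stimuli per run, default 20.
#' @param reps Presentations of each stimulus within a run, default 3.
#' @param n_targets,n_blanks Target and blank trials per run, default 3 each.
#' @param tr_s Repetition time in seconds, default 2.3.
#' @param stim_tr TRs occupied by the stimulus itself, default 1.
#' @param lead_tr Silent TRs before the first trial and after the last.
#' @param seed Integer seed.
#' @return Data.frame of class `event_table` with columns `run`, `session`,
#'   `onset_s` (alias `onset`), `duration_s`, `stimulus_id`, `trial_type`
#'   (stimulus/target/blank) and attribute `n_tr` (TRs per run).
#' @export
make_event_schedule <- function(pool = stimulus_pool(), n_runs = 12,
                                sessions = 2, stimuli_per_run = 20,
                                reps = 3, n_targets = 3, n_blanks = 3,
                                tr_s = 2.3, stim_tr = 1, lead_tr = 4,
                                seed = 1) {
  runs_per_session <- n_runs / sessions
  if (runs_per_session != round(runs_per_session)) {
    stop("n_runs must be divisible by sessions")
  }
  classes <- split(pool$stimulus_id, pool$plausibility)
  per_class <- stimuli_per_run / length(classes)
  if (any(vapply(classes, length, 1L) != per_class * runs_per_session)) {
    stop("stimulus pool cannot be partitioned into balanced run-sets")
  }
  with_seed(seed, {
    run_sets <- lapply(seq_len(runs_per_session), function(r) {
      unlist(lapply(classes, function(ids) {
        ids[((r - 1) * per_class + 1):(r * per_class)]
      }), use.names = FALSE)
    })
    ev <- list()
    max_tr <- 0
    for (run in seq_len(n_runs)) {
      set_idx <- ((run - 1) %% runs_per_session) + 1
      ids <- c(rep(run_sets[[set_idx]], reps),
               rep("target", n_targets), rep(NA_character_, n_blanks))
      type <- c(rep("stimulus", stimuli_per_run * reps),
                rep("target", n_targets), rep("blank", n_blanks))
      ord <- sample(length(ids))
      ids <- ids[ord]; type <- type[ord]
      isi <- sample(2:4, length(ids), replace = TRUE)
      onset_tr <- lead_tr + c(0, cumsum(stim_tr + isi[-length(isi)]))
      ev[[run]] <- data.frame(
        run = run,
        session = ((run - 1) %/% runs_per_session) + 1,
        onset_s = onset_tr * tr_s,
        duration_s = ifelse(type == "blank", isi * tr_s, stim_tr * tr_s),
        stimulus_id = ids,
        trial_type = type,
        stringsAsFactors = FALSE
      )
      max_tr <- max(max_tr, onset_tr[length(onset_tr)] + stim_tr + 8)
    }
    out <- do.call(rbind, ev)
    attr(out, "tr_s") <- tr_s
    attr(out, "n_tr") <- max_tr + lead_tr
    class(out) <- c("event_table", "data.frame")
    out
  })
}
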