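# Readers and writers: BIDS-dialect event TSVs, feature-matrix TSVs and
# time-series TSVs. Everything round-trips losslessly at full double
# precision (values are serialized with 17 significant digits).

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("malformed file %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
}

#' Write / read an event table (BIDS events dialect)
#'
#' Columns `onset`, `duration`, `trial_type`, `stimulus_id`, `run`,
#' `session`; TR and run length are stored in a JSON sidecar.
#'
#' @param events An `event_table`.
#' @param path Output TSV path.
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset = events$onset_s, duration = events$duration_s,
                   trial_type = events$trial_type,
                   stimulus_id = events$stimulus_id,
                   run = events$run, session = events$session)
  .write_tsv(df, path)
  jsonlite::write_json(list(tr_s = attr(events, "tr_s"),
                            n_tr = attr(events, "n_tr")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("onset", "duration", "trial_type", "run"), path)
  out <- data.frame(run = df$run,
                    session = df$session %||% rep(1L, nrow(df)),
                    onset_s = df$onset, duration_s = df$duration,
                    stimulus_id = df$stimulus_id,
                    trial_type = df$trial_type,
                    stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(out, "tr_s") <- meta$tr_s
    attr(out, "n_tr") <- meta$n_tr
  }
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write / read a feature space as TSV
#'
#' First column `stimulus_id`, remaining columns the named features.
#'
#' @param fs A `feature_space`.
#' @param path Output TSV path.
#' @export
write_features <- function(fs, path) {
  df <- data.frame(stimulus_id = fs$stimulus_ids, fs$X,
                   check.names = FALSE)
  .write_tsv(df, path)
  jsonlite::write_json(list(name = fs$name), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @param name Feature-space label (read back from the sidecar if
#'   present).
#' @export
read_features <- function(path, name = NULL) {
  df <- .read_tsv(path)
  .require_columns(df, "stimulus_id", path)
  side <- paste0(path, ".json")
  if (is.null(name)) {
    name <- if (file.exists(side)) jsonlite::read_json(side)$name else "features"
  }
  X <- as.matrix(df[, setdiff(names(df), "stimulus_id"), drop = FALSE])
  feature_space(name, X, feature_names = colnames(X),
                stimulus_ids = df$stimulus_id)
}

#' Write / read voxel time series as TSV
#'
#' Columns `run`, `tr`, then one column per voxel.
#'
#' @param Y n_TR x voxels matrix with a `runs` attribute (or `runs`
#'   argument).
#' @param path Output TSV path.
#' @param runs Run label per row.
#' @export
write_timeseries <- function(Y, path, runs = attr(Y, "runs")) {
  runs <- runs %||% rep(1L, nrow(Y))
  colnames(Y) <- colnames(Y) %||% sprintf("v%04d", seq_len(ncol(Y)))
  df <- data.frame(run = runs,
                   tr = unlist(lapply(split(runs, runs), seq_along),
                               use.names = FALSE),
                   Y, check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("run", "tr"), path)
  Y <- as.matrix(df[, setdiff(names(df), c("run", "tr")), drop = FALSE])
  attr(Y, "runs") <- df$run
  Y
}
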