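# Readers for the study CSV schemas. Each checks required columns and
# returns a plain data frame; gait files are reassembled into
# `gait_recording` objects.

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s lacks column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  df
}

#' Read study input tables
#'
#' Thin readers for the CSV schemas produced by [gen_study()] (or supplied
#' by the user in the same layout).
#'
#' @param path File path.
#' @return A data frame with the schema-mandated columns.
#' @name study_readers
NULL

#' @rdname study_readers
#' @export
read_subjects <- function(path)
  read_checked(path, c("subject_id", "body_mass_kg", "self_selected_speed_mps",
                       "resting_rate_w"))

#' @rdname study_readers
#' @export
read_preference_log <- function(path)
  read_checked(path, c("subject_id", "speed_rel", "repetition",
                       "preferred_stiffness_nm_per_deg"))

#' @rdname study_readers
#' @export
read_breaths <- function(path)
  read_checked(path, c("subject_id", "speed_rel", "time_s", "power_w"))

#' @rdname study_readers
#' @export
read_trial_schedule <- function(path)
  read_checked(path, c("subject_id", "speed_rel", "trial_index",
                       "stiffness_rel", "start_s", "duration_s"))

#' @rdname study_readers
#' @export
read_tenmwt <- function(path)
  read_checked(path, c("subject_id", "stiffness_rel", "repetition",
                       "distance_m", "time_s", "device"))

#' @rdname study_readers
#' @export
read_descriptors <- function(path)
  read_checked(path, c("subject_id", "speed_rel", "stiffness_rel",
                       "descriptor_name", "value"))

#' Read a gait trial CSV into a gait recording
#'
#' Parses a `gait/<subject>_spd<s>_stf<d>.csv` file (column `time_s`, one
#' column per channel, optional `crossover` flags) into a `gait_recording`.
#' Subject metadata (body mass) is attached from the subjects table.
#'
#' @param path Gait CSV path.
#' @param subjects Data frame from [read_subjects()].
#' @return A `gait_recording`.
#' @export
read_gait_csv <- function(path, subjects) {
  df <- read_checked(path, c("time_s", "vgrf_aff", "vgrf_una"))
  m <- regmatches(basename(path),
                  regexec("^(.+)_spd(-?[0-9]+)_stf(-?[0-9]+)\\.csv$",
                          basename(path)))[[1]]
  if (length(m) != 4L)
    stop("gait file name not parseable: ", basename(path))
  id <- m[2]
  srow <- subjects[subjects$subject_id == id, , drop = FALSE]
  if (nrow(srow) != 1L) stop("subject not found in subjects table: ", id)
  fs <- 1 / stats::median(diff(df$time_s))
  crossover <- if ("crossover" %in% names(df)) df$crossover else integer(nrow(df))
  ch <- df[, setdiff(names(df), c("time_s", "crossover")), drop = FALSE]
  structure(list(sample_rate = fs, time_s = df$time_s,
                 channels = as.list(ch), crossover = crossover,
                 meta = list(subject_id = id,
                             speed_rel = as.numeric(m[3]) / 100,
                             stiffness_rel = as.numeric(m[4]),
                             body_mass = srow$body_mass_kg)),
            class = "gait_recording")
}
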