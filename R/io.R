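#' Write a simulated experiment to flat files
#'
#' Writes three plain-text files into `dir`: `<id>_frames.csv` (per-frame
#' tracking and stimulus), `<id>_bouts.csv` (the true bout table) and
#' `<id>_meta.json` (condition, rates, seed).
#'
#' @param experiment A `fish_experiment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- attr(experiment, "id") %||% "exp"
  paths <- file.path(dir, paste0(id, c("_frames.csv", "_bouts.csv", "_meta.json")))
  readr::write_csv(as.data.frame(experiment), paths[1])
  readr::write_csv(true_bouts(experiment), paths[2])
  meta <- list(
    id = id,
    condition = attr(experiment, "condition"),
    frame_rate = attr(experiment, "frame_rate"),
    bin_rate = attr(experiment, "bin_rate"),
    arena_radius_mm = attr(experiment, "arena_radius_mm"),
    seed = attr(experiment, "seed")
  )
  writeLines(to_json_chr(meta), paths[3])
  invisible(paths)
}

# tiny JSON writer for flat named lists (keeps jsonlite in Suggests)
to_json_chr <- function(x) {
  item <- function(v) {
    if (is.character(v)) sprintf("\"%s\"", v) else format(v, digits = 15)
  }
  paste0(
    "{", paste(sprintf("\"%s\": %s", names(x), vapply(x, item, "")),
      collapse = ", "
    ), "}"
  )
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir Directory containing the files.
#' @param id Experiment id used when writing.
#' @return A `fish_experiment` tibble with its bout table attached.
#' @export
read_experiment <- function(dir, id) {
  frames <- readr::read_csv(
    file.path(dir, paste0(id, "_frames.csv")),
    show_col_types = FALSE
  )
  bouts <- readr::read_csv(
    file.path(dir, paste0(id, "_bouts.csv")),
    show_col_types = FALSE
  )
  meta_txt <- paste(readLines(file.path(dir, paste0(id, "_meta.json"))), collapse = "")
  cond <- sub(".*\"condition\": \"([^\"]+)\".*", "\\1", meta_txt)
  fr <- as.numeric(sub(".*\"frame_rate\": ([0-9.]+).*", "\\1", meta_txt))
  br <- as.numeric(sub(".*\"bin_rate\": ([0-9.]+).*", "\\1", meta_txt))
  fpb <- fr / br
  n_bins <- floor(nrow(frames) / fpb)
  structure(
    frames,
    class = c("fish_experiment", class(frames)),
    condition = cond, id = id, frame_rate = fr, bin_rate = br,
    bouts = bouts,
    temp_bin = colMeans(matrix(frames$temp_c[seq_len(n_bins * fpb)], nrow = fpb))
  )
}

#' Write a bout table as CSV
#'
#' One row per bout with times in seconds: `start_s`, `end_s`,
#' `displacement_mm`, `turn_deg`, `ibi_s`.
#'
#' @param bouts Bout tibble with kinematics.
#' @param path Output path.
#' @param frame_rate Frames per second used to convert indices to seconds.
#' @export
write_bout_table <- function(bouts, path, frame_rate = 250) {
  out <- tibble::tibble(
    start_s = bouts$start_frame / frame_rate,
    end_s = bouts$end_frame / frame_rate,
    displacement_mm = bouts$displacement_mm %||% NA_real_,
    turn_deg = bouts$turn_deg %||% NA_real_,
    ibi_s = bouts$interbout_interval_s %||% NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}
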