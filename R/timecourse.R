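#' Residual-activity time course
#'
#' Container for thermal-stability observations of one enzyme at one
#' incubation temperature: residual activity (fraction of the activity at
#' t = 0) versus incubation time in minutes, possibly with replicates.
#' Observations are expected pre-normalised so that the curve starts at 1.
#'
#' @param time observation times in minutes, non-negative and finite.
#' @param alpha_obs residual-activity fractions (same length as `time`).
#' @param replicate replicate index per observation (recycled).
#' @param enzyme_id,temperature optional labels (strain/enzyme tag, degrees C).
#' @param truth optional [ground_truth] the data were simulated from.
#' @param seed optional seed the data were simulated with.
#' @return an object of class `timecourse`: a list with a `data` data.frame
#'   (`time`, `replicate`, `alpha_obs`) plus metadata.
#' @examples
#' tc <- timecourse(time = c(0, 10, 20, 40), alpha_obs = c(1, 0.7, 0.55, 0.4))
#' @export
timecourse <- function(time, alpha_obs, replicate = 1L,
                       enzyme_id = NA_character_, temperature = NA_real_,
                       truth = NULL, seed = NULL) {
  time <- as.numeric(time)
  alpha_obs <- as.numeric(alpha_obs)
  if (length(time) != length(alpha_obs))
    stop("time and alpha_obs must have the same length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(alpha_obs)))
    stop("alpha_obs must be finite", call. = FALSE)
  replicate <- as.integer(rep_len(replicate, length(time)))
  structure(
    list(enzyme_id = enzyme_id, temperature = temperature,
         data = data.frame(time = time, replicate = replicate,
                           alpha_obs = alpha_obs),
         truth = truth, seed = seed),
    class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %s at %s C: %d observations, %d replicates, t = %g..%g min\n",
              x$enzyme_id, format(x$temperature), nrow(x$data),
              length(unique(x$data$replicate)),
              min(x$data$time), max(x$data$time)))
  invisible(x)
}

#' Read and write tidy time-course tables
#'
#' The on-disk dialect is a plain CSV with columns `enzyme_id`,
#' `temperature_C`, `replicate`, `time_min`, `residual_activity`; one file may
#' hold many enzyme/temperature combinations.
#'
#' @param tcs a `timecourse` or list of them (for writing).
#' @param path file path.
#' @return `read_timecourse_csv()` returns a named list of `timecourse`
#'   objects (names `"<enzyme_id>_<temperature>C"`);
#'   `write_timecourse_csv()` returns `path` invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    data.frame(enzyme_id = tc$enzyme_id, temperature_C = tc$temperature,
               replicate = tc$data$replicate, time_min = tc$data$time,
               residual_activity = tc$data$alpha_obs)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme_id", "temperature_C", "replicate", "time_min",
            "residual_activity")
  if (!all(need %in% names(df)))
    stop("time-course CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- split(df, list(df$enzyme_id, df$temperature_C), drop = TRUE)
  out <- lapply(keys, function(d) {
    timecourse(d$time_min, d$residual_activity, d$replicate,
               enzyme_id = d$enzyme_id[1], temperature = d$temperature_C[1])
  })
  names(out) <- vapply(out, function(tc)
    sprintf("%s_%gC", tc$enzyme_id, tc$temperature), character(1))
  out[order(names(out))]
}
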