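#' Write and read accelerometer traces as delimited text
#'
#' Tab-separated columns `time_ms`, `x`, `y`, `z`.
#'
#' @param kin a `kinematic_signal`.
#' @param path file path.
#' @return `read_acceleration` returns a `kinematic_signal`.
#' @export
write_acceleration <- function(kin, path) {
  stopifnot(inherits(kin, "kinematic_signal"))
  n <- ncol(kin$axes)
  df <- data.frame(time_ms = (seq_len(n) - 1L) / kin$sample_rate * 1000,
                   x = kin$axes[1, ], y = kin$axes[2, ], z = kin$axes[3, ])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_acceleration
#' @param finger finger id to attach on read.
#' @export
read_acceleration <- function(path, finger = "D2") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- 1000 / stats::median(diff(df$time_ms))
  structure(list(finger = finger, axes = rbind(df$x, df$y, df$z),
                 sample_rate = fs),
            class = "kinematic_signal")
}

#' Write a stimulus design and ground truth as JSON
#'
#' @param design a [stimulus_design()].
#' @param truth optional [ground_truth()] (kernel functions are dropped).
#' @param path file path.
#' @export
write_design_json <- function(design, truth = NULL, path) {
  stopifnot(inherits(design, "stimulus_design"))
  obj <- list(design = list(condition = design$condition,
                            fingers = design$fingers,
                            freq = as.list(design$freq),
                            bursts = apply(design$bursts, 1, as.list),
                            total_duration = design$total_duration,
                            sample_rate = design$sample_rate))
  if (!is.null(truth)) {
    t <- unclass(truth)
    t$evoked_kernel <- NULL
    obj$ground_truth <- t
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read coherence topography tables
#'
#' @param tab a [topography_table()] data.frame.
#' @param path file path.
#' @export
write_topography <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", rep("numeric", 4)))
}

#' Write and read peak-source coordinate tables
#'
#' Tab-separated columns `subject`, `finger`, `condition`, `x`, `y`, `z`.
#'
#' @param coords coordinate data.frame.
#' @param path file path.
#' @export
write_coordinates <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' JSON summary of a CKC fit
#'
#' Writes `{peak_value, peak_channel, pair_channel, threshold,
#' significant, K, stim_freq}`.
#'
#' @param fit a [ckc()] object.
#' @param path file path.
#' @export
write_ckc_summary <- function(fit, path) {
  stopifnot(inherits(fit, "ckc"))
  jsonlite::write_json(list(peak_value = fit$peak$value,
                            peak_channel = fit$peak$channel,
                            pair_channel = fit$peak$pair,
                            pair_value = fit$peak$pair_value,
                            threshold = fit$threshold,
                            significant = fit$significant,
                            K = fit$K, stim_freq = fit$stim_freq),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
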