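#' @export
print.ckc <- function(x, ...) {
  cat("Corticokinematic coherence fit\n")
  cat(sprintf("  K = %d epochs, stimulation frequency %g Hz (bin width %g Hz)\n",
              x$K, x$stim_freq, x$freqs[2] - x$freqs[1]))
  cat(sprintf("  peak CKC = %.3f at channel %d (planar partner %s: %.3f)\n",
              x$peak$value, x$peak$channel,
              ifelse(is.na(x$peak$pair), "-", x$peak$pair),
              ifelse(is.na(x$peak$pair_value), NA, x$peak$pair_value)))
  cat(sprintf("  significance threshold (alpha = %g, %d channels) = %.4f -> %s\n",
              x$alpha, x$n_sens, x$threshold,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
summary.ckc <- function(object, ...) {
  bin <- object$peak$bin
  v <- object$coh[, bin]
  out <- list(peak = object$peak, threshold = object$threshold,
              significant = object$significant, K = object$K,
              stim_freq = object$stim_freq,
              coh_at_f = stats::quantile(v, c(0, 0.5, 0.9, 1), na.rm = TRUE),
              n_sens = object$n_sens, alpha = object$alpha)
  class(out) <- "summary.ckc"
  out
}

#' @export
print.summary.ckc <- function(x, ...) {
  cat("CKC summary\n")
  cat(sprintf("  K = %d epochs, f = %g Hz, alpha = %g over %d channels\n",
              x$K, x$stim_freq, x$alpha, x$n_sens))
  cat("  coherence at f (min / median / 90% / max):",
      paste(sprintf("%.3f", x$coh_at_f), collapse = " / "), "\n")
  cat(sprintf("  peak = %.3f (channel %d), threshold = %.4f, %s\n",
              x$peak$value, x$peak$channel, x$threshold,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
coef.ckc <- function(object, ...) {
  c(peak_ckc = object$peak$value, threshold = object$threshold,
    peak_channel = object$peak$channel, K = object$K,
    stim_freq = object$stim_freq)
}

#' Plot the coherence spectrum of the peak channel
#'
#' @param x a [ckc()] fit.
#' @param fmax upper frequency limit of the plot (Hz).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ckc <- function(x, fmax = 20, ...) {
  sel <- x$freqs <= fmax
  graphics::plot(x$freqs[sel], x$coh[x$peak$channel, sel], type = "h",
                 xlab = "frequency (Hz)", ylab = "coherence",
                 main = sprintf("CKC, peak channel %d", x$peak$channel),
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(v = x$stim_freq, col = "grey", lty = 3)
  invisible(x)
}
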