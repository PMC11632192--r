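#' Per-epoch numeric series anchored at lights-off
#'
#' Uniform epoch grid carrying one value per epoch (a sleepiness score or a
#' theta/alpha ratio) plus a validity flag. Epoch 0 starts at lights-off;
#' epoch centers are at (i - 1/2) * epoch_len.
#'
#' @param values numeric vector, one value per epoch.
#' @param epoch_len epoch length in seconds.
#' @param valid logical vector marking usable epochs (default: finite values).
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(values, epoch_len, valid = NULL) {
  if (epoch_len <= 0) stop("epoch_len must be positive")
  values <- as.numeric(values)
  if (is.null(valid)) valid <- is.finite(values)
  if (length(valid) != length(values)) stop("valid must match values in length")
  structure(
    list(values = values, valid = as.logical(valid),
         epoch_len = epoch_len, anchor = "lights_off"),
    class = "epoch_series"
  )
}

#' Epoch center times of a series, in minutes from lights-off
#' @param x an `epoch_series`.
#' @return numeric vector of epoch-center times (minutes).
#' @export
epoch_centers <- function(x) {
  stopifnot(inherits(x, "epoch_series"))
  (seq_along(x$values) - 0.5) * x$epoch_len / 60
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series: %d x %gs epochs (%d valid), anchored at lights-off>\n",
              length(x$values), x$epoch_len, sum(x$valid)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)
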