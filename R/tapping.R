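# Two-finger alternating tapping features from 20 s event streams:
# timing (inter-tap intervals), spatial precision (drift, scatter) and
# target accuracy.

#' Assign tap events to buttons
#'
#' Membership test of each tap coordinate against the two button bounding
#' boxes (half-open pixel boxes `[x0, x1) x [y0, y1)`, origin top-left).
#' Events outside both boxes are labelled `"none"`.
#'
#' @param events data frame with columns `t`, `x`, `y`
#' @param geometry list with elements `left` and `right`, each
#'   `c(x0, y0, x1, y1)`
#' @return `events` with a `button` column (`left`/`right`/`none`)
#' @export
assign_buttons <- function(events, geometry) {
  inside <- function(box) {
    events$x >= box[1] & events$x < box[3] &
      events$y >= box[2] & events$y < box[4]
  }
  b <- rep("none", nrow(events))
  b[inside(geometry$right)] <- "right"
  b[inside(geometry$left)] <- "left"
  events$button <- b
  events
}

#' Inter-tap interval features
#'
#' `numberTaps` is the event count. The remaining statistics summarize the
#' successive time differences: mean, SD, coefficient of variation
#' (SD/mean), median absolute deviation, interquartile range, minimum,
#' 95th percentile, skewness and excess kurtosis. With fewer than 2 events
#' the interval statistics are missing but `numberTaps` is still emitted.
#'
#' @param stream data frame with columns `t` (seconds, non-decreasing),
#'   `x`, `y`, `button`
#' @return named list `numberTaps`, `TapInter.mean`, `TapInter.sd`,
#'   `TapInter.cv`, `TapInter.mad`, `TapInter.iqr`, `TapInter.min`,
#'   `TapInter.p95`, `TapInter.skew`, `TapInter.kur`
#' @export
interval_features <- function(stream) {
  n <- nrow(stream)
  na_stats <- list(mean = NA_real_, sd = NA_real_, cv = NA_real_,
                   mad = NA_real_, iqr = NA_real_, min = NA_real_,
                   p95 = NA_real_, skew = NA_real_, kur = NA_real_)
  if (n < 2) {
    out <- c(list(numberTaps = n), na_stats)
  } else {
    iti <- diff(stream$t)
    s <- sd(iti)
    out <- list(
      numberTaps = n,
      mean = mean(iti), sd = s,
      cv = if (mean(iti) > 0) s / mean(iti) else NA_real_,
      mad = stats::mad(iti, constant = 1),
      iqr = unname(diff(quantile(iti, c(0.25, 0.75)))),
      min = min(iti),
      p95 = unname(quantile(iti, 0.95)),
      skew = if (s > 0 && length(iti) >= 3)
        e1071::skewness(iti, type = 2) else NA_real_,
      kur = if (s > 0 && length(iti) >= 4)
        e1071::kurtosis(iti, type = 2) else NA_real_)
  }
  names(out)[-1] <- paste0("TapInter.", names(out)[-1])
  out
}

#' Spatial tapping features
#'
#' `DriftLeft`/`DriftRight`: mean Euclidean distance between consecutive
#' taps landing on the same button (missing with fewer than 2 taps on that
#' button). `corXY`: Pearson correlation of all x and y coordinates
#' (missing under zero variance in either coordinate).
#' `TapDist.mean`/`TapDist.sd`: Euclidean distance between consecutive
#' taps regardless of button.
#'
#' @inheritParams interval_features
#' @return named list
#' @export
spatial_features <- function(stream) {
  drift <- function(btn) {
    s <- stream[stream$button == btn, , drop = FALSE]
    if (nrow(s) < 2) return(NA_real_)
    mean(sqrt(diff(s$x)^2 + diff(s$y)^2))
  }
  cor_xy <- if (nrow(stream) >= 3 && sd(stream$x) > 0 && sd(stream$y) > 0)
    cor(stream$x, stream$y) else NA_real_
  d <- if (nrow(stream) >= 2) sqrt(diff(stream$x)^2 + diff(stream$y)^2)
       else numeric(0)
  list(DriftLeft = drift("left"), DriftRight = drift("right"),
       corXY = cor_xy,
       TapDist.mean = if (length(d)) mean(d) else NA_real_,
       TapDist.sd = if (length(d) > 1) sd(d) else NA_real_)
}

#' Target-accuracy features
#'
#' `buttonNoneFreq`: fraction of tap events landing outside both buttons.
#'
#' @inheritParams interval_features
#' @return named list `buttonNoneFreq`
#' @export
accuracy_features <- function(stream) {
  if (nrow(stream) < 1) return(list(buttonNoneFreq = NA_real_))
  list(buttonNoneFreq = mean(stream$button == "none"))
}

#' Tapping features from one 20 s event stream
#'
#' Combines interval, spatial and accuracy features into long-format rows
#' namespaced `tap.*`.
#'
#' @inheritParams interval_features
#' @param record_id identifier attached to the output rows
#' @return tibble `record_id`, `feature`, `value`
#' @export
extract_tapping_features <- function(stream, record_id = NA_character_) {
  vals <- c(interval_features(stream), spatial_features(stream),
            accuracy_features(stream))
  dplyr::bind_rows(purrr::imap(vals, function(v, nm)
    tibble::tibble(record_id = record_id, feature = paste0("tap.", nm),
                   value = as.numeric(v %||% NA_real_))))
}
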