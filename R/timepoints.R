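#' Developmental time-point scheme for the pig skeletal-muscle design
#'
#' Returns the 27-time-point metadata table used throughout the package as
#' the default sampling design: 15 prenatal stages (embryonic day E33 to
#' E105) and 12 postnatal stages (day D0 to D180), partitioned into four
#' contiguous developmental phases: Embryonic (E33-E65, primary myotube
#' formation), Fetal (E70-E105, secondary myotube formation), Neonatal
#' (D0-D60, fiber-type transformation) and Adult (D80-D180, growth and
#' maturation).
#'
#' `day_numeric` places pre- and postnatal stages on one axis by offsetting
#' postnatal days by the approximate 114-day gestation.
#'
#' @return A data.frame with columns `timepoint`, `day_numeric`, `phase`.
#' @examples
#' head(pig_timepoints())
#' table(pig_timepoints()$phase)
#' @export
pig_timepoints <- function() {
  emb <- c(33, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100, 105)
  post <- c(0, 9, 20, 30, 40, 60, 80, 100, 120, 140, 160, 180)
  tp <- c(paste0("E", emb), paste0("D", post))
  day <- c(emb, 114 + post)
  phase <- c(rep("Embryonic", 7), rep("Fetal", 8),
             rep("Neonatal", 6), rep("Adult", 6))
  data.frame(timepoint = tp, day_numeric = day, phase = phase,
             stringsAsFactors = FALSE)
}

#' Validate a phase scheme
#'
#' A phase scheme maps every time point to exactly one phase and phases must
#' be contiguous in time order.
#'
#' @param meta data.frame with columns `timepoint` and `phase`, ordered by
#'   developmental time.
#' @return `meta`, invisibly, after validation.
#' @export
validate_phase_scheme <- function(meta) {
  if (!all(c("timepoint", "phase") %in% names(meta)))
    stopf("phase scheme needs columns 'timepoint' and 'phase'")
  if (anyNA(meta$phase)) stopf("every time point must be assigned a phase")
  r <- rle(as.character(meta$phase))
  if (anyDuplicated(r$values))
    stopf("phases must be contiguous in time order; '%s' is split",
          r$values[duplicated(r$values)][1L])
  invisible(meta)
}
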