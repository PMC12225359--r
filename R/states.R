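#' Define a Normal-state reference band
#'
#' The two-state classification of an RR interval uses a closed duration
#' band: intervals inside `[lower, upper]` (inclusive at both ends) are
#' Normal (`N`), everything outside — too short or too long — is
#' Arrhythmic (`A`). Bounds are in milliseconds and compared at full float
#' precision.
#'
#' @param lower Lower edge in ms; must satisfy `0 < lower < upper`.
#' @param upper Upper edge in ms.
#' @param name Optional band name (e.g. `"alpha1"`).
#' @return An object of class `alpha_band`.
#' @examples
#' alpha_band(800, 1000, name = "alpha1")
#' @export
alpha_band <- function(lower, upper, name = NULL) {
  lower <- as.numeric(lower)[1]
  upper <- as.numeric(upper)[1]
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper <= lower) {
    stop("band must satisfy 0 < lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 name = if (is.null(name)) NULL else as.character(name)[1]),
            class = "alpha_band")
}

#' @export
print.alpha_band <- function(x, ...) {
  cat(sprintf("Normal-state band%s: [%g, %g] ms (closed)\n",
              if (is.null(x$name)) "" else paste0(" \"", x$name, "\""),
              x$lower, x$upper))
  invisible(x)
}

#' Preset reference bands for the two study cohorts
#'
#' Around a resting mean RR interval of roughly 900 ms, the arachnophobia
#' cohort uses the band \[800, 1000\] ms and the blood-pressure
#' (hypertensive/normotensive) cohorts use \[900, 1100\] ms.
#'
#' @param cohort `"arachnophobia"` or `"blood_pressure"`.
#' @return An [alpha_band].
#' @examples
#' default_band("arachnophobia")
#' @export
default_band <- function(cohort = c("arachnophobia", "blood_pressure")) {
  cohort <- match.arg(cohort)
  switch(cohort,
         arachnophobia = alpha_band(800, 1000, name = "alpha1"),
         blood_pressure = alpha_band(900, 1100, name = "alpha2"))
}

#' Classify RR intervals into Arrhythmic/Normal states
#'
#' Elementwise, stateless classification: interval `k` is labelled `N` when
#' `lower <= intervals[k] <= upper`, else `A`. `A` covers deviation on
#' either side of the band; short and long intervals are not distinguished.
#'
#' @param rr An [rr_series] or numeric vector of RR intervals in ms.
#' @param band An [alpha_band].
#' @return An object of class `state_sequence`: a list with `labels`
#'   (character vector of `"A"`/`"N"`, same length and order as the input),
#'   `subject_id` and `band`.
#' @examples
#' classify_states(c(850, 950, 1020), alpha_band(800, 1000))$labels
#' @export
classify_states <- function(rr, band) {
  rr <- as_rr_series(rr)
  stopifnot(inherits(band, "alpha_band"))
  x <- rr$intervals
  labels <- ifelse(x >= band$lower & x <= band$upper, "N", "A")
  state_sequence(labels, subject_id = rr$subject_id, band = band)
}

#' Construct a state sequence
#'
#' The realisation of the two-state process X0, X1, X2, ... derived from an
#' RR series; position in the sequence is the discrete time index.
#'
#' @param labels Character vector with elements `"A"` or `"N"`.
#' @param subject_id Subject identifier.
#' @param band The [alpha_band] used to produce the labels, if any.
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(labels, subject_id = "unknown", band = NULL) {
  labels <- as.character(labels)
  if (length(labels) && !all(labels %in% c("A", "N"))) {
    stop("state labels must be \"A\" or \"N\"", call. = FALSE)
  }
  structure(list(labels = labels, subject_id = as.character(subject_id)[1],
                 band = band),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("State sequence: %d labels (subject %s): %d A, %d N\n",
              n, x$subject_id, sum(x$labels == "A"), sum(x$labels == "N")))
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$labels)

as_state_labels <- function(x) {
  if (inherits(x, "state_sequence")) x$labels
  else if (is.character(x)) state_sequence(x)$labels
  else stop("expected a state_sequence or character vector of A/N labels",
            call. = FALSE)
}
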