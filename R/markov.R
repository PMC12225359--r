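TRANSITIONS <- c("AA", "AN", "NA", "NN")

#' Slide a fixed-width window over a state sequence
#'
#' Windows start at offsets 0, `step`, `2 * step`, ... (0-based) while the
#' whole window fits inside the sequence, so the number of windows is
#' `floor((L - window_size) / step) + 1` for `L >= window_size` and 0
#' otherwise.
#'
#' @param seq A `state_sequence` or character vector of `"A"`/`"N"` labels.
#' @param window_size Number of RR intervals per window (default 10).
#' @param step Offset between consecutive window starts (default 1,
#'   maximally overlapping).
#' @return A list of window views, each a list with `labels` (length
#'   `window_size`) and `start_index` (0-based). A sequence shorter than
#'   the window yields an empty list with a warning.
#' @export
sliding_windows <- function(seq, window_size = 10, step = 1) {
  labels <- as_state_labels(seq)
  check_window_config(window_size, step)
  L <- length(labels)
  if (L < window_size) {
    warning(sprintf("sequence of length %d is shorter than the window (%d);",
                    L, window_size), " no windows produced", call. = FALSE)
    return(list())
  }
  starts <- as.integer(seq.int(0L, L - window_size, by = step))
  lapply(starts, function(s) {
    list(labels = labels[(s + 1):(s + window_size)], start_index = s)
  })
}

check_window_config <- function(window_size, step) {
  if (length(window_size) != 1 || window_size < 2 ||
      window_size != round(window_size)) {
    stop("window_size must be an integer >= 2", call. = FALSE)
  }
  if (length(step) != 1 || step < 1 || step != round(step)) {
    stop("step must be an integer >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimate a 2x2 transition matrix from one window of states
#'
#' Counts the adjacent ordered pairs (labels\[k\], labels\[k + 1\]) within
#' the window and divides each count by the total number of transitions
#' leaving its origin state. A row whose state never occurs before the last
#' position has no outgoing transitions; its probabilities are undefined
#' (`NA`), never imputed. Each defined row sums to 1 by construction — the
#' conservation condition P(A->A) + P(A->N) = 1, P(N->A) + P(N->N) = 1.
#'
#' @param window A window view from [sliding_windows], a `state_sequence`,
#'   or a character vector of labels; length must be at least 2.
#' @return An object of class `transition_matrix`: a list with `p` (2x2
#'   numeric matrix, rows/cols named `A`, `N`, `NA` for undefined rows) and
#'   `counts` (2x2 integer matrix of pair counts).
#' @examples
#' estimate_transition_matrix(c("A", "A", "A", "N", "A", "N"))
#' @export
estimate_transition_matrix <- function(window) {
  if (is.list(window) && !inherits(window, "state_sequence") &&
      !is.null(window$labels)) {
    window <- window$labels
  }
  labels <- as_state_labels(window)
  if (length(labels) < 2) {
    stop("at least 2 states are needed to count a transition", call. = FALSE)
  }
  from <- labels[-length(labels)]
  to <- labels[-1]
  counts <- matrix(0L, 2, 2, dimnames = list(c("A", "N"), c("A", "N")))
  for (i in c("A", "N")) for (j in c("A", "N")) {
    counts[i, j] <- sum(from == i & to == j)
  }
  transition_matrix_from_counts(counts)
}

transition_matrix_from_counts <- function(counts) {
  row_tot <- rowSums(counts)
  p <- counts / ifelse(row_tot > 0, row_tot, NA_real_)
  structure(list(p = p, counts = counts), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("2x2 state-transition matrix (rows: from, cols: to)\n")
  print(round(x$p, digits))
  cat("pair counts:\n")
  print(x$counts)
  if (anyNA(x$p)) {
    cat("NA row: state never left, probabilities undefined\n")
  }
  invisible(x)
}

# Vectorised per-window transition counts: indicator vector per pair type,
# prefix sums, window w starting at 0-based s covers pairs s+1 .. s+w-1.
window_transition_counts <- function(labels, window_size, step) {
  L <- length(labels)
  starts <- as.integer(seq.int(0L, L - window_size, by = step))
  from <- labels[-L]
  to <- labels[-1]
  counts <- matrix(0L, length(starts), 4,
                   dimnames = list(NULL, TRANSITIONS))
  for (tr in TRANSITIONS) {
    i <- substr(tr, 1, 1)
    j <- substr(tr, 2, 2)
    cs <- c(0, cumsum(from == i & to == j))
    counts[, tr] <- cs[starts + window_size] - cs[starts + 1]
  }
  list(starts = starts, counts = counts)
}

#' Fit the windowed Markov-chain model to an RR series
#'
#' The central analysis: classify every RR interval as Arrhythmic or Normal
#' against the reference band, slide a window of `window_size` intervals
#' (advancing by `step`) over the state sequence, and estimate a 2x2
#' transition matrix in every window by adjacent-pair counting. Window-level
#' probabilities for rows that are undefined in a given window (origin state
#' absent before the window's last position) are recorded as `NA` and
#' excluded from the pooled per-transition samples.
#'
#' The fitted object also carries a whole-sequence transition-matrix
#' estimate (all adjacent pairs of the full record pooled into one count
#' table), which [coef.rsa_markov] returns.
#'
#' @param rr An [rr_series] or numeric vector of RR intervals in ms.
#' @param band An [alpha_band]; defaults to the arachnophobia preset
#'   \[800, 1000\] ms.
#' @param window_size Window width in RR intervals (default 10).
#' @param step Window advance in intervals (default 1).
#' @return An object of class `rsa_markov` with components
#'   \describe{
#'     \item{states}{the derived `state_sequence`,}
#'     \item{window_p}{numeric matrix (windows x 4, columns `AA`, `AN`,
#'       `NA`, `NN`) of per-window probabilities with `NA` for undefined
#'       rows,}
#'     \item{window_counts}{integer matrix of per-window pair counts,}
#'     \item{starts}{0-based window start offsets,}
#'     \item{samples}{list of the four pooled per-transition sample
#'       vectors (defined values only, window order preserved),}
#'     \item{global}{whole-sequence `transition_matrix`.}
#'   }
#' @examples
#' rr <- simulate_markov_rr(n_intervals = 200, seed = 1)
#' fit <- rsa_markov(rr$rr, band = default_band("arachnophobia"))
#' coef(fit)
#' @export
rsa_markov <- function(rr, band = default_band("arachnophobia"),
                       window_size = 10, step = 1) {
  cl <- match.call()
  rr <- as_rr_series(rr)
  check_window_config(window_size, step)
  states <- classify_states(rr, band)
  labels <- states$labels
  L <- length(labels)

  if (L >= window_size) {
    wc <- window_transition_counts(labels, window_size, step)
    row_a <- wc$counts[, "AA"] + wc$counts[, "AN"]
    row_n <- wc$counts[, "NA"] + wc$counts[, "NN"]
    denom <- cbind(row_a, row_a, row_n, row_n)
    window_p <- ifelse(denom > 0, wc$counts / denom, NA_real_)
    dimnames(window_p) <- list(NULL, TRANSITIONS)
    starts <- wc$starts
    counts <- wc$counts
  } else {
    warning(sprintf("record has %d intervals, fewer than window_size = %d;",
                    L, window_size), " zero windows", call. = FALSE)
    window_p <- counts <- matrix(numeric(0), 0, 4,
                                 dimnames = list(NULL, TRANSITIONS))
    starts <- integer(0)
  }

  samples <- lapply(TRANSITIONS, function(tr) {
    v <- window_p[, tr]
    v[!is.na(v)]
  })
  names(samples) <- TRANSITIONS

  global <- if (L >= 2) estimate_transition_matrix(labels) else NULL

  structure(
    list(call = cl, subject_id = rr$subject_id,
         group_label = rr$group_label, band = band,
         window_size = window_size, step = step,
         n_intervals = L, n_windows = nrow(window_p),
         states = states, starts = starts,
         window_p = window_p, window_counts = counts,
         samples = samples, global = global),
    class = "rsa_markov"
  )
}

#' @export
print.rsa_markov <- function(x, digits = 3, ...) {
  cat("Windowed Markov-chain model of RR-interval states\n")
  cat(sprintf("  subject: %s, %d intervals, band [%g, %g] ms\n",
              x$subject_id, x$n_intervals, x$band$lower, x$band$upper))
  cat(sprintf("  window: %d intervals, step %d -> %d windows\n",
              x$window_size, x$step, x$n_windows))
  if (!is.null(x$global)) {
    cat("  whole-sequence transition estimate:\n")
    print(round(x$global$p, digits))
  }
  invisible(x)
}

#' Summarise a fitted windowed Markov-chain model
#'
#' Per transition type: the number of windows where the probability was
#' defined, and the mean and sample standard deviation of the pooled
#' window-level values.
#'
#' @param object An `rsa_markov` fit.
#' @param ... Unused.
#' @return A `summary.rsa_markov` object wrapping a per-transition
#'   data frame and the whole-sequence estimate.
#' @export
summary.rsa_markov <- function(object, ...) {
  tab <- do.call(rbind, lapply(TRANSITIONS, function(tr) {
    s <- summarize_probs(object$samples[[tr]], quiet = TRUE)
    data.frame(transition = transition_pretty(tr), n = s$n,
               mean = s$mean, sd = s$sd)
  }))
  structure(list(fit = object, table = tab), class = "summary.rsa_markov")
}

#' @export
print.summary.rsa_markov <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("pooled window-level probabilities:\n")
  tab <- x$table
  tab$mean <- round(tab$mean, digits)
  tab$sd <- round(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Whole-sequence transition-probability estimate
#'
#' @param object An `rsa_markov` fit.
#' @param ... Unused.
#' @return The 2x2 row-stochastic matrix estimated from all adjacent state
#'   pairs of the record (`NA` rows when a state never occurs before the
#'   end).
#' @export
coef.rsa_markov <- function(object, ...) {
  if (is.null(object$global)) {
    matrix(NA_real_, 2, 2, dimnames = list(c("A", "N"), c("A", "N")))
  } else {
    object$global$p
  }
}

#' Plot window-level transition probabilities over time
#'
#' Shows the per-window probability of remaining in each state (A->A and
#' N->N) against the window start offset; gaps are windows where the row
#' was undefined.
#'
#' @param x An `rsa_markov` fit.
#' @param ... Passed to [graphics::plot].
#' @export
plot.rsa_markov <- function(x, ...) {
  if (x$n_windows == 0) {
    stop("no windows to plot", call. = FALSE)
  }
  graphics::plot(x$starts, x$window_p[, "AA"], type = "l", col = "firebrick",
                 ylim = c(0, 1), xlab = "window start (interval offset)",
                 ylab = "transition probability",
                 main = sprintf("Per-window P(A→A) and P(N→N), subject %s",
                                x$subject_id), ...)
  graphics::lines(x$starts, x$window_p[, "NN"], col = "steelblue")
  graphics::legend("bottomright", legend = c("A→A", "N→N"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate RR series from a fitted model
#'
#' Draws new RR records from the hidden two-state generator parameterised
#' by the fit's whole-sequence transition estimate and its reference band.
#'
#' @param object An `rsa_markov` fit with a fully defined whole-sequence
#'   estimate.
#' @param nsim Number of records to simulate.
#' @param seed Seed passed to the generator (incremented per record).
#' @param n_intervals Length of each simulated record; defaults to the
#'   fitted record's length.
#' @param ... Unused.
#' @return A list of [rr_series] objects of length `nsim`.
#' @export
simulate.rsa_markov <- function(object, nsim = 1, seed = 1,
                                n_intervals = object$n_intervals, ...) {
  p <- coef(object)
  if (anyNA(p)) {
    stop("whole-sequence estimate has an undefined row; cannot simulate",
         call. = FALSE)
  }
  lapply(seq_len(nsim), function(k) {
    simulate_markov_rr(p_true = p, band = object$band,
                       n_intervals = n_intervals, seed = seed + k - 1)$rr
  })
}

transition_pretty <- function(tr) {
  paste(substr(tr, 1, 1), "to", substr(tr, 2, 2))
}

#' Pool per-transition samples across fitted records
#'
#' Concatenates the defined window-level probabilities for one transition
#' type over a list of fits — the pooling unit used for group comparisons.
#'
#' @param fits A list of `rsa_markov` fits.
#' @param transition One of `"AA"`, `"AN"`, `"NA"`, `"NN"`.
#' @return Numeric vector of pooled window-level probabilities.
#' @export
pooled_samples <- function(fits, transition = TRANSITIONS) {
  transition <- match.arg(transition)
  stopifnot(all(vapply(fits, inherits, logical(1), "rsa_markov")))
  unlist(lapply(fits, function(f) f$samples[[transition]]), use.names = FALSE)
}
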