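# report order mirrors the published comparison tables
TRANSITION_REPORT_ORDER <- c("AN", "AA", "NA", "NN")

#' Summarise a pooled probability sample
#'
#' Arithmetic mean and sample standard deviation (denominator n - 1) of a
#' vector of pooled window-level transition probabilities.
#'
#' @param samples Numeric vector; may be empty.
#' @param quiet Suppress the empty-sample warning.
#' @return A list with `n`, `mean` and `sd`; `mean`/`sd` are `NA` when
#'   undefined (empty sample; `sd` also for a single observation).
#' @export
summarize_probs <- function(samples, quiet = FALSE) {
  n <- length(samples)
  if (n == 0) {
    if (!quiet) {
      warning("empty sample: mean and sd undefined", call. = FALSE)
    }
    return(list(n = 0L, mean = NA_real_, sd = NA_real_))
  }
  list(n = n, mean = mean(samples),
       sd = if (n > 1) stats::sd(samples) else NA_real_)
}

#' Two-sided Mann-Whitney U test with exact and approximate modes
#'
#' Rank-sum test for two independent samples. Ranks use midranks for ties.
#' In `exact` mode the null distribution of U is obtained by full
#' enumeration of all ways to assign the pooled (mid)ranks to the first
#' sample, which remains valid in the presence of ties; the two-sided
#' p-value is the probability of a U at least as far from `n_x n_y / 2` as
#' the observed one. In `approx` mode the normal approximation is used with
#' the tie-corrected variance and a 0.5 continuity correction.
#'
#' `mode = "auto"` selects exact enumeration when `min(n_x, n_y) <= 8` and
#' the enumeration is affordable (`choose(n_x + n_y, n_x) <=
#' enumeration_limit`), otherwise the approximation. Pooled window samples
#' are large and tie-heavy, so group comparisons in practice use the
#' tie-corrected approximation.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param enumeration_limit Largest number of subsets `auto`/`exact` will
#'   enumerate (default 2e5).
#' @return A list of class `mw_test`: `u_statistic` (U of `x`),
#'   `u_other` (U of `y`; the two always sum to `n_x * n_y`), `p_value`
#'   (two-sided), `method` (`"exact"` or `"normal_approximation"`), `n_x`,
#'   `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           enumeration_limit = 2e5) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  ranks <- rank(c(x, y))
  u_x <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x

  do_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = min(nx, ny) <= 8 && choose(n, nx) <= enumeration_limit)
  if (do_exact && choose(n, nx) > enumeration_limit) {
    stop(sprintf("exact enumeration needs %.3g subsets, above the limit %g;",
                 choose(n, nx), enumeration_limit),
         " use mode = \"approx\"", call. = FALSE)
  }

  if (do_exact) {
    subsets <- utils::combn(n, nx)
    rs <- colSums(matrix(ranks[subsets], nrow = nx))
    u_null <- rs - nx * (nx + 1) / 2
    mid <- nx * ny / 2
    p <- mean(abs(u_null - mid) >= abs(u_x - mid) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(ranks)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    num <- u_x - nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      num_cc <- sign(num) * max(abs(num) - 0.5, 0) # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(num_cc) / sqrt(sigma2)))
    }
    method <- "normal_approximation"
  }

  structure(list(u_statistic = u_x, u_other = u_y, p_value = p,
                 method = method, n_x = nx, n_y = ny),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g (n = %d, %d), two-sided p = %.3g\n",
              x$method, x$u_statistic, x$n_x, x$n_y, x$p_value))
  invisible(x)
}

as_fit_list <- function(g, band, window_size, step) {
  if (inherits(g, "rsa_markov")) g <- list(g)
  if (inherits(g, "rr_series")) g <- list(g)
  stopifnot(is.list(g), length(g) >= 1)
  lapply(g, function(el) {
    if (inherits(el, "rsa_markov")) el
    else rsa_markov(el, band = band, window_size = window_size, step = step)
  })
}

#' Compare two subject groups per transition type
#'
#' Pools the defined window-level transition probabilities of all records
#' within each group into one sample per transition, then for each of the
#' four transitions reports group means, sample standard deviations and a
#' two-sided Mann-Whitney U test between the pooled samples. Rows are
#' ordered A to N, A to A, N to A, N to N, the layout of the published
#' comparison tables.
#'
#' Because the A-row samples are pointwise complements (P(A->N) = 1 -
#' P(A->A) window by window), the A to N and A to A rows share the same
#' standard deviations and the same p-value, and their means sum to 1;
#' likewise for the N row. No multiple-testing correction is applied.
#'
#' @param group_a,group_b Lists of `rsa_markov` fits, or lists of
#'   [rr_series]/numeric RR vectors which are then fitted with `band`,
#'   `window_size` and `step`.
#' @param labels Character vector of two group display names.
#' @param band,window_size,step Used only when raw RR records are given.
#' @param mode Mann-Whitney mode, see [mann_whitney_u].
#' @return An object of class `rsa_comparison` wrapping a data frame with
#'   columns `transition`, `p_value`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`, `u_statistic`, `method`. A transition with an empty
#'   pooled sample in either group is reported as `not_computable`; the
#'   other rows are unaffected.
#' @export
compare_groups <- function(group_a, group_b,
                           labels = c("group_a", "group_b"),
                           band = default_band("arachnophobia"),
                           window_size = 10, step = 1,
                           mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  fits_a <- as_fit_list(group_a, band, window_size, step)
  fits_b <- as_fit_list(group_b, band, window_size, step)

  rows <- lapply(TRANSITION_REPORT_ORDER, function(tr) {
    sa <- pooled_samples(fits_a, tr)
    sb <- pooled_samples(fits_b, tr)
    suma <- summarize_probs(sa, quiet = TRUE)
    sumb <- summarize_probs(sb, quiet = TRUE)
    if (!length(sa) || !length(sb)) {
      return(data.frame(transition = transition_pretty(tr),
                        p_value = NA_real_,
                        mean_a = suma$mean, mean_b = sumb$mean,
                        sd_a = suma$sd, sd_b = sumb$sd,
                        n_a = suma$n, n_b = sumb$n,
                        u_statistic = NA_real_,
                        method = "not_computable"))
    }
    mw <- mann_whitney_u(sa, sb, mode = mode)
    data.frame(transition = transition_pretty(tr),
               p_value = mw$p_value,
               mean_a = suma$mean, mean_b = sumb$mean,
               sd_a = suma$sd, sd_b = sumb$sd,
               n_a = suma$n, n_b = sumb$n,
               u_statistic = mw$u_statistic,
               method = mw$method)
  })

  structure(list(table = do.call(rbind, rows), labels = labels,
                 n_records = c(length(fits_a), length(fits_b))),
            class = "rsa_comparison")
}

#' @export
print.rsa_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Group comparison of pooled window-level transition probabilities\n"))
  cat(sprintf("  %s: %d record(s); %s: %d record(s)\n",
              x$labels[1], x$n_records[1], x$labels[2], x$n_records[2]))
  tab <- x$table
  disp <- data.frame(
    Probability = tab$transition,
    `p-Value` = signif(tab$p_value, 2),
    mean_a = round(tab$mean_a, digits - 1),
    mean_b = round(tab$mean_b, digits - 1),
    sd_a = round(tab$sd_a, digits - 1),
    sd_b = round(tab$sd_b, digits - 1),
    check.names = FALSE)
  names(disp)[3:6] <- c(paste0("mean(", x$labels, ")"),
                        paste0("sd(", x$labels, ")"))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rsa_comparison <- function(object, ...) object

#' @export
as.data.frame.rsa_comparison <- function(x, ...) x$table

#' Bar chart of group mean transition probabilities
#'
#' Side-by-side bars of the pooled group means per transition type, the
#' figure style used for the published cohort comparisons.
#'
#' @param x An `rsa_comparison`.
#' @param ... Passed to [graphics::barplot].
#' @export
plot.rsa_comparison <- function(x, ...) {
  m <- t(as.matrix(x$table[, c("mean_a", "mean_b")]))
  colnames(m) <- x$table$transition
  rownames(m) <- x$labels
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    col = c("steelblue", "firebrick"),
                    legend.text = x$labels,
                    ylab = "mean transition probability", ...)
  invisible(x)
}
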