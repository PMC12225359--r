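# Independent oracles used across the suite. These deliberately use
# different mechanics from the package code paths they check.

# Brute-force transition estimate: walk every adjacent pair with an
# explicit loop and divide by row totals.
brute_force_tm <- function(labels) {
  counts <- matrix(0, 2, 2, dimnames = list(c("A", "N"), c("A", "N")))
  for (k in seq_len(length(labels) - 1)) {
    counts[labels[k], labels[k + 1]] <- counts[labels[k], labels[k + 1]] + 1
  }
  p <- counts
  for (i in 1:2) {
    tot <- sum(counts[i, ])
    p[i, ] <- if (tot > 0) counts[i, ] / tot else NA_real_
  }
  list(p = p, counts = counts)
}

# Full-enumeration two-sided Mann-Whitney p-value, computing U by direct
# pair comparison (not rank sums): U = #{x_i > y_j} + 0.5 #{x_i == y_j}.
mw_pair_count_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

mw_enum_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool)
  nx <- length(x)
  mid <- nx * length(y) / 2
  u_obs <- mw_pair_count_u(x, y)
  idx <- utils::combn(n, nx)
  count <- 0
  for (col in seq_len(ncol(idx))) {
    xs <- pool[idx[, col]]
    ys <- pool[-idx[, col]]
    if (abs(mw_pair_count_u(xs, ys) - mid) >= abs(u_obs - mid) - 1e-9) {
      count <- count + 1
    }
  }
  count / ncol(idx)
}

random_labels <- function(n, p_a = runif(1, 0.1, 0.9)) {
  sample(c("A", "N"), n, replace = TRUE, prob = c(p_a, 1 - p_a))
}

write_temp_rr <- function(intervals, dir = tempfile("rrdir"),
                          name = "rec.txt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, name)
  writeLines(as.character(intervals), path)
  path
}
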