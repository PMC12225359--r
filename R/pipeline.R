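#' Run the single-record analysis pipeline
#'
#' Reads one record — either a plain-text RR/IBI file or a raw EKG file
#' (in which case R peaks are detected automatically and RR intervals
#' derived) — fits the windowed Markov-chain model and writes two
#' artifacts: a per-window CSV (`start_index, p_aa, p_an, p_na, p_nn`,
#' undefined probabilities as empty cells) and a JSON summary with the full
#' configuration and the pooled per-transition statistics.
#'
#' @param input Path to the input file.
#' @param input_type `"rr"` or `"ekg"`.
#' @param sampling_rate_hz Required when `input_type = "ekg"`.
#' @param band An [alpha_band].
#' @param window_size,step Window configuration.
#' @param out_prefix Path prefix for the artifacts; writes
#'   `<out_prefix>_windows.csv` and `<out_prefix>_summary.json`.
#' @param verbose Print progress counts.
#' @return Invisibly, a list with the `rsa_markov` fit and the two output
#'   paths.
#' @export
run_analyze <- function(input, input_type = c("rr", "ekg"),
                        sampling_rate_hz = NULL,
                        band = default_band("arachnophobia"),
                        window_size = 10, step = 1,
                        out_prefix = "analysis", verbose = TRUE) {
  input_type <- match.arg(input_type)
  if (!file.exists(input)) {
    stop(sprintf("input file not found: %s", input), call. = FALSE)
  }
  if (input_type == "rr") {
    rr <- read_rr_file(input)
  } else {
    if (is.null(sampling_rate_hz)) {
      stop("sampling_rate_hz is required for EKG input", call. = FALSE)
    }
    sig <- read_ekg_file(input, sampling_rate_hz)
    peaks <- detect_r_peaks(sig)
    rr <- rr_from_peaks(peaks, sampling_rate_hz,
                        subject_id = tools::file_path_sans_ext(basename(input)))
  }
  fit <- rsa_markov(rr, band = band, window_size = window_size, step = step)

  csv_path <- paste0(out_prefix, "_windows.csv")
  win_df <- data.frame(start_index = fit$starts,
                       p_aa = fit$window_p[, "AA"],
                       p_an = fit$window_p[, "AN"],
                       p_na = fit$window_p[, "NA"],
                       p_nn = fit$window_p[, "NN"])
  utils::write.csv(win_df, csv_path, row.names = FALSE, na = "")

  summ <- summary(fit)$table
  json_path <- paste0(out_prefix, "_summary.json")
  jsonlite::write_json(
    list(input = input, input_type = input_type,
         subject_id = fit$subject_id,
         band = list(lower_ms = band$lower, upper_ms = band$upper),
         window_size = window_size, step = step,
         n_intervals = fit$n_intervals, n_windows = fit$n_windows,
         n_defined = as.list(stats::setNames(
           vapply(fit$samples, length, integer(1)), TRANSITIONS)),
         pooled = summ),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")

  if (verbose) {
    message(sprintf("read %d intervals -> %d windows (window %d, step %d)",
                    fit$n_intervals, fit$n_windows, window_size, step))
    message(sprintf("wrote %s and %s", csv_path, json_path))
  }
  invisible(list(fit = fit, windows_csv = csv_path, summary_json = json_path))
}

#' Run the two-group comparison pipeline
#'
#' Reads every `.txt` RR file in each group directory, fits the windowed
#' model per record, pools window-level probabilities per group, and writes
#' the four-row comparison report as CSV (columns `transition, p_value,
#' mean_a, mean_b, sd_a, sd_b, n_a, n_b, u_statistic, method`).
#'
#' @param group_a_dir,group_b_dir Directories of RR `.txt` files (one
#'   record per file); each must contain at least one file.
#' @param labels Display names for the two groups.
#' @param band An [alpha_band].
#' @param window_size,step Window configuration.
#' @param out_csv Output CSV path, or `NULL` to skip writing.
#' @param verbose Print progress counts.
#' @return Invisibly, the `rsa_comparison` object.
#' @export
run_compare <- function(group_a_dir, group_b_dir,
                        labels = c(basename(group_a_dir),
                                   basename(group_b_dir)),
                        band = default_band("arachnophobia"),
                        window_size = 10, step = 1,
                        out_csv = "comparison.csv", verbose = TRUE) {
  read_group <- function(dir) {
    if (!dir.exists(dir)) {
      stop(sprintf("group directory not found: %s", dir), call. = FALSE)
    }
    files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
    if (!length(files)) {
      stop(sprintf("group directory %s contains no .txt RR files", dir),
           call. = FALSE)
    }
    lapply(files, read_rr_file)
  }
  grp_a <- read_group(group_a_dir)
  grp_b <- read_group(group_b_dir)
  if (verbose) {
    message(sprintf("group %s: %d record(s); group %s: %d record(s)",
                    labels[1], length(grp_a), labels[2], length(grp_b)))
  }
  cmp <- compare_groups(grp_a, grp_b, labels = labels, band = band,
                        window_size = window_size, step = step)
  if (!is.null(out_csv)) {
    utils::write.csv(cmp$table, out_csv, row.names = FALSE, na = "")
    if (verbose) message("wrote ", out_csv)
  }
  invisible(cmp)
}
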