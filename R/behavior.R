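# Behavioral analysis of percept reports: dominance durations, normality
# testing with log transform, and group-level duration-difference tests.

#' Extract percept dominance durations from a button stream
#'
#' Contiguous same-state runs of the button stream (ignoring `none`/`both`
#' samples) are converted to seconds. A switch is a change of state between
#' successive unambiguous runs; runs of the same state separated only by
#' `none`/`both` gaps are counted as separate durations but not as a switch.
#'
#' @param button_stream Per-sample state vector.
#' @param fs Sampling rate of the stream (Hz).
#' @return List with `gallop`, `segregated` (duration vectors, s),
#'   `n_switches`, and `ambiguous_s` (total none/both time).
#' @export
extract_durations <- function(button_stream, fs) {
  r <- rle(as.character(button_stream))
  keep <- r$values %in% c("gallop", "segregated")
  if (!any(keep)) {
    warning("no unambiguous percept segments")
    return(list(gallop = numeric(0), segregated = numeric(0),
                n_switches = 0L,
                ambiguous_s = sum(r$lengths[!keep]) / fs))
  }
  states <- r$values[keep]
  durs <- r$lengths[keep] / fs
  list(gallop = durs[states == "gallop"],
       segregated = durs[states == "segregated"],
       n_switches = sum(states[-1] != states[-length(states)]),
       ambiguous_s = sum(r$lengths[!keep]) / fs)
}

#' Test durations for normality before and after log transform
#'
#' One-sample Kolmogorov-Smirnov test against a normal with the sample mean
#' and SD (the conventional procedure, although estimating the parameters
#' from the sample makes the test conservative — Lilliefors' correction is
#' available as `method = "lilliefors"`).
#'
#' @param durations Positive duration vector (s).
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return List with `p_raw` and `p_log`; both `NA` (undefined) when `n < 5`
#'   or the sample is degenerate.
#' @export
test_normality <- function(durations, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  undef <- list(p_raw = NA_real_, p_log = NA_real_, undefined = TRUE)
  if (length(durations) < 5L) return(undef)
  if (stats::sd(durations) == 0) return(undef)
  one <- function(x) {
    if (method == "ks")
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    else nortest::lillie.test(x)$p.value
  }
  list(p_raw = one(durations), p_log = one(log(durations)), undefined = FALSE)
}

#' Per-subject dominance-duration summary
#'
#' @param button_stream Per-sample state vector.
#' @param fs Sampling rate (Hz).
#' @param subject_id Identifier carried into group analyses.
#' @return A `duration_summary`: per-state duration lists, switch count, and
#'   per-state mean/median/sd on the raw and log scale with KS p-values.
#' @export
duration_summary <- function(button_stream, fs, subject_id = NA) {
  d <- extract_durations(button_stream, fs)
  per_state <- lapply(d[c("gallop", "segregated")], function(x) {
    ks <- test_normality(x)
    list(durations = x, n = length(x),
         mean = mean(x), median = stats::median(x), sd = stats::sd(x),
         mean_log = mean(log(x)), median_log = stats::median(log(x)),
         sd_log = stats::sd(log(x)),
         ks_p_raw = ks$p_raw, ks_p_log = ks$p_log)
  })
  structure(list(subject_id = subject_id, gallop = per_state$gallop,
                 segregated = per_state$segregated,
                 n_switches = d$n_switches, ambiguous_s = d$ambiguous_s),
            class = "duration_summary")
}

#' Group test of gallop-vs-segregated duration difference
#'
#' Per subject, the chosen average (mean or median, raw or log scale) of
#' gallop durations minus that of segregated durations; the differences are
#' tested against zero with a two-sided one-sample t-test.
#'
#' @param summaries List of [duration_summary()] objects.
#' @param stat `"mean"` or `"median"`.
#' @param log Use log-transformed durations.
#' @return List with `t`, `df`, `p`, and the per-subject `diffs`.
#' @export
group_duration_difference <- function(summaries, stat = c("mean", "median"),
                                      log = FALSE) {
  stat <- match.arg(stat)
  field <- paste0(stat, if (log) "_log" else "")
  diffs <- vapply(summaries, function(s) {
    if (s$gallop$n == 0 || s$segregated$n == 0) return(NA_real_)
    s$gallop[[field]] - s$segregated[[field]]
  }, numeric(1))
  if (anyNA(diffs)) {
    warning(sum(is.na(diffs)), " subject(s) missing a state; excluded")
    diffs <- diffs[!is.na(diffs)]
  }
  if (length(diffs) < 2L) stop("need >= 2 subjects with both states")
  if (stats::sd(diffs) == 0) {
    return(list(t = 0, df = length(diffs) - 1L, p = 1, diffs = diffs))
  }
  tt <- stats::t.test(diffs, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, diffs = diffs)
}

#' Log-duration histograms per subject and state
#'
#' Binned counts of log dominance durations, one panel per subject with both
#' percepts on a shared set of bins (plot-ready; rendering is left to the
#' caller).
#'
#' @param summaries List of [duration_summary()] objects.
#' @param n_bins Number of bins on the log scale.
#' @return List per subject: `breaks` (log s) and per-state `counts`.
#' @export
duration_histograms <- function(summaries, n_bins = 20L) {
  lapply(summaries, function(s) {
    all_log <- log(c(s$gallop$durations, s$segregated$durations))
    if (!length(all_log)) return(list(breaks = numeric(0)))
    rng <- range(all_log)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    cnt <- function(x) if (length(x))
      graphics::hist(log(x), breaks = breaks, plot = FALSE)$counts
    else integer(n_bins)
    list(subject_id = s$subject_id, breaks = breaks,
         gallop = cnt(s$gallop$durations),
         segregated = cnt(s$segregated$durations))
  })
}
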