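#' Mass-window filter
#'
#' Retains peaks whose m/z lies within `[low, high]` Da, both bounds
#' inclusive (the diterpenoid-range convention used throughout: 295-400).
#'
#' @param t a [peak_table()].
#' @param low,high window bounds in Da, `low < high`.
#' @return filtered [peak_table()].
#' @export
filter_mass_window <- function(t, low = 295, high = 400) {
  stopifnot(inherits(t, "tf_peaks"))
  if (low >= high) stop("low must be < high", call. = FALSE)
  keep <- t$peaks$peak_id[t$peaks$mz >= low & t$peaks$mz <= high]
  subset_peaks(t, keep)
}

# Rowwise one-way ANOVA F on log2(x + 1) intensities across groups.
row_anova <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(groups)
  gm <- rowMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    cols <- groups == lev
    nj <- sum(cols)
    mj <- rowMeans(x[, cols, drop = FALSE])
    ssb <- ssb + nj * (mj - gm)^2
    ssw <- ssw + rowSums((x[, cols, drop = FALSE] - mj)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  # zero within-group variance: changing means -> p = 0, flat -> p = 1
  degen <- ssw == 0
  p[degen & ssb > 1e-12] <- 0
  p[degen & ssb <= 1e-12] <- 1
  list(F = f, p = p)
}

#' Responsiveness filter (ANOVA + max-fold)
#'
#' One-way ANOVA across sample groups on `log2(x + 1)` intensities, plus a
#' raw-scale max-fold = max group mean / min group mean (pseudocount 1).
#' Retains peaks that change: `p < alpha` and `max-fold > min_maxfold`.
#'
#' The inverse reading — keeping the unresponsive peaks — is available with
#' `keep = "unresponsive"`.
#'
#' @param t a [peak_table()].
#' @param groups grouping factor over samples; defaults to
#'   condition-by-time for time-course samples (tissue samples are dropped
#'   from the test when a default grouping is built).
#' @param alpha significance level (strict `<`).
#' @param min_maxfold max-fold threshold (strict `>`).
#' @param keep `"responsive"` (default) or `"unresponsive"`.
#' @return filtered [peak_table()] with a `stats` attribute
#'   (`peak_id`, `F`, `p`, `max_fold`).
#' @export
filter_responsive <- function(t, groups = NULL, alpha = 0.01,
                              min_maxfold = 2, keep = c("responsive",
                                                        "unresponsive")) {
  stopifnot(inherits(t, "tf_peaks"))
  keep <- match.arg(keep)
  if (is.null(groups)) {
    d <- t$design
    sel <- d$condition %in% c("treated", "control")
    groups <- paste(d$condition[sel], d$time_h[sel], sep = "_")
    x <- t$intensities[, sel, drop = FALSE]
  } else {
    x <- t$intensities
  }
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop("group(s) with < 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  an <- row_anova(log2(x + 1), groups)
  gmeans <- sapply(unique(groups), function(g) {
    rowMeans(x[, groups == g, drop = FALSE])
  })
  max_fold <- (apply(gmeans, 1, max) + 1) / (apply(gmeans, 1, min) + 1)
  responsive <- an$p < alpha & max_fold > min_maxfold
  sel_rows <- if (keep == "responsive") responsive else !responsive
  out <- subset_peaks(t, t$peaks$peak_id[sel_rows])
  attr(out, "stats") <- data.frame(peak_id = t$peaks$peak_id, F = an$F,
                                   p = an$p, max_fold = max_fold,
                                   stringsAsFactors = FALSE)
  out
}

#' Fragment-presence filter
#'
#' Removes peaks with no fragments (retains `fragment_count >= 1`).
#'
#' @param t a [peak_table()].
#' @return filtered [peak_table()].
#' @export
filter_fragmentless <- function(t) {
  stopifnot(inherits(t, "tf_peaks"))
  subset_peaks(t, t$peaks$peak_id[t$peaks$fragment_count >= 1])
}

#' Run the full peak-filter funnel
#'
#' Applies, in order, the mass-window filter, the ANOVA responsiveness
#' filter, and the fragment filter, recording each stage's survivors.
#'
#' @param t a [peak_table()].
#' @param mass_low,mass_high mass window (Da, inclusive).
#' @param alpha,min_maxfold responsiveness thresholds.
#' @param groups optional grouping for the ANOVA (see
#'   [filter_responsive()]).
#' @return list with `peaks` (final [peak_table()]) and `report` (class
#'   `tf_peak_report`: per-stage names, surviving ids and counts).
#' @export
run_peak_funnel <- function(t, mass_low = 295, mass_high = 400,
                            alpha = 0.01, min_maxfold = 2, groups = NULL) {
  stopifnot(inherits(t, "tf_peaks"))
  s0 <- t$peaks$peak_id
  t1 <- filter_mass_window(t, mass_low, mass_high)
  t2 <- filter_responsive(t1, groups = groups, alpha = alpha,
                          min_maxfold = min_maxfold)
  t3 <- filter_fragmentless(t2)
  report <- structure(list(
    stages = c("input", "mass_window", "responsiveness", "fragments"),
    survivors = list(input = s0, mass_window = t1$peaks$peak_id,
                     responsiveness = t2$peaks$peak_id,
                     fragments = t3$peaks$peak_id),
    counts = c(input = length(s0), mass_window = nrow(t1$peaks),
               responsiveness = nrow(t2$peaks), fragments = nrow(t3$peaks))),
    class = "tf_peak_report")
  list(peaks = t3, report = report)
}

#' @export
print.tf_peak_report <- function(x, ...) {
  cat("peak funnel:\n")
  for (s in x$stages) cat(sprintf("  %-15s %d\n", s, x$counts[[s]]))
  invisible(x)
}
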