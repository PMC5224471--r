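#' Aggregate per-cell co-localization into a time-course summary
#'
#' Groups per-cell percentages by (time point, label pair, direction)
#' and reports the across-cell mean, SEM (sample sd / sqrt(n); absent
#' for n < 2) and cell count. Undefined (zero-denominator) results are
#' excluded from the statistics and the exclusion count reported via a
#' message, mirroring the convention of presenting per-timepoint means
#' over 10-20 analysed cells as mean +/- SEM.
#'
#' @param results A list of `coloc_result` objects or a tidy data.frame
#'   from [coloc_results_df()].
#' @return Data.frame of class `timecourse_summary` with columns
#'   `time_min`, `label_A`, `label_B`, `direction`, `n_cells`,
#'   `mean_percent`, `sem_percent`, `mean_null_percent`.
#' @export
summarize_timecourse <- function(results) {
  df <- if (is.data.frame(results)) results else coloc_results_df(results)
  if (!nrow(df)) vc_degenerate_error("no results to summarize")
  defined <- !is.na(df$percent)
  if (any(!defined)) {
    message(sprintf("excluding %d undefined (zero-denominator) result(s)",
                    sum(!defined)))
  }
  df <- df[defined, , drop = FALSE]
  if (!nrow(df)) vc_degenerate_error("all results are undefined")
  key <- interaction(df$time_min, df$label_A, df$label_B, df$direction,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(df, key), function(g) {
    n <- nrow(g)
    data.frame(
      time_min = g$time_min[1L], label_A = g$label_A[1L],
      label_B = g$label_B[1L], direction = g$direction[1L],
      n_cells = n,
      mean_percent = mean(g$percent),
      sem_percent = if (n >= 2L) stats::sd(g$percent) / sqrt(n) else NA_real_,
      mean_null_percent = if (all(is.na(g$null_percent))) NA_real_
                          else mean(g$null_percent, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label_A, out$label_B, out$direction, out$time_min), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("timecourse_summary", "data.frame")
  out
}

#' Two-sample comparison of per-cell percentages
#'
#' Two-tailed two-sample t-test between two groups of per-cell
#' values. `"student"` pools the variances (classic Student's test);
#' `"welch"` does not assume equal variances.
#'
#' @param x,y Numeric vectors of per-cell percentages (each needs at
#'   least 2 non-missing values).
#' @param variant `"student"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`, `variant`, `mean_x`, `mean_y`.
#' @export
compare_pairs <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    vc_degenerate_error("each group needs at least 2 defined values")
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, variant = variant,
       mean_x = mean(x), mean_y = mean(y))
}

#' Significance stars at the conventional 0.05 / 0.01 / 0.001 levels
#' @param p P-value(s).
#' @return Character vector of `""`, `"*"`, `"**"` or `"***"`.
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = TRUE) |> as.character()
}

#' Per-timepoint comparison of two label pairs
#'
#' At each time point shared by both pairs, runs [compare_pairs()] on
#' the per-cell percentages (skipping time points where either group
#' has fewer than 2 defined cells).
#'
#' @param per_cell Tidy per-cell data.frame ([coloc_results_df()]).
#' @param pair1,pair2 Character vectors `c(label_A, label_B)`.
#' @param direction Direction to compare (default `"B_with_A"`).
#' @param variant Test variant, see [compare_pairs()].
#' @return Data.frame with one row per compared time point.
#' @export
compare_timecourse <- function(per_cell, pair1, pair2,
                               direction = "B_with_A",
                               variant = c("student", "welch")) {
  variant <- match.arg(variant)
  sel <- function(pair) {
    per_cell[per_cell$label_A == pair[1L] & per_cell$label_B == pair[2L] &
             per_cell$direction == direction & !is.na(per_cell$percent), ,
             drop = FALSE]
  }
  d1 <- sel(pair1); d2 <- sel(pair2)
  times <- sort(intersect(unique(d1$time_min), unique(d2$time_min)))
  rows <- lapply(times, function(tm) {
    g1 <- d1$percent[d1$time_min == tm]
    g2 <- d2$percent[d2$time_min == tm]
    if (length(g1) < 2L || length(g2) < 2L) {
      return(data.frame(time_min = tm, n1 = length(g1), n2 = length(g2),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stars = NA_character_, stringsAsFactors = FALSE))
    }
    cp <- compare_pairs(g1, g2, variant)
    data.frame(time_min = tm, n1 = length(g1), n2 = length(g2),
               t = cp$t, df = cp$df, p = cp$p, stars = signif_stars(cp$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time_min = numeric(0), n1 = integer(0), n2 = integer(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE)
  }
  out$pair1 <- paste(pair1, collapse = "|")
  out$pair2 <- paste(pair2, collapse = "|")
  out[c("pair1", "pair2", setdiff(names(out), c("pair1", "pair2")))]
}
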