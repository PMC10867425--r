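# Mitotic timing and event statistics: cumulative frequency, t50,
# per-replicate event fractions, and the standard hypothesis tests used to
# compare conditions.

#' Time by which half the cells complete a transition (t50)
#'
#' Reads the empirical cumulative step function at 0.5 without
#' interpolation: the smallest observed duration t with
#' \code{#(durations <= t) / n_total >= 0.5}. Cells that never reach the
#' event stay in the denominator (cumulative-frequency curves that plateau
#' below 100%); pass \code{n_total = length(durations)} for a
#' completers-only estimate.
#'
#' @param durations durations (min) of the cells that completed the event.
#' @param n_total number of cells observed (>= \code{length(durations)}).
#' @return the t50 in min, or \code{NA} with attribute
#'   \code{reached = FALSE} when fewer than half the cells complete.
#' @examples
#' t50(c(6, 12, 18, 24), 4)   # 12
#' @export
t50 <- function(durations, n_total = length(durations)) {
  if (n_total < 1) stop("t50: n_total must be >= 1")
  if (length(durations) > n_total)
    stop("t50: more completers than cells observed")
  if (length(durations) / n_total < 0.5)
    return(structure(NA_real_, reached = FALSE))
  ts <- sort(durations)
  frac <- seq_along(ts) / n_total
  structure(ts[match(TRUE, frac >= 0.5)], reached = TRUE)
}

#' Cumulative-frequency table of event times
#'
#' @param durations completer durations (min).
#' @param n_total denominator (all observed cells by default).
#' @return data.frame \code{time_min, cum_fraction}, one row per distinct
#'   observed time.
#' @export
cumulative_frequency <- function(durations, n_total = length(durations)) {
  ts <- sort(unique(durations))
  data.frame(time_min = ts,
             cum_fraction = vapply(ts, function(t)
               sum(durations <= t) / n_total, numeric(1)))
}

#' Per-replicate mitotic event fractions
#'
#' Computes the fraction of cells positive for each logical event column
#' within every replicate, then summarizes conditions by the mean across
#' replicates (one dot per independent experiment, as such data are
#' usually plotted) alongside the raw pooled fractions.
#'
#' @param records data.frame with \code{condition}, \code{replicate_id}
#'   and any subset of the logical columns \code{completed, congressed,
#'   maintained, lagging}.
#' @return list with \code{per_replicate} (one row per condition x
#'   replicate) and \code{summary} (per condition: \code{n_cells},
#'   \code{n_replicates}, and for each event \code{frac_<event>}, the mean
#'   of replicate fractions, and \code{pooled_<event>}).
#' @export
event_fractions <- function(records) {
  events <- intersect(c("completed", "congressed", "maintained", "lagging"),
                      names(records))
  if (nrow(records) == 0)
    return(list(per_replicate = data.frame(), summary = data.frame()))
  stopifnot("condition" %in% names(records),
            "replicate_id" %in% names(records), length(events) > 0)
  grp <- interaction(records$condition, records$replicate_id, drop = TRUE)
  per <- data.frame(
    condition = tapply(as.character(records$condition), grp, `[`, 1),
    replicate_id = tapply(as.character(records$replicate_id), grp, `[`, 1),
    n_cells = as.integer(tapply(records$condition, grp, length)))
  for (e in events)
    per[[paste0("frac_", e)]] <- as.numeric(tapply(records[[e]], grp, mean))
  rownames(per) <- NULL
  conds <- unique(per$condition)
  summ <- data.frame(condition = conds)
  summ$n_cells <- vapply(conds, function(cd)
    sum(records$condition == cd), integer(1))
  summ$n_replicates <- vapply(conds, function(cd)
    sum(per$condition == cd), integer(1))
  for (e in events) {
    summ[[paste0("frac_", e)]] <- vapply(conds, function(cd)
      mean(per[[paste0("frac_", e)]][per$condition == cd]), numeric(1))
    summ[[paste0("pooled_", e)]] <- vapply(conds, function(cd)
      mean(records[[e]][records$condition == cd]), numeric(1))
  }
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ)
}

#' Compare experimental groups with the study's standard tests
#'
#' Thin dispatcher over the standard two-sided tests: Mann-Whitney U
#' (exact when both groups have at most 8 observations and no ties,
#' otherwise the normal approximation with tie correction), chi-square on
#' a contingency table (no continuity correction), paired t, or one-way
#' ANOVA with Dunnett contrasts against the first (control) group.
#'
#' @param a first sample; for \code{"chi_square"} a contingency matrix;
#'   for \code{"anova_dunnett"} a named list of numeric vectors whose
#'   first element is the control.
#' @param b second sample (ignored for chi-square and ANOVA).
#' @param test one of \code{"mann_whitney"}, \code{"chi_square"},
#'   \code{"paired_t"}, \code{"anova_dunnett"}.
#' @return list \code{statistic}, \code{p}; for \code{"anova_dunnett"}
#'   also \code{dunnett}, a data.frame of per-comparison adjusted p
#'   values.
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("mann_whitney", "chi_square",
                                    "paired_t", "anova_dunnett")) {
  test <- match.arg(test)
  if (test == "mann_whitney") {
    if (length(a) < 1 || length(b) < 1)
      stop("compare_groups: both samples must be non-empty")
    exact <- length(a) <= 8 && length(b) <= 8
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = FALSE))
    return(list(statistic = unname(wt$statistic), p = wt$p.value))
  }
  if (test == "chi_square") {
    if (!is.matrix(a)) stop("compare_groups: chi_square needs a matrix")
    ct <- suppressWarnings(stats::chisq.test(a, correct = FALSE))
    return(list(statistic = unname(ct$statistic), p = ct$p.value))
  }
  if (test == "paired_t") {
    if (length(a) != length(b) || length(a) < 2)
      stop("compare_groups: paired_t needs two equal-length samples (n >= 2)")
    tt <- stats::t.test(a, b, paired = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value))
  }
  # anova_dunnett
  if (!is.list(a) || length(a) < 2)
    stop("compare_groups: anova_dunnett needs a list of >= 2 groups")
  if (is.null(names(a))) names(a) <- paste0("g", seq_along(a))
  df <- data.frame(y = unlist(a, use.names = FALSE),
                   g = factor(rep(names(a), lengths(a)), levels = names(a)))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(glht)
  dunnett <- data.frame(
    comparison = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    t = unname(sm$test$tstat),
    p_adj = unname(as.numeric(sm$test$pvalues)))
  list(statistic = an$`F value`[1], p = an$`Pr(>F)`[1], dunnett = dunnett)
}
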