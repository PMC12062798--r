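# Respiratory-function evaluation metrics from session traces: peak
# expiratory flow, mean tidal volume, minute ventilation with inspiratory /
# expiratory phase split, improvement rates and paired significance.

#' Segment a trace into complete breaths
#'
#' Offline analogue of the controller's binary phase segmentation: a
#' hysteresis state machine on the flow sign (expiration positive) marks
#' expiration and inspiration onsets; a complete breath runs from one
#' expiration onset to the next with an inspiration in between. Partial
#' first/last breaths are discarded.
#'
#' @param trace a `session_trace` (or any data frame with columns `t`, `Q`;
#'   a `V` column is used when present, otherwise volume is integrated from
#'   flow).
#' @param hysteresis flow threshold for phase flips, L/s; defaults to 2% of
#'   the peak absolute flow.
#' @param min_vol_frac artifact rejection: candidate expirations whose
#'   expired volume is below this fraction of the largest expired volume
#'   are flow flutter at phase boundaries, not breaths, and are merged into
#'   the surrounding cycle (default 0.1).
#' @return data frame with one row per complete breath: sample indices
#'   `cycle_start` (expiration onset), `exp_end` (last expiratory sample),
#'   `cycle_end` (last sample before the next expiration onset).
#' @export
segment_breaths <- function(trace, hysteresis = NULL, min_vol_frac = 0.1) {
  stopifnot(nrow(trace) > 0L)
  Q <- trace$Q
  empty <- data.frame(cycle_start = integer(), exp_end = integer(),
                      cycle_end = integer())
  if (is.null(hysteresis)) hysteresis <- 0.02 * max(abs(Q))
  if (max(abs(Q)) == 0 || hysteresis <= 0) return(empty)
  V <- if (!is.null(trace$V)) trace$V else
    cumsum(c(0, diff(trace$t) * (Q[-length(Q)] + Q[-1L]) / 2))
  phase <- 0L  # 0 unknown, 1 expiration, -1 inspiration
  exp_on <- integer(); insp_on <- integer()
  for (i in seq_along(Q)) {
    if (phase != 1L && Q[i] > hysteresis) {
      phase <- 1L; exp_on <- c(exp_on, i)
    } else if (phase != -1L && Q[i] < -hysteresis) {
      if (phase == 1L) insp_on <- c(insp_on, i)
      phase <- -1L
    }
  }
  if (length(exp_on) < 2L) return(empty)
  # expired volume of each candidate expiration (onset to its insp onset)
  cand_vol <- vapply(exp_on, function(o) {
    m <- insp_on[insp_on > o]
    if (length(m)) V[m[1L] - 1L] - V[o] else NA_real_
  }, numeric(1))
  ok <- !is.na(cand_vol) & cand_vol >= min_vol_frac * max(cand_vol,
                                                          na.rm = TRUE)
  # the trailing onset may have no inspiration yet; keep it as a boundary
  ok[is.na(cand_vol)] <- TRUE
  exp_on <- exp_on[ok]
  if (length(exp_on) < 2L) return(empty)
  n <- length(exp_on) - 1L
  cs <- exp_on[seq_len(n)]; ce <- exp_on[-1L] - 1L
  ee <- integer(n); keep <- logical(n)
  for (k in seq_len(n)) {
    m <- insp_on[insp_on > cs[k] & insp_on <= ce[k] + 1L]
    if (length(m) >= 1L) { ee[k] <- m[1L] - 1L; keep[k] <- TRUE }
  }
  data.frame(cycle_start = cs[keep], exp_end = ee[keep],
             cycle_end = ce[keep])
}

#' Ventilation metrics of a session
#'
#' Computes the evaluation metrics over the complete breaths of a trace:
#' \describe{
#'   \item{PEF}{peak expiratory flow, the session maximum of expiratory
#'     flow, L/s (per-breath mean of maxima under `pef_per_breath`).}
#'   \item{MTV}{mean tidal volume: per-breath difference between
#'     end-expiratory and end-inspiratory lung volume, averaged, L.}
#'   \item{MV}{minute ventilation: total expired volume normalised to one
#'     minute, L/min (expiration-side convention; conventions vary, so the
#'     phase-split values are always reported alongside).}
#'   \item{MV_e, MV_i}{phase-split minute ventilation from expired and
#'     inspired volumes separately.}
#' }
#'
#' @param trace a `session_trace`.
#' @param hysteresis passed to [segment_breaths()].
#' @param pef_per_breath report the mean of per-breath flow maxima instead
#'   of the session maximum.
#' @return an object of class `metrics_report`.
#' @examples
#' \donttest{
#' s <- subject_from_table("S2")
#' tr <- run_session(s, spec = session_spec("natural", 12, 30), noise = FALSE)
#' compute_metrics(tr)
#' }
#' @export
compute_metrics <- function(trace, hysteresis = NULL,
                            pef_per_breath = FALSE) {
  br <- segment_breaths(trace, hysteresis)
  if (nrow(br) < 1L)
    stop("no complete breath in trace", call. = FALSE)
  Q <- trace$Q; V <- trace$V; t <- trace$t
  n <- nrow(br)
  tv <- exp_vol <- insp_vol <- pef_k <- numeric(n)
  for (k in seq_len(n)) {
    cs <- br$cycle_start[k]; ee <- br$exp_end[k]; ce <- br$cycle_end[k]
    pef_k[k] <- max(Q[cs:ee])
    exp_vol[k] <- V[ee] - V[cs]
    insp_vol[k] <- V[ee] - V[ce]        # volume re-inspired after expiration
    tv[k] <- V[ee] - V[ce]              # end-expiratory minus end-inspiratory
  }
  dur <- t[br$cycle_end[n]] - t[br$cycle_start[1L]]
  rate_obs <- n / dur * 60
  structure(list(pef = if (pef_per_breath) mean(pef_k) else max(pef_k),
                 mtv = mean(tv),
                 mv = sum(exp_vol) / dur * 60,
                 mv_exp = sum(exp_vol) / dur * 60,
                 mv_insp = sum(insp_vol) / dur * 60,
                 n_breaths = n, rate_observed = rate_obs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Ventilation metrics over %d breaths (%.3g breaths/min observed):\n",
              x$n_breaths, x$rate_observed))
  cat(sprintf("  PEF %.4g L/s, MTV %.4g L, MV %.4g L/min (MVe %.4g, MVi %.4g)\n",
              x$pef, x$mtv, x$mv, x$mv_exp, x$mv_insp))
  invisible(x)
}

#' Baseline-to-assisted improvement rates
#'
#' Percent change (assisted - baseline)/baseline * 100 for each metric.
#'
#' @param baseline,assisted `metrics_report` objects from a matched pair.
#' @return an object of class `improvement_report`: a data frame with one
#'   row per metric (`pef`, `mtv`, `mv`, `mv_exp`, `mv_insp`).
#' @export
improvement_rates <- function(baseline, assisted) {
  met <- c("pef", "mtv", "mv", "mv_exp", "mv_insp")
  b <- unlist(baseline[met]); a <- unlist(assisted[met])
  if (any(b <= 0)) stop("baseline metrics must be positive", call. = FALSE)
  structure(data.frame(metric = met, baseline = unname(b),
                       assisted = unname(a),
                       pct_change = unname((a - b) / b * 100)),
            class = c("improvement_report", "data.frame"))
}

#' Paired significance of cohort improvements
#'
#' Two-sided paired test per metric across subjects, with the conventional
#' star coding (* p < 0.05, ** p < 0.01, *** p < 0.001). Identical vectors
#' give p = 1 and no stars; a constant nonzero shift (zero variance of the
#' differences) is flagged degenerate rather than tested.
#'
#' @param baseline,assisted numeric matrices or data frames with one row
#'   per subject and one column per metric (>= 3 rows).
#' @param test `"t"` (paired t-test, default) or `"wilcoxon"`.
#' @return data frame with columns `metric`, `mean_diff`, `p_value`,
#'   `stars`, `degenerate`.
#' @export
paired_significance <- function(baseline, assisted, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  baseline <- as.matrix(baseline); assisted <- as.matrix(assisted)
  stopifnot(all(dim(baseline) == dim(assisted)))
  if (nrow(baseline) < 3L) stop("need at least 3 subject pairs", call. = FALSE)
  mets <- colnames(baseline)
  if (is.null(mets)) mets <- paste0("m", seq_len(ncol(baseline)))
  out <- data.frame(metric = mets, mean_diff = NA_real_, p_value = NA_real_,
                    stars = "", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(baseline))) {
    d <- assisted[, j] - baseline[, j]
    out$mean_diff[j] <- mean(d)
    if (all(d == 0)) {
      out$p_value[j] <- 1
    } else if (stats::sd(d) <= 1e-10 * abs(mean(d))) {
      out$degenerate[j] <- TRUE
    } else {
      out$p_value[j] <- if (test == "t")
        stats::t.test(assisted[, j], baseline[, j], paired = TRUE)$p.value
      else
        stats::wilcox.test(assisted[, j], baseline[, j], paired = TRUE,
                           exact = FALSE)$p.value
      out$stars[j] <- if (out$p_value[j] < 0.001) "***"
        else if (out$p_value[j] < 0.01) "**"
        else if (out$p_value[j] < 0.05) "*" else ""
    }
  }
  out
}

#' Cohort crossover summary
#'
#' Metrics and improvement rates for every matched pair of a crossover set
#' (or a list of them, one per subject), aggregated per rate.
#'
#' @param sets a `crossover_set` or list of them.
#' @return data frame with one row per subject x rate x rep x metric.
#' @export
crossover_summary <- function(sets) {
  if (inherits(sets, "crossover_set")) sets <- list(sets)
  rows <- list()
  for (cs in sets) {
    sid <- attr(cs, "subject_id")
    for (pair in cs) {
      imp <- improvement_rates(compute_metrics(pair$baseline),
                               compute_metrics(pair$assisted))
      imp$subject <- sid; imp$rate <- pair$rate; imp$rep <- pair$rep
      rows[[length(rows) + 1L]] <- imp
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}
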