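#' Label calls as true or false positives against simulation truth
#'
#' A call is a true positive when it lies within `window_bp` base pairs of a
#' true QTN on the same chromosome. Each QTN is credited at most once per
#' replicate: the closest call wins, distance ties break toward the larger
#' `|effect|`, and a call can credit only one QTN. Every other call is a
#' false positive.
#'
#' @param calls Data frame with `chrom`, `pos`, `effect` (and any score
#'   columns, carried through).
#' @param truth Data frame with `chrom`, `pos` (one row per true QTN).
#' @param window_bp Matching half-window in bp (default 1000).
#' @return `calls` with added logical column `tp` and integer column
#'   `qtn` (credited truth row, `NA` for false positives).
#' @export
match_calls <- function(calls, truth, window_bp = 1000L) {
  calls <- as.data.frame(calls)
  truth <- as.data.frame(truth)
  nc <- nrow(calls)
  calls$tp <- rep(FALSE, nc)
  calls$qtn <- rep(NA_integer_, nc)
  if (nc == 0L || nrow(truth) == 0L) return(calls)
  pairs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(t_) {
    same <- which(as.character(calls$chrom) == as.character(truth$chrom[t_]))
    d <- abs(calls$pos[same] - truth$pos[t_])
    ok <- d <= window_bp
    if (!any(ok)) return(NULL)
    data.frame(call = same[ok], qtn = t_, dist = d[ok],
               eff = abs(calls$effect[same[ok]]))
  }))
  if (is.null(pairs)) return(calls)
  pairs <- pairs[order(pairs$dist, -pairs$eff), , drop = FALSE]
  used_call <- logical(nc)
  used_qtn <- logical(nrow(truth))
  for (r in seq_len(nrow(pairs))) {
    ci <- pairs$call[r]
    qi <- pairs$qtn[r]
    if (!used_call[ci] && !used_qtn[qi]) {
      used_call[ci] <- TRUE
      used_qtn[qi] <- TRUE
      calls$tp[ci] <- TRUE
      calls$qtn[ci] <- qi
    }
  }
  calls
}

#' Per-QTN mean squared error of effect estimates
#'
#' `MSE_i = (1/R_i) * sum_s (beta_hat_is - beta_i)^2` over the `R_i`
#' replicates in which QTN i was detected; the average MSE is the
#' unweighted mean over QTNs detected at least once. QTNs never detected
#' have `NA` MSE and are excluded from the average.
#'
#' @param estimates Data frame with columns `qtn` (truth row index) and
#'   `effect` (the estimate), pooled over replicates.
#' @param truth_effects Numeric vector of true effects, indexed by `qtn`.
#' @return List with `per_qtn` (data frame `qtn`, `r_i`, `mse`) and
#'   `average` (scalar).
#' @export
compute_mse <- function(estimates, truth_effects) {
  k <- length(truth_effects)
  mse <- rep(NA_real_, k)
  r_i <- integer(k)
  for (q in seq_len(k)) {
    est <- estimates$effect[estimates$qtn == q & !is.na(estimates$qtn)]
    r_i[q] <- length(est)
    if (r_i[q] >= 1L)
      mse[q] <- mean((est - truth_effects[q])^2)
  }
  list(per_qtn = data.frame(qtn = seq_len(k), r_i = r_i, mse = mse),
       average = mean(mse, na.rm = TRUE))
}

#' Markers falling in QTN areas
#'
#' Counts map markers within `window_bp` of any true QTN (the "QTN area"),
#' the complement of the false-positive-rate denominator.
#'
#' @param map Marker map (`chrom`, `pos`).
#' @param truth Truth data frame (`chrom`, `pos`).
#' @param window_bp Half-window in bp (default 1000).
#' @return Integer count.
#' @export
qtn_area_size <- function(map, truth, window_bp = 1000L) {
  inarea <- rep(FALSE, nrow(map))
  for (t_ in seq_len(nrow(truth))) {
    inarea <- inarea |
      (as.character(map$chrom) == as.character(truth$chrom[t_]) &
         abs(map$pos - truth$pos[t_]) <= window_bp)
  }
  sum(inarea)
}

#' False positive rate over non-QTN markers
#'
#' FPR = (false-positive calls) / (markers outside every QTN area), pooled
#' over replicates: pass the summed FP count and multiply the denominator
#' by the number of replicates yourself, or call once per replicate.
#'
#' @param labeled Labeled calls from [match_calls()] (or anything with a
#'   logical `tp` column), pooled.
#' @param m Total number of markers scanned (pooled over replicates if
#'   `labeled` is pooled).
#' @param n_qtn_area Markers inside QTN areas (same pooling).
#' @return Scalar FPR in `[0, 1]`.
#' @export
compute_fpr <- function(labeled, m, n_qtn_area) {
  stopifnot(m > n_qtn_area)
  sum(!labeled$tp) / (m - n_qtn_area)
}

#' Power-versus-FDR (or Type I error) curve and its AUC
#'
#' Sweeps a detection threshold over the full observed score range (LOD by
#' default: calls with `score >= t` are accepted). At each threshold, power
#' is the fraction of QTN-replicate pairs detected, FDR is FP/(FP+TP)
#' pooled, and Type I error is FP divided by the pooled number of non-QTN
#' markers. The area under the sorted (x, power) curve is computed by the
#' trapezoid rule, both on the observed x-range as-is (`auc`) and
#' normalized by that range's width (`auc_norm`); a single-point curve has
#' zero area and triggers a warning.
#'
#' @param replicates List with one element per replicate: a labeled call
#'   data frame (from [match_calls()]) with a `score` column.
#' @param n_qtn Number of true QTNs per replicate.
#' @param n_negative Number of non-QTN markers per replicate (Type I error
#'   denominator).
#' @param mode `"fdr"` or `"type1"` for the x-axis.
#' @return List with `curve` (data frame `threshold`, `x`, `power`),
#'   `auc`, and `auc_norm`.
#' @export
power_curves <- function(replicates, n_qtn, n_negative,
                         mode = c("fdr", "type1")) {
  mode <- match.arg(mode)
  all_calls <- do.call(rbind, lapply(replicates, function(d)
    d[, c("score", "tp", "qtn"), drop = FALSE]))
  n_rep <- length(replicates)
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    warning("no calls at any threshold; degenerate curve")
    return(list(curve = data.frame(threshold = numeric(), x = numeric(),
                                   power = numeric()),
                auc = 0, auc_norm = 0))
  }
  thresholds <- sort(unique(all_calls$score), decreasing = TRUE)
  pts <- t(vapply(thresholds, function(th) {
    acc <- all_calls$score >= th
    tp <- sum(acc & all_calls$tp)
    fp <- sum(acc & !all_calls$tp)
    power <- tp / (n_qtn * n_rep)
    x <- if (mode == "fdr") {
      if (tp + fp > 0) fp / (tp + fp) else 0
    } else {
      fp / (n_negative * n_rep)
    }
    c(x = x, power = power)
  }, numeric(2)))
  curve <- data.frame(threshold = thresholds, x = pts[, "x"],
                      power = pts[, "power"])
  ord <- order(curve$x, curve$power)
  xs <- curve$x[ord]
  ps <- cummax(curve$power[ord])  # best achievable power at each x
  if (length(unique(xs)) < 2L) {
    warning("single-point curve; AUC of a point is 0")
    return(list(curve = curve, auc = 0, auc_norm = 0))
  }
  auc <- sum(diff(xs) * (utils::head(ps, -1) + utils::tail(ps, -1)) / 2)
  list(curve = curve, auc = auc,
       auc_norm = auc / (max(xs) - min(xs)))
}
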