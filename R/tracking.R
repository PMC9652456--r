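#' Match ROIs across two sessions by centroid position
#'
#' Finds the one-to-one assignment between the two centroid sets that
#' minimises total gated centroid distance (Hungarian algorithm on costs
#' capped at the threshold, so cells with no partner within `max_dist_px`
#' never pull a genuine close pair apart), then drops pairs farther apart
#' than `max_dist_px`. Matching by position stands in for manual cross-day
#' identification of cells by structure and relative position within the
#' field of view.
#'
#' @param centroidsA,centroidsB Numeric matrices, cells x 2 (row, col).
#' @param max_dist_px Maximum accepted centroid distance, pixels (default 3).
#' @return A `cell_match`: list with `pairs` (data frame `idA`, `idB`,
#'   `dist_px`), `unmatched_a`, `unmatched_b`.
#' @export
match_rois <- function(centroidsA, centroidsB, max_dist_px = 3) {
  a <- as.matrix(centroidsA); b <- as.matrix(centroidsB)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(structure(list(pairs = data.frame(idA = integer(0),
                                             idB = integer(0),
                                             dist_px = numeric(0)),
                          unmatched_a = seq_len(nrow(a)),
                          unmatched_b = seq_len(nrow(b))),
                     class = "cell_match"))
  }
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("centroids must be finite", call. = FALSE)
  d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") -
                   2 * tcrossprod(a, b), 0))
  flip <- nrow(d) > ncol(d)
  # gate: beyond-threshold pairs all cost the same, so the solver prefers
  # any genuine sub-threshold pair and far assignments are interchangeable
  cost <- pmin(if (flip) t(d) else d, max_dist_px + 1)
  asg <- solve_assignment(cost)
  rows <- seq_len(nrow(cost))
  idA <- if (flip) asg else rows
  idB <- if (flip) rows else asg
  dist <- d[cbind(idA, idB)]
  keep <- dist <= max_dist_px
  pairs <- data.frame(idA = idA[keep], idB = idB[keep],
                      dist_px = dist[keep])
  pairs <- pairs[order(pairs$idA), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(nrow(a)), pairs$idA),
                 unmatched_b = setdiff(seq_len(nrow(b)), pairs$idB)),
            class = "cell_match")
}

#' @export
print.cell_match <- function(x, ...) {
  cat(sprintf("<cell_match> %d matched pairs (%d / %d unmatched)\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Response adaptation of tracked cells across two sessions
#'
#' For every matched cell, the mean trial-averaged z-score over the response
#' segment (0 to `response_window_s` s post-press) is computed in each
#' session; the per-cell delta (B minus A), per-ensemble aggregates, and the
#' Pearson correlation of per-cell responses across sessions quantify how
#' responses adapt (e.g. drug-induced attenuation of excited and inhibited
#' ensembles).
#'
#' @param tensorA,tensorB `peri_event_tensor`s for the two sessions (same
#'   window spec).
#' @param match A `cell_match` from [match_rois()].
#' @param ensembles Optional per-cell ensemble labels for session A (full
#'   population, indexed by `idA`).
#' @param response_window_s Response segment length, seconds.
#' @return An `adaptation_result`: list with `per_cell` (data frame `idA`,
#'   `idB`, `ensemble`, `response_a`, `response_b`, `delta`),
#'   `per_ensemble` (data frame of mean responses and deltas), `pearson_r`,
#'   `pearson_p`.
#' @export
response_adaptation <- function(tensorA, tensorB, match, ensembles = NULL,
                                response_window_s = 3) {
  stopifnot(inherits(tensorA, "peri_event_tensor"),
            inherits(tensorB, "peri_event_tensor"),
            inherits(match, "cell_match"))
  if (!all(tensorA$window == tensorB$window))
    stop("tensors must share the window spec", call. = FALSE)
  if (nrow(match$pairs) == 0)
    stop("empty match: no tracked cells", call. = FALSE)
  mean_resp <- function(tensor) {
    avg <- trial_average(tensor)
    seg <- tensor$timepoints_s >= 0 & tensor$timepoints_s < response_window_s
    rowMeans(avg[, seg, drop = FALSE])
  }
  ra <- mean_resp(tensorA)[match$pairs$idA]
  rb <- mean_resp(tensorB)[match$pairs$idB]
  ens <- if (is.null(ensembles)) rep("all", nrow(match$pairs)) else
    as.character(ensembles[match$pairs$idA])
  per_cell <- data.frame(idA = match$pairs$idA, idB = match$pairs$idB,
                         ensemble = ens, response_a = ra, response_b = rb,
                         delta = rb - ra)
  per_ensemble <- do.call(rbind, lapply(split(per_cell, per_cell$ensemble),
    function(d) data.frame(ensemble = d$ensemble[1], n = nrow(d),
                           mean_a = mean(d$response_a),
                           mean_b = mean(d$response_b),
                           mean_delta = mean(d$delta))))
  rownames(per_ensemble) <- NULL
  if (length(ra) >= 3 && sd(ra) > 0 && sd(rb) > 0) {
    ct <- stats::cor.test(ra, rb)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  structure(list(per_cell = per_cell, per_ensemble = per_ensemble,
                 pearson_r = r, pearson_p = p),
            class = "adaptation_result")
}
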