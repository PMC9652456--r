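#' Build a peri-event tensor around active lever presses
#'
#' Slices every neuron's trace into windows aligned to active lever presses:
#' `pre_s` seconds before the press, `mid_s` seconds between press and
#' sucrose delivery, and `post_s` seconds after delivery (defaults 10/3/10,
#' the 23-s window). Trials whose window would run off either end of the
#' session are excluded and counted. Each neuron is z-scored against its own
#' baseline segment, -10 to -5 s pre-press, pooled across trials; that early
#' segment is used because activity immediately pre-press can already carry
#' approach-related signal.
#'
#' @param traces A [trace_matrix()].
#' @param events An `event_log`; its `press_active` events define trials.
#' @param pre_s,mid_s,post_s Window segments, seconds.
#' @param baseline_window Length-2 vector, baseline segment for z-scoring in
#'   seconds relative to the press (default `c(-10, -5)`).
#' @param zscore Apply baseline z-scoring (default `TRUE`). Neurons whose
#'   baseline SD is numerically zero fall back to unit SD (values are then
#'   baseline-centred only).
#' @return A `peri_event_tensor`: list with `values` (neuron x trial x
#'   timepoint array of z-scores), `window`, `frame_rate_hz`, `event_times`
#'   (used trials), `n_excluded`, and the per-neuron `baseline_mean`,
#'   `baseline_sd`.
#' @export
build_peri_event_tensor <- function(traces, events, pre_s = 10, mid_s = 3,
                                    post_s = 10,
                                    baseline_window = c(-10, -5),
                                    zscore = TRUE) {
  fr <- frame_rate(traces)
  n <- nrow(traces); n_frames <- ncol(traces)
  n_t <- round((pre_s + mid_s + post_s) * fr)
  press <- active_press_times(events)
  if (length(press) == 0) stop("no usable events: empty tensor", call. = FALSE)
  press_frame <- round(press * fr) + 1L
  start <- press_frame - round(pre_s * fr)
  keep <- start >= 1L & (start + n_t - 1L) <= n_frames
  n_excluded <- sum(!keep)
  if (!any(keep))
    stop("no usable events: all trials have incomplete windows",
         call. = FALSE)
  start <- start[keep]
  n_trials <- length(start)
  vals <- array(NA_real_, dim = c(n, n_trials, n_t))
  m <- unclass(traces)
  for (j in seq_len(n_trials))
    vals[, j, ] <- m[, start[j]:(start[j] + n_t - 1L), drop = FALSE]
  # baseline segment indices within the window (times relative to press)
  tp <- (seq_len(n_t) - 1L) / fr - pre_s
  b_idx <- which(tp >= baseline_window[1] & tp < baseline_window[2])
  bmat <- matrix(vals[, , b_idx], nrow = n)   # neurons x (trials*timepoints)
  b_mean <- rowMeans(bmat)
  b_sd <- apply(bmat, 1, sd)
  if (zscore) {
    sd_use <- ifelse(b_sd < 1e-12, 1, b_sd)
    vals <- (vals - b_mean) / sd_use
  }
  structure(list(values = vals,
                 window = c(pre_s = pre_s, mid_s = mid_s, post_s = post_s),
                 frame_rate_hz = fr, event_times = press[keep],
                 n_excluded = n_excluded, baseline_mean = b_mean,
                 baseline_sd = b_sd, timepoints_s = tp),
            class = "peri_event_tensor")
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<peri_event_tensor> %d neurons x %d trials x %d timepoints (%g s window, %d trials excluded)\n",
    d[1], d[2], d[3], sum(x$window), x$n_excluded))
  invisible(x)
}

#' Trial-averaged response matrix
#'
#' @param tensor A `peri_event_tensor`.
#' @return A neuron x timepoint matrix of trial-mean values.
#' @export
trial_average <- function(tensor) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  apply(tensor$values, c(1, 3), mean)
}

#' Select the number of principal components at the scree knee
#'
#' Runs PCA on the trial-averaged neuron x timepoint matrix (neurons as
#' observations) and picks the component count at the inflection of the
#' explained-variance-ratio scree curve, operationalised as the index `i`
#' maximising the discrete curvature `r_i - 2 r_{i+1} + r_{i+2}`. At least 2
#' components are always retained; when the curve has no clear knee
#' (curvature below `min_curvature` everywhere) the minimum is returned with
#' a warning.
#'
#' @param trial_avg_matrix Neuron x timepoint matrix (>= 3 neurons), e.g.
#'   from [trial_average()].
#' @param max_components Cap on components examined (default 30).
#' @param min_curvature Curvature below which the knee is declared unclear.
#' @return A list: `n_components`, `explained_variance_ratio`, `pca`
#'   (the `prcomp` fit), `scores` (neuron x `n_components`).
#' @export
select_n_components <- function(trial_avg_matrix, max_components = 30,
                                min_curvature = 0.01) {
  x <- as.matrix(trial_avg_matrix)
  if (nrow(x) < 3) stop("need at least 3 neurons for PCA", call. = FALSE)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pca$sdev^2
  if (sum(v) == 0) stop("degenerate input: zero variance", call. = FALSE)
  evr <- v / sum(v)
  m <- min(length(evr), max_components)
  r <- evr[seq_len(m)]
  if (sum(r > 1e-12) < 2) {
    warning("degenerate scree (effective rank < 2): n_components = 1")
    n_star <- 1L
  } else if (m < 3) {
    n_star <- 2L
  } else {
    curv <- r[seq_len(m - 2)] - 2 * r[seq_len(m - 2) + 1] + r[seq_len(m - 2) + 2]
    if (max(curv) < min_curvature) {
      warning("no clear scree knee; using the enforced minimum of 2 components")
      n_star <- 2L
    } else {
      n_star <- max(2L, which.max(curv))
    }
  }
  list(n_components = n_star, explained_variance_ratio = evr, pca = pca,
       scores = pca$x[, seq_len(max(n_star, 1L)), drop = FALSE])
}

#' Spectral clustering of neurons into ensembles
#'
#' Clusters neurons in principal-component score space: a symmetric
#' k-nearest-neighbour connectivity graph is built on the scores, the
#' symmetric normalized graph Laplacian is eigendecomposed, and k-means
#' (10 restarts, seeded) is run on the row-normalized k smallest-eigenvalue
#' eigenvectors.
#'
#' @param component_scores Neuron x component score matrix.
#' @param k Number of clusters (>= 2); default 3 ensembles.
#' @param knn Neighbourhood size; default `round(sqrt(n_neurons))`.
#' @param seed Seed for k-means restarts.
#' @return A list: `cluster` (per-neuron id in 1..k), `k`, `knn`,
#'   `eigenvalues` (k smallest), `scores` (the input).
#' @export
cluster_ensembles <- function(component_scores, k = 3, knn = NULL,
                              seed = 1L) {
  x <- as.matrix(component_scores)
  n <- nrow(x)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n <= k) stop("need more neurons than clusters", call. = FALSE)
  if (is.null(knn)) knn <- max(2L, round(sqrt(n)))
  if (knn >= n) stop("knn must be < number of neurons", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(knn + 1)]  # skip self
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))            # symmetric (union) connectivity
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  n_comp <- igraph::components(g)$no
  if (n_comp > k)
    stop("k-NN graph has ", n_comp, " connected components (> k = ", k,
         "); increase knn", call. = FALSE)
  deg <- rowSums(adj)
  d_inv_sqrt <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  l_sym <- diag(n) - (d_inv_sqrt * adj) %*% diag(d_inv_sqrt)
  eig <- eigen(l_sym, symmetric = TRUE)
  idx <- n:(n - k + 1)                # k smallest eigenvalues
  u <- eig$vectors[, idx, drop = FALSE]
  rn <- sqrt(rowSums(u^2))
  u <- u / ifelse(rn < 1e-12, 1, rn)
  km <- withr::with_seed(as.integer(seed),
                         kmeans(u, centers = k, nstart = 10, iter.max = 100))
  list(cluster = km$cluster, k = k, knn = knn,
       eigenvalues = rev(eig$values[idx]), scores = x)
}

#' Categorize clusters as excited, non-responding or inhibited
#'
#' For each cluster, the mean trial-averaged z-score over the response
#' segment (0 to `response_window_s` seconds post-press, default 3 s — the
#' press-to-delivery interval) is compared with a threshold: above `+theta`
#' excited, below `-theta` inhibited, otherwise non-responding.
#'
#' @param clustering Result of [cluster_ensembles()].
#' @param tensor The `peri_event_tensor` the scores came from.
#' @param theta Category threshold in z units (default 0.5).
#' @param response_window_s Response segment length after the press.
#' @return A list: `cluster_category` (per cluster), `category` (per
#'   neuron), `cluster_mean_z` (per cluster).
#' @export
categorize_clusters <- function(clustering, tensor, theta = 0.5,
                                response_window_s = 3) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  avg <- trial_average(tensor)
  tp <- tensor$timepoints_s
  seg <- which(tp >= 0 & tp < response_window_s)
  resp <- rowMeans(avg[, seg, drop = FALSE])
  kk <- clustering$k
  cl_mean <- vapply(seq_len(kk),
                    function(c) mean(resp[clustering$cluster == c]),
                    numeric(1))
  cat_of <- function(z) {
    if (z > theta) "excited" else if (z < -theta) "inhibited"
    else "non_responding"
  }
  cl_cat <- vapply(cl_mean, cat_of, character(1))
  list(cluster_category = cl_cat, category = cl_cat[clustering$cluster],
       cluster_mean_z = cl_mean)
}

#' Full ensemble-detection pipeline
#'
#' Peri-event tensor, PCA with scree-knee component selection, spectral
#' clustering, and category assignment in one call.
#'
#' @inheritParams build_peri_event_tensor
#' @inheritParams cluster_ensembles
#' @param theta Category threshold, z units.
#' @return A list combining the clustering, categories, component selection
#'   and tensor (`cluster`, `category`, `cluster_category`, `n_components`,
#'   `explained_variance_ratio`, `scores`, `tensor`).
#' @export
detect_ensembles <- function(traces, events, k = 3, knn = NULL, seed = 1L,
                             theta = 0.5, pre_s = 10, mid_s = 3,
                             post_s = 10) {
  tensor <- build_peri_event_tensor(traces, events, pre_s, mid_s, post_s)
  sel <- select_n_components(trial_average(tensor))
  clustering <- cluster_ensembles(sel$scores, k = k, knn = knn, seed = seed)
  cats <- categorize_clusters(clustering, tensor, theta = theta)
  c(clustering[c("cluster", "k", "knn")],
    cats,
    list(n_components = sel$n_components,
         explained_variance_ratio = sel$explained_variance_ratio,
         scores = sel$scores, tensor = tensor))
}

#' Tonic (basal) fluorescence across a session
#'
#' Averages each neuron's trace in consecutive time bins (default 3 min) and
#' normalizes either each neuron to its own first bin
#' (`first_bin_per_neuron`) or every neuron to the population-mean first bin
#' (`population_baseline`). Sessions vary in length, so the first-vs-last
#' bin contrast is returned per neuron alongside the population trajectory.
#'
#' @param traces A [trace_matrix()].
#' @param bin_s Bin length, seconds (default 180).
#' @param normalize Normalization mode.
#' @return A list: `bins` (neuron x bin matrix, normalized), `bin_s`,
#'   `normalize`, `first_last` (data frame with per-neuron `first`, `last`,
#'   `ratio`), `population_mean` (per-bin mean across neurons).
#' @export
tonic_bins <- function(traces, bin_s = 180,
                       normalize = c("first_bin_per_neuron",
                                     "population_baseline")) {
  normalize <- match.arg(normalize)
  fr <- frame_rate(traces)
  m <- unclass(traces)
  frames_per_bin <- round(bin_s * fr)
  n_bins <- floor(ncol(m) / frames_per_bin)
  if (n_bins < 2)
    stop("session shorter than 2 bins of ", bin_s, " s", call. = FALSE)
  bins <- vapply(seq_len(n_bins), function(b) {
    idx <- ((b - 1) * frames_per_bin + 1):(b * frames_per_bin)
    rowMeans(m[, idx, drop = FALSE])
  }, numeric(nrow(m)))
  bins <- matrix(bins, nrow = nrow(m))
  base <- switch(normalize,
                 first_bin_per_neuron = bins[, 1],
                 population_baseline = rep(mean(bins[, 1]), nrow(bins)))
  if (any(base <= 0))
    stop("non-positive first-bin baseline for neuron(s): ",
         paste(which(base <= 0), collapse = ", "), call. = FALSE)
  bins <- bins / base
  list(bins = bins, bin_s = bin_s, normalize = normalize,
       first_last = data.frame(first = bins[, 1], last = bins[, n_bins],
                               ratio = bins[, n_bins] / bins[, 1]),
       population_mean = colMeans(bins))
}
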