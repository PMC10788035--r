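# Hyperparameter tuning (elbow + silhouette curves) and PCA embedding.

#' Tune a clustering algorithm over a hyperparameter grid
#'
#' For cluster-count algorithms (\code{kmeans}, \code{agglomerative},
#' \code{spectral}, \code{birch}) the SSE-vs-k (elbow) and silhouette-vs-k
#' curves are produced; the selected k is the silhouette argmax subject to a
#' degeneracy guard: k = 2 is rejected when its SSE is still large relative
#' to the unclustered total (SSE(2) > \code{sse_ratio} * SSE(1)), in which
#' case the next-best silhouette wins. For density/bandwidth-style
#' algorithms (\code{meanshift}, \code{dbscan}, \code{optics},
#' \code{affinity_propagation}) a silhouette-vs-hyperparameter curve is
#' emitted and its argmax reported.
#'
#' @param fps 0/1 fingerprint matrix.
#' @param algorithm algorithm name (see \code{\link{run_clustering}}).
#' @param search named list with one entry: the grid to scan (\code{k},
#'   \code{bandwidth}, \code{eps}, \code{min_samples} or
#'   \code{preference}). Defaults to \code{k = 2:min(10, n-1)} for count
#'   algorithms and distance-quantile grids otherwise.
#' @param seed integer seed for all stochastic steps.
#' @param sse_ratio the k = 2 degeneracy threshold (default 0.5).
#' @return Object of class \code{lsr_tuning}: \code{best}
#'   (an \code{lsr_clustering}), \code{best_param}, \code{curves} (data
#'   frame of parameter, k, sse, silhouette), \code{algorithm}.
#' @export
tune_clusters <- function(fps, algorithm, search = NULL, seed = 1,
                          sse_ratio = 0.5) {
  algorithm <- match.arg(algorithm, .ALL_ALGOS)
  fps <- as.matrix(fps)
  n <- nrow(fps)
  if (n < 3) stop("tune_clusters: need at least 3 observations")
  E <- euclid_matrix(fps)
  qs <- function(p) stats::quantile(E[upper.tri(E)], p, names = FALSE)
  count_algo <- algorithm %in% .COUNT_ALGOS

  if (is.null(search) || !length(search)) {
    search <- if (count_algo) list(k = 2:min(10L, n - 1L))
    else switch(algorithm,
      meanshift = list(bandwidth = qs(seq(0.1, 0.9, by = 0.1))),
      dbscan = list(eps = qs(seq(0.05, 0.75, by = 0.1))),
      optics = list(min_samples = 2:min(10L, n - 1L)),
      affinity_propagation = list(preference = -qs(seq(0.1, 0.9, by = 0.2))^2))
  }
  if (length(search) != 1L)
    stop("tune_clusters: search must name exactly one hyperparameter")
  pname <- names(search)
  values <- search[[1]]
  if (!length(values)) stop("tune_clusters: empty search grid")
  if (count_algo && pname != "k")
    stop(sprintf("tune_clusters: %s is tuned over k", algorithm))

  reports <- lapply(values, function(v) {
    params <- stats::setNames(list(v), pname)
    tryCatch(run_clustering(fps, algorithm, params = params, seed = seed),
             error = function(e) NULL)
  })
  curves <- data.frame(
    param = values,
    k = vapply(reports, function(r) if (is.null(r)) NA_integer_ else r$k, 0L),
    sse = vapply(reports, function(r) if (is.null(r)) NA_real_ else r$sse, 0),
    silhouette = vapply(reports, function(r)
      if (is.null(r)) NA_real_ else r$silhouette, 0))
  names(curves)[1] <- pname

  usable <- which(!vapply(reports, is.null, TRUE) &
                    !is.na(curves$silhouette) & curves$k >= 2)
  if (!length(usable)) {
    stop(sprintf(
      "tune_clusters: all candidates degenerate for %s; k values seen: %s",
      algorithm, paste(unique(curves$k), collapse = ",")))
  }

  pick <- usable[order(-curves$silhouette[usable])]
  if (count_algo) {
    sse_total <- labels_sse(fps, rep(1L, n))   # SSE at k = 1
    while (length(pick) > 1 && curves$k[pick[1]] == 2 &&
           !is.na(curves$sse[pick[1]]) &&
           curves$sse[pick[1]] > sse_ratio * sse_total) {
      pick <- pick[-1]       # retreat to the next-best silhouette
    }
  }
  best_i <- pick[1]
  structure(list(algorithm = algorithm, best = reports[[best_i]],
                 best_param = stats::setNames(values[best_i], pname),
                 curves = curves, seed = seed),
            class = "lsr_tuning")
}

#' @export
print.lsr_tuning <- function(x, ...) {
  cat(sprintf("<lsr_tuning %s> best %s = %s -> k %d, silhouette %.3f\n",
              x$algorithm, names(x$best_param),
              format(x$best_param, digits = 4), x$best$k,
              x$best$silhouette))
  invisible(x)
}

#' @export
plot.lsr_tuning <- function(x, ...) {
  cv <- x$curves
  pname <- names(cv)[1]
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (!all(is.na(cv$sse))) {
    plot(cv[[pname]], cv$sse, type = "b", xlab = pname, ylab = "SSE",
         main = sprintf("%s: elbow", x$algorithm))
  } else {
    plot(cv[[pname]], cv$k, type = "b", xlab = pname, ylab = "clusters k",
         main = sprintf("%s: cluster count", x$algorithm))
  }
  plot(cv[[pname]], cv$silhouette, type = "b", xlab = pname,
       ylab = "mean silhouette", main = "silhouette")
  abline(v = x$best_param, lty = 2)
  invisible(x)
}

#' PCA embedding of fingerprint vectors
#'
#' Principal-component projection of the centred fingerprint rows to 2 or 3
#' dimensions. Deterministic up to component sign; the sign is fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param fps 0/1 fingerprint matrix, n >= dims + 1 rows.
#' @param dims 2 or 3.
#' @return n x dims matrix of scores (columns \code{PC1}, ...).
#' @export
pca_embed <- function(fps, dims = 2) {
  fps <- as.matrix(fps)
  if (!dims %in% c(2, 3)) stop("pca_embed: dims must be 2 or 3")
  if (nrow(fps) < dims + 1)
    stop(sprintf("pca_embed: need at least %d rows", dims + 1))
  pc <- stats::prcomp(fps, center = TRUE, scale. = FALSE)
  d <- min(dims, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    v <- rot[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- pc$x[, seq_len(d), drop = FALSE] %*% diag(flip, d)
  if (d < dims)   # rank-deficient input: pad with zero coordinates
    scores <- cbind(scores, matrix(0, nrow(fps), dims - d))
  colnames(scores) <- paste0("PC", seq_len(dims))
  scores
}
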