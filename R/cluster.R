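# Unsupervised clustering of fingerprinted fragments. Vector-space
# algorithms run on the raw binary vectors (Euclidean geometry); the
# silhouette is always evaluated on the Tanimoto distance matrix so
# algorithms remain comparable. kmeans/hclust/specc come from
# stats/kernlab; mean-shift, DBSCAN, OPTICS, affinity propagation and a
# simplified BIRCH are implemented here.

euclid_matrix <- function(x) as.matrix(dist(x))

labels_sse <- function(x, labels) {
  x <- as.matrix(x)
  sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    ctr <- colMeans(xs)
    sum(sweep(xs, 2, ctr)^2)
  }, 0))
}

#' Mean silhouette coefficient on a distance matrix
#'
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} with \eqn{a(i)} the mean
#' within-cluster distance and \eqn{b(i)} the smallest mean distance to
#' another cluster; singleton clusters score 0.
#'
#' @param D symmetric distance matrix.
#' @param labels cluster labels (>= 2 distinct values).
#' @return Mean silhouette in [-1, 1].
#' @export
silhouette_mean <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.vector(labels)
  n <- nrow(D)
  if (length(labels) != n) stop("silhouette_mean: labels length != nrow(D)")
  ul <- unique(labels)
  if (length(ul) < 2) stop("silhouette_mean: need at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(ul, labels[i]), function(l)
      mean(D[i, labels == l]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# ---- in-package algorithm implementations ---------------------------------

lsr_meanshift <- function(x, bandwidth, max_iter = 100, tol = 1e-5) {
  x <- as.matrix(x)
  modes <- x
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(modes^2), rowSums(x^2), "+") - 2 * modes %*% t(x)
    w <- exp(-pmax(d2, 0) / (2 * bandwidth^2))
    new_modes <- (w %*% x) / rowSums(w)
    shift <- max(abs(new_modes - modes))
    modes <- new_modes
    if (shift < tol) break
  }
  # merge modes closer than bandwidth / 2
  labels <- integer(nrow(x))
  centers <- NULL
  for (i in seq_len(nrow(modes))) {
    if (is.null(centers)) { centers <- modes[i, , drop = FALSE]; labels[i] <- 1L; next }
    d <- sqrt(rowSums(sweep(centers, 2, modes[i, ])^2))
    j <- which.min(d)
    if (d[j] <= bandwidth / 2) labels[i] <- j
    else { centers <- rbind(centers, modes[i, ]); labels[i] <- nrow(centers) }
  }
  labels
}

lsr_dbscan <- function(D, eps, min_pts) {
  n <- nrow(D)
  labels <- rep(0L, n)        # 0 = noise
  visited <- logical(n)
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours[[i]]
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nb, i)
    while (length(seeds)) {
      j <- seeds[1]; seeds <- seeds[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours[[j]]
        if (length(nbj) >= min_pts) seeds <- union(seeds, setdiff(nbj, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

lsr_optics <- function(D, min_samples, eps_cl = NULL) {
  n <- nrow(D)
  core_dist <- vapply(seq_len(n), function(i)
    sort(D[i, ])[min_samples], 0)   # includes self at distance 0
  reach <- rep(Inf, n)
  processed <- logical(n)
  order_out <- integer(0)
  seeds <- integer(0)
  update_seeds <- function(i, seeds) {
    for (j in which(!processed)) {
      nr <- max(core_dist[i], D[i, j])
      if (nr < reach[j]) { reach[j] <<- nr; seeds <- union(seeds, j) }
    }
    seeds
  }
  while (any(!processed)) {
    i <- if (length(seeds)) {
      s <- seeds[which.min(reach[seeds])]; seeds <- setdiff(seeds, s); s
    } else which(!processed)[1]
    if (processed[i]) next
    processed[i] <- TRUE
    order_out <- c(order_out, i)
    seeds <- update_seeds(i, seeds)
  }
  if (is.null(eps_cl)) {
    fr <- reach[is.finite(reach)]
    eps_cl <- if (length(fr)) stats::median(fr) else Inf
  }
  # DBSCAN-style extraction from the reachability profile
  labels <- rep(0L, n)
  cl <- 0L
  for (i in order_out) {
    if (reach[i] > eps_cl) {
      if (core_dist[i] <= eps_cl) { cl <- cl + 1L; labels[i] <- cl }
    } else labels[i] <- max(cl, 1L)
  }
  labels
}

lsr_affinity_propagation <- function(S, damping = 0.9, max_iter = 300,
                                     conv_iter = 30) {
  n <- nrow(S)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; last <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    AS <- A + S
    first <- apply(AS, 1, max)
    which_first <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which_first)] <- -Inf
    second <- apply(AS2, 1, max)
    Rnew <- S - first
    Rnew[cbind(seq_len(n), which_first)] <- (S - second)[cbind(seq_len(n), which_first)]
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(rep(cs, each = n), n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R + A) > 0)
    if (!length(ex)) ex <- which.max(diag(R + A))
    labels <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    labels[ex] <- ex
    if (identical(labels, last)) stable <- stable + 1L else stable <- 0L
    last <- labels
    if (stable >= conv_iter) break
  }
  as.integer(factor(last))
}

lsr_birch <- function(x, threshold, k = NULL) {
  x <- as.matrix(x)
  # leader pass: incremental subclusters with a radius threshold
  centers <- x[1, , drop = FALSE]
  counts <- 1
  assign_sub <- integer(nrow(x)); assign_sub[1] <- 1L
  for (i in seq_len(nrow(x))[-1]) {
    d <- sqrt(rowSums(sweep(centers, 2, x[i, ])^2))
    j <- which.min(d)
    if (d[j] <= threshold) {
      centers[j, ] <- (centers[j, ] * counts[j] + x[i, ]) / (counts[j] + 1)
      counts[j] <- counts[j] + 1
      assign_sub[i] <- j
    } else {
      centers <- rbind(centers, x[i, ])
      counts <- c(counts, 1)
      assign_sub[i] <- nrow(centers)
    }
  }
  if (is.null(k) || k >= nrow(centers)) return(assign_sub)
  hc <- stats::hclust(dist(centers), method = "ward.D2")
  sub2cl <- stats::cutree(hc, k = k)
  sub2cl[assign_sub]
}

# ---- dispatcher ------------------------------------------------------------

.COUNT_ALGOS <- c("kmeans", "agglomerative", "spectral", "birch")
.ALL_ALGOS <- c(.COUNT_ALGOS, "meanshift", "optics", "affinity_propagation",
                "dbscan")

#' Run one clustering algorithm over a fingerprint set
#'
#' Supported algorithms: \code{kmeans} (k-means++-style multi-restart via
#' \code{stats::kmeans}, 20 restarts), \code{agglomerative}
#' (\code{hclust}/\code{cutree}), \code{spectral} (\pkg{kernlab}
#' \code{specc} on a Gaussian kernel), \code{birch} (simplified: leader
#' pass + Ward merge of subcluster centroids), \code{meanshift},
#' \code{optics}, \code{affinity_propagation} and \code{dbscan}
#' (in-package implementations). Vector-space algorithms take the binary
#' fingerprint rows with Euclidean geometry; \code{agglomerative},
#' \code{spectral}, \code{dbscan}, \code{optics} and
#' \code{affinity_propagation} accept a precomputed distance matrix
#' \code{D} instead. The silhouette is always computed on Tanimoto
#' distances when fingerprints are given, else on \code{D}.
#'
#' @param fps 0/1 fingerprint matrix (rows = molecules), or \code{NULL}.
#' @param algorithm algorithm name (see above).
#' @param params named list of hyperparameters (\code{k}, \code{bandwidth},
#'   \code{eps}, \code{min_pts}, \code{min_samples}, \code{threshold},
#'   \code{preference}, \code{linkage}).
#' @param seed integer seed; fixed seed gives reproducible labels.
#' @param D optional precomputed symmetric distance matrix.
#' @return Object of class \code{lsr_clustering}: \code{algorithm},
#'   \code{hyperparameters}, \code{labels}, \code{k}, \code{sse} (centroid
#'   algorithms, fingerprint space), \code{silhouette}, \code{n}.
#' @export
run_clustering <- function(fps = NULL, algorithm, params = list(), seed = 1,
                           D = NULL) {
  algorithm <- match.arg(algorithm, .ALL_ALGOS)
  if (is.null(fps) && is.null(D))
    stop("run_clustering: provide fingerprints or a distance matrix")
  n <- if (!is.null(fps)) nrow(fps) else nrow(D)
  if (n < 2) stop("run_clustering: need at least 2 observations")
  k_req <- params$k
  if (!is.null(k_req) && k_req > n)
    stop(sprintf("run_clustering: k = %d exceeds n = %d", k_req, n))
  E <- if (!is.null(fps)) euclid_matrix(fps) else D
  Dsil <- if (!is.null(fps)) tanimoto_distance_matrix(fps) else D

  set.seed(seed)
  labels <- switch(algorithm,
    kmeans = {
      if (is.null(fps)) stop("run_clustering: kmeans needs fingerprints")
      if (is.null(k_req)) stop("run_clustering: kmeans needs params$k")
      # fit on distinct rows so duplicated fingerprints cannot break the
      # centre sampling; duplicates inherit their row's cluster
      key <- apply(fps, 1, paste, collapse = "")
      ux <- fps[!duplicated(key), , drop = FALSE]
      if (k_req >= nrow(ux)) {
        match(key, unique(key))
      } else {
        km <- suppressWarnings(stats::kmeans(ux, centers = k_req,
                                             nstart = 20, iter.max = 100))
        km$cluster[match(key, unique(key))]
      }
    },
    agglomerative = {
      if (is.null(k_req)) stop("run_clustering: agglomerative needs params$k")
      hc <- stats::hclust(as.dist(E), method = params$linkage %||% "average")
      stats::cutree(hc, k = k_req)
    },
    spectral = {
      if (is.null(k_req)) stop("run_clustering: spectral needs params$k")
      h <- params$bandwidth %||% max(stats::median(E[upper.tri(E)]), 1e-6)
      K <- exp(-E^2 / (2 * h^2))
      as.integer(kernlab::specc(kernlab::as.kernelMatrix(K), centers = k_req))
    },
    birch = {
      if (is.null(fps)) stop("run_clustering: birch needs fingerprints")
      thr <- params$threshold %||% stats::median(E[upper.tri(E)]) / 2
      lsr_birch(fps, threshold = thr, k = k_req)
    },
    meanshift = {
      if (is.null(fps)) stop("run_clustering: meanshift needs fingerprints")
      bw <- params$bandwidth %||% stats::median(E[upper.tri(E)])
      lsr_meanshift(fps, bandwidth = bw)
    },
    optics = {
      ms <- params$min_samples %||% max(2L, min(5L, n - 1L))
      lsr_optics(E, min_samples = ms, eps_cl = params$eps_cl)
    },
    affinity_propagation = {
      S <- -E^2
      pref <- params$preference %||% stats::median(S[upper.tri(S)])
      diag(S) <- pref
      lsr_affinity_propagation(S, damping = params$damping %||% 0.9)
    },
    dbscan = {
      eps <- params$eps %||% stats::median(E[upper.tri(E)]) / 2
      lsr_dbscan(E, eps = eps, min_pts = params$min_pts %||% 3L)
    })

  labels <- as.integer(labels)
  k <- length(unique(labels[labels != 0L | algorithm %in% .COUNT_ALGOS]))
  if (all(labels == 0L)) k <- 0L
  sse <- if (!is.null(fps) && k >= 1 && !any(labels == 0L))
    labels_sse(fps, labels) else NA_real_
  sil <- if (length(unique(labels)) >= 2)
    silhouette_mean(Dsil, labels) else NA_real_
  structure(list(algorithm = algorithm, hyperparameters = params,
                 labels = labels, k = k, sse = sse, silhouette = sil, n = n),
            class = "lsr_clustering")
}

#' @export
print.lsr_clustering <- function(x, ...) {
  cat(sprintf("<lsr_clustering %s> n %d, k %d, silhouette %s, sse %s\n",
              x$algorithm, x$n, x$k,
              if (is.na(x$silhouette)) "NA" else sprintf("%.3f", x$silhouette),
              if (is.na(x$sse)) "NA" else sprintf("%.2f", x$sse)))
  invisible(x)
}
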