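# Connectivity vectors, inter-group network distances and the global
# threshold Gcst, band-selection tests, temporal variability of dynamic
# functional connectivity (tvDFC), and eigenvector-centrality hubs with
# an Erdos-Renyi null.

#' Weighted multi-hot connectivity vector
#'
#' One vector per (band, segment, group): the group-mean PLV of each
#' channel pair where the permutation test found a significant
#' connection, and exactly zero elsewhere.
#'
#' @param sig A `significance_result` (its `mask` is used).
#' @param group_mean_plv Per-pair mean PLV, aligned to the same pair
#'   index as `sig`.
#' @return Numeric vector of length P (the pair count).
#' @export
connectivity_vector <- function(sig, group_mean_plv) {
  if (length(sig$mask) != length(group_mean_plv)) {
    stop("mask and mean-PLV vectors disagree in length (",
         length(sig$mask), " vs ", length(group_mean_plv), ")")
  }
  ifelse(sig$mask, group_mean_plv, 0)
}

#' Euclidean distances between all group pairs of connectivity vectors
#'
#' @param vectors Named list (or matrix rows) of equal-length
#'   connectivity vectors, one per emotion group.
#' @return data.frame `group_a`, `group_b`, `distance`; `choose(k, 2)`
#'   rows for k groups.
#' @export
group_pair_distances <- function(vectors) {
  if (is.matrix(vectors)) {
    vectors <- stats::setNames(
      lapply(seq_len(nrow(vectors)), function(i) vectors[i, ]),
      rownames(vectors) %||% seq_len(nrow(vectors)))
  }
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("connectivity vectors differ in length")
  }
  k <- length(vectors)
  nm <- names(vectors) %||% as.character(seq_len(k))
  combs <- utils::combn(k, 2)
  data.frame(
    group_a = nm[combs[1, ]],
    group_b = nm[combs[2, ]],
    distance = apply(combs, 2, function(ab)
      l2(vectors[[ab[1]]] - vectors[[ab[2]]])),
    stringsAsFactors = FALSE
  )
}

#' Segment-pooled average distance per group pair for one band
#'
#' @param dist_table data.frame with columns `band`, `segment`,
#'   `group_a`, `group_b`, `distance` (all segments of all bands).
#' @param band Band name to pool.
#' @param n_segments Expected segment count (default 9); an error is
#'   raised if any segment is missing.
#' @return data.frame `group_a`, `group_b`, `distance` (mean over
#'   segments); 28 rows for 8 groups.
#' @export
band_average_distances <- function(dist_table, band, n_segments = 9) {
  d <- dist_table[dist_table$band == band, , drop = FALSE]
  if (!nrow(d)) stop("no distances for band '", band, "'")
  got <- sort(unique(d$segment))
  if (length(got) != n_segments) {
    stop("band '", band, "' has segments {",
         paste(got, collapse = ","), "}; expected ", n_segments)
  }
  key <- paste(d$group_a, d$group_b, sep = "|")
  agg <- tapply(d$distance, key, mean)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(parts, `[`, "", 1),
    group_b = vapply(parts, `[`, "", 2),
    distance = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  out[order(out$group_a, out$group_b), , drop = FALSE]
}

#' Global connectivity-distance threshold Gcst
#'
#' The grand arithmetic mean of the segment-pooled group-pair distances
#' across all bands: the population mean against which each band's
#' distances are tested.
#'
#' @param band_averages Named list (by band) of data.frames from
#'   [band_average_distances()], or a single numeric vector of all
#'   pooled distances.
#' @return Scalar Gcst.
#' @export
global_threshold <- function(band_averages) {
  if (is.numeric(band_averages)) return(mean(band_averages))
  mean(unlist(lapply(band_averages, function(d) d$distance)))
}

#' One-sample band-selection t-test against Gcst
#'
#' Tests whether a band's 28 segment-pooled group-pair distances are
#' significantly GREATER than the global threshold (one-sided); p is
#' Bonferroni-corrected for the number of bands tested. Cohen's d is
#' (mean - Gcst) / sd.
#'
#' @param band_averages Numeric vector of pooled distances for one band
#'   (28 values for 8 groups), or the data.frame from
#'   [band_average_distances()].
#' @param gcst The global threshold.
#' @param n_bands Bonferroni factor (default 6).
#' @return list `t`, `df`, `p` (corrected, clipped at 1), `p_raw`,
#'   `cohens_d`, `selected` (p < 0.05).
#' @export
band_selection_test <- function(band_averages, gcst, n_bands = 6) {
  x <- if (is.data.frame(band_averages)) band_averages$distance
       else band_averages
  if (length(x) < 2) stop("need at least 2 distances")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance among distances")
  n <- length(x)
  t <- (mean(x) - gcst) / (s / sqrt(n))
  p_raw <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  p <- min(1, p_raw * n_bands)
  list(t = t, df = n - 1, p = p, p_raw = p_raw,
       cohens_d = (mean(x) - gcst) / s, selected = p < 0.05)
}

#' Paired t-test between two bands' pooled distances
#'
#' @param averages_a,averages_b Numeric vectors of pooled distances,
#'   matched by group pair (28 values each for 8 groups).
#' @return list `t`, `df`, `p` (two-sided), `ci95`, `cohens_d` (mean
#'   difference / sd of differences).
#' @export
paired_band_comparison <- function(averages_a, averages_b) {
  if (length(averages_a) != length(averages_b)) {
    stop("distance vectors differ in length")
  }
  d <- averages_a - averages_b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = 0, df = n - 1, p = 1, ci95 = c(0, 0), cohens_d = 0))
  }
  se <- s / sqrt(n)
  t <- mean(d) / se
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df = n - 1)
  list(t = t, df = n - 1, p = p,
       ci95 = c(mean(d) - tcrit * se, mean(d) + tcrit * se),
       cohens_d = mean(d) / s)
}

#' Temporal variability of dynamic functional connectivity (tvDFC)
#'
#' The mean Euclidean distance between the connectivity vectors of
#' consecutive time segments: with 9 segments, the average of 8
#' consecutive-segment dissimilarities. Zero means a static network;
#' larger values mean a network whose significant-connection profile
#' reshapes from segment to segment.
#'
#' @param segment_vectors Segments x P matrix (rows in temporal order),
#'   or a list of equal-length vectors.
#' @return Scalar tv >= 0.
#' @export
temporal_variability <- function(segment_vectors) {
  if (is.list(segment_vectors)) {
    segment_vectors <- do.call(rbind, segment_vectors)
  }
  n <- nrow(segment_vectors)
  if (is.null(n) || n < 2) {
    stop("need at least 2 segment vectors for temporal variability")
  }
  mean(vapply(seq_len(n - 1), function(i)
    l2(segment_vectors[i + 1, ] - segment_vectors[i, ]), numeric(1)))
}

#' Eigenvector centrality of a scalp network
#'
#' Principal-eigenvector scores of the (symmetric, non-negative)
#' adjacency matrix, computed on the largest connected component and
#' zero elsewhere, normalized to unit Euclidean norm. A node scores high
#' when it is connected to other high-scoring nodes.
#'
#' @param adjacency Symmetric non-negative channels x channels matrix
#'   (zero diagonal).
#' @return Named numeric vector of non-negative scores, unit L2 norm.
#' @export
eigenvector_centrality <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (all(A == 0)) stop("empty graph: eigenvector centrality undefined")
  n <- nrow(A)
  # largest connected component (by node count) of the nonzero pattern
  comp <- connected_components(A > 0)
  sizes <- tabulate(comp)
  # prefer components that contain edges
  has_edge <- vapply(seq_len(max(comp)), function(c)
    any(A[comp == c, comp == c] > 0), logical(1))
  sizes[!has_edge] <- 0
  main <- which.max(sizes)
  idx <- which(comp == main)
  ev <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                       # Perron vector is non-negative
  scores <- numeric(n)
  scores[idx] <- v / l2(v)
  names(scores) <- rownames(A) %||% colnames(A)
  scores
}

# union-find free BFS component labelling on a logical adjacency
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Hub detection against an Erdos-Renyi null
#'
#' The observed network's eigenvector centralities are compared with the
#' pooled centrality distribution of `n_random` Erdos-Renyi graphs with
#' the same node count and connection probability equal to the observed
#' edge density. A channel is a significant hub when its observed
#' centrality exceeds the (1 - alpha) quantile of the pooled null
#' scores, i.e. a score with less than an `alpha` chance of arising in a
#' density-matched random graph.
#'
#' @param adjacency Symmetric non-negative weights (channels x channels).
#' @param n_random Number of random graphs (default 10000).
#' @param alpha Hub significance level (default 0.05).
#' @param seed Integer seed.
#' @return data.frame `channel`, `centrality`, `null_percentile`,
#'   `is_hub`; attributes `threshold`, `density`, `n_random`, `seed`.
#' @export
hub_significance <- function(adjacency, n_random = 10000, alpha = 0.05,
                             seed = 1L) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  n_edges <- sum(A[upper.tri(A)] > 0)
  n_possible <- n * (n - 1) / 2
  density <- n_edges / n_possible
  if (density <= 0 || density >= 1) {
    stop("edge density ", signif(density, 3),
         " is degenerate; the random-graph null is undefined")
  }
  obs <- eigenvector_centrality(A)
  null_scores <- with_seed(seed, {
    unlist(lapply(seq_len(n_random), function(k) {
      # G(n, p) with p = observed density, binary adjacency
      edges <- stats::runif(n_possible) < density
      if (!any(edges)) return(numeric(0))
      R <- matrix(0, n, n)
      R[upper.tri(R)] <- as.numeric(edges)
      R <- R + t(R)
      eigenvector_centrality(R)
    }))
  })
  thr <- stats::quantile(null_scores, 1 - alpha, names = FALSE)
  pct <- vapply(obs, function(x) mean(null_scores <= x), numeric(1))
  out <- data.frame(
    channel = names(obs) %||% as.character(seq_len(n)),
    centrality = unname(obs),
    null_percentile = pct,
    is_hub = unname(obs) > thr,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  attr(out, "density") <- density
  attr(out, "n_random") <- n_random
  attr(out, "seed") <- seed
  out
}
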