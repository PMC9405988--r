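# Pooling the 24 self-reported emotion labels into 8 groups by proximity
# in valence-arousal space under an approximate instance-balance
# constraint (few instances per raw label make per-label analysis
# unstable; grouped labels give roughly equal-sized conditions).

#' Per-label mean valence/arousal positions
#'
#' @param events Events data.frame with `emotion`, `valence`, `arousal`.
#' @param labels Optional label vocabulary to validate against; events
#'   with labels outside it raise an error.
#' @return data.frame with `label`, `n`, `valence`, `arousal` (means),
#'   one row per label present.
#' @export
label_va_means <- function(events, labels = NULL) {
  if (!is.null(labels)) {
    unknown <- setdiff(unique(events$emotion), labels)
    if (length(unknown)) {
      stop("unknown emotion label(s): ", paste(unknown, collapse = ", "))
    }
  }
  sp <- split(events, events$emotion)
  out <- data.frame(
    label = names(sp),
    n = vapply(sp, nrow, integer(1)),
    valence = vapply(sp, function(d) mean(d$valence), numeric(1)),
    arousal = vapply(sp, function(d) mean(d$arousal), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cluster emotion labels into k balanced groups on the V-A plane
#'
#' Two criteria drive the grouping: (1) proximity of the labels' mean
#' positions in valence-arousal space, and (2) approximately equal
#' instance counts across groups. Proximity is handled by complete-linkage
#' agglomerative clustering on Euclidean distances between V-A means;
#' balance by a deterministic greedy pass that moves the best-fitting
#' boundary label from the most oversized group to the nearest undersized
#' group until every group is within `balance_tolerance` of the ideal
#' size `total / k` or no improving move exists.
#'
#' Groups are numbered in descending mean valence (ties broken by
#' descending mean arousal), so group 1 is the most pleasant cluster and
#' group k the least.
#'
#' @param label_means data.frame from [label_va_means()] (`label`, `n`,
#'   `valence`, `arousal`).
#' @param k Number of groups (default 8).
#' @param balance_tolerance Allowed fractional deviation of a group's
#'   instance count from `total / k` (default 0.25).
#' @return data.frame with `label`, `group`, `n`; attribute `"groups"`
#'   holds the per-group summary (`group`, `n_labels`, `n_instances`,
#'   `mean_valence`, `mean_arousal`).
#' @export
group_labels <- function(label_means, k = 8, balance_tolerance = 0.25) {
  m <- label_means
  if (nrow(m) < k) {
    stop("cannot form ", k, " groups from ", nrow(m), " labels")
  }
  xy <- as.matrix(m[, c("valence", "arousal")])
  rownames(xy) <- m$label
  assign <- stats::cutree(stats::hclust(stats::dist(xy), "complete"), k)

  target <- sum(m$n) / k
  counts <- function(a) vapply(seq_len(k), function(g)
    sum(m$n[a == g]), numeric(1))
  centroid <- function(a, g) colMeans(xy[a == g, , drop = FALSE])
  repeat {
    cnt <- counts(assign)
    over <- which(cnt > (1 + balance_tolerance) * target)
    if (!length(over)) break
    src <- over[which.max(cnt[over])]
    under <- which(cnt < target & seq_len(k) != src)
    if (!length(under)) break
    members <- which(assign == src)
    if (length(members) < 2) break          # never empty a group
    # best (label, destination) move: minimal V-A distance to destination
    best <- NULL
    for (lab in members) {
      for (g in under) {
        d <- l2(xy[lab, ] - centroid(assign, g))
        if (is.null(best) || d < best$d) best <- list(lab = lab, g = g, d = d)
      }
    }
    new_assign <- assign
    new_assign[best$lab] <- best$g
    new_cnt <- counts(new_assign)
    if (max(new_cnt / target) >= max(cnt / target)) break  # no improvement
    assign <- new_assign
  }

  # renumber by descending mean valence (arousal as tie-break)
  gv <- vapply(seq_len(k), function(g)
    mean(xy[assign == g, 1]), numeric(1))
  ga <- vapply(seq_len(k), function(g)
    mean(xy[assign == g, 2]), numeric(1))
  ord <- order(-gv, -ga)
  renum <- integer(k); renum[ord] <- seq_len(k)
  assign <- renum[assign]

  out <- data.frame(label = m$label, group = assign, n = m$n,
                    stringsAsFactors = FALSE)
  summ <- data.frame(
    group = seq_len(k),
    n_labels = vapply(seq_len(k), function(g) sum(assign == g), integer(1)),
    n_instances = vapply(seq_len(k), function(g)
      sum(m$n[assign == g]), numeric(1)),
    mean_valence = vapply(seq_len(k), function(g)
      mean(xy[assign == g, 1]), numeric(1)),
    mean_arousal = vapply(seq_len(k), function(g)
      mean(xy[assign == g, 2]), numeric(1))
  )
  attr(out, "groups") <- summ
  out
}

#' Attach group ids to an events table
#'
#' @param events Events data.frame with an `emotion` column.
#' @param grouping Output of [group_labels()].
#' @return `events` with a `group` column (overwritten if present).
#' @export
assign_groups <- function(events, grouping) {
  i <- match(events$emotion, grouping$label)
  if (anyNA(i)) {
    stop("events contain labels absent from the grouping: ",
         paste(unique(events$emotion[is.na(i)]), collapse = ", "))
  }
  events$group <- grouping$group[i]
  events
}
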