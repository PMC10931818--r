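#' Match ROIs between two sessions by centroid proximity
#'
#' For each reference centroid the nearest candidates in the comparison
#' session are computed; a pair is accepted automatically when the two ROIs
#' are mutual nearest neighbors and their distance does not exceed
#' `max_dist` (the reproducible surrogate for visual shape inspection).
#' Mutual-nearest-neighbor acceptance is one-to-one by construction; pairs
#' are returned in ascending distance.
#'
#' @param a,b ROI maps: data frames with columns `roi`, `x`, `y` (pixels).
#' @param max_dist maximum accepted centroid distance in pixels (default 5).
#' @param k_candidates candidate neighbors recorded per reference ROI
#'   (default 3), returned in the `candidates` attribute.
#' @return Tibble of matches (`roi_a`, `roi_b`, `dist`) with attributes
#'   `unmatched_a`, `unmatched_b` and `candidates`.
#' @export
match_sessions <- function(a, b, max_dist = 5, k_candidates = 3L) {
  stopifnot(all(c("roi", "x", "y") %in% names(a)),
            all(c("roi", "x", "y") %in% names(b)))
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty ROI map")
  if (anyDuplicated(a$roi) || anyDuplicated(b$roi))
    stop("roi ids must be unique within a session")
  D <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  D <- sqrt(D)
  nn_ab <- apply(D, 1, which.min)
  nn_ba <- apply(D, 2, which.min)
  d_ab <- D[cbind(seq_len(nrow(a)), nn_ab)]
  mutual <- nn_ba[nn_ab] == seq_len(nrow(a)) & d_ab <= max_dist
  out <- tibble::tibble(roi_a = a$roi[mutual], roi_b = b$roi[nn_ab[mutual]],
                        dist = d_ab[mutual])
  out <- out[order(out$dist), ]
  cand <- lapply(seq_len(nrow(a)), function(i) {
    k <- min(k_candidates, nrow(b))
    ord <- order(D[i, ])[seq_len(k)]
    tibble::tibble(roi_a = a$roi[i], roi_b = b$roi[ord], dist = D[i, ord])
  })
  attr(out, "unmatched_a") <- setdiff(a$roi, out$roi_a)
  attr(out, "unmatched_b") <- setdiff(b$roi, out$roi_b)
  attr(out, "candidates") <- dplyr::bind_rows(cand)
  out
}

#' Track ROIs across multiple sessions
#'
#' Runs pairwise centroid matching between every pair of sessions, then
#' links pairs into cross-session tracks with a union-find pass over edges
#' in ascending distance; an edge is skipped when it would place two ROIs
#' of the same session in one track, so tracks contain at most one ROI per
#' session.
#'
#' @param maps named list of ROI maps (one per session).
#' @param max_dist centroid acceptance distance in pixels.
#' @return Tibble with columns `track_id`, `session`, `roi` and attribute
#'   `n_sessions` (total sessions supplied).
#' @export
match_rois <- function(maps, max_dist = 5) {
  stopifnot(is.list(maps), length(maps) >= 2, !is.null(names(maps)))
  sessions <- names(maps)
  edges <- list()
  for (i in seq_along(maps)) for (j in seq_along(maps)) {
    if (i >= j) next
    m <- match_sessions(maps[[i]], maps[[j]], max_dist)
    if (nrow(m)) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        s1 = sessions[i], r1 = m$roi_a, s2 = sessions[j], r2 = m$roi_b,
        dist = m$dist)
    }
  }
  nodes <- unique(dplyr::bind_rows(lapply(seq_along(maps), function(i)
    tibble::tibble(session = sessions[i], roi = maps[[i]]$roi))))
  nodes$key <- paste(nodes$session, nodes$roi, sep = "\r")
  parent <- stats::setNames(seq_len(nrow(nodes)), nodes$key)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  comp_sessions <- split(nodes$session, seq_len(nrow(nodes)))
  if (length(edges)) {
    E <- dplyr::bind_rows(edges)
    E <- E[order(E$dist), ]
    for (r in seq_len(nrow(E))) {
      i <- find(match(paste(E$s1[r], E$r1[r], sep = "\r"), nodes$key))
      j <- find(match(paste(E$s2[r], E$r2[r], sep = "\r"), nodes$key))
      if (i == j) next
      if (length(intersect(comp_sessions[[i]], comp_sessions[[j]]))) next
      parent[j] <- i
      comp_sessions[[i]] <- c(comp_sessions[[i]], comp_sessions[[j]])
    }
  }
  root <- vapply(seq_len(nrow(nodes)), function(i) find(i), numeric(1))
  out <- tibble::tibble(track_id = match(root, unique(root)),
                        session = nodes$session, roi = nodes$roi)
  out <- out[order(out$track_id, out$session), ]
  attr(out, "n_sessions") <- length(maps)
  out
}

#' Summarize cross-session ROI tracking
#'
#' Counts tracks observed in at least `min_sessions` sessions and the
#' percentage of those tracked through every session.
#'
#' @param tracks output of [match_rois()], or a tibble with a
#'   `n_sessions_matched` column (one row per ROI track).
#' @param n_sessions total number of sessions (taken from the `tracks`
#'   attribute when present).
#' @param min_sessions minimum sessions for a track to count (default 2).
#' @return One-row tibble: `n_tracked`, `n_full`, `pct_full`.
#' @export
summarize_matches <- function(tracks, n_sessions = attr(tracks, "n_sessions"),
                              min_sessions = 2L) {
  counts <- if ("n_sessions_matched" %in% names(tracks)) {
    tracks$n_sessions_matched
  } else {
    as.integer(table(tracks$track_id))
  }
  if (is.null(n_sessions)) n_sessions <- max(counts)
  kept <- counts[counts >= min_sessions]
  tibble::tibble(n_tracked = length(kept),
                 n_full = sum(kept == n_sessions),
                 pct_full = 100 * sum(kept == n_sessions) / length(kept))
}
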