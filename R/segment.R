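#' Segment a beta track into methylation blocks
#'
#' Recursive binary segmentation over the ordered per-position beta values:
#' at each step the split maximising the reduction in within-segment sum of
#' squared errors is taken, and accepted only if the reduction exceeds a
#' BIC-style penalty `penalty_lambda * log(n_total) * sigma2`, where
#' `sigma2` is the position-to-position noise variance estimated robustly
#' from the median absolute successive difference (so block structure does
#' not inflate the penalty), and both children have at least `min_size`
#' positions. Segment means are then grouped by one-dimensional
#' k-means (`n_groups` groups, 20 restarts, seeded), and -- the
#' neighbour-joining step -- adjacent segments assigned to the same group
#' are merged.
#'
#' @param track `data.table` from [beta_track()] (sorted by position); only
#'   rows with `strand == "forward"` equivalents are not required -- all
#'   rows are used in position order.
#' @param penalty_lambda split-acceptance penalty multiplier.
#' @param min_size minimum positions per segment.
#' @param n_groups k-means groups for neighbour joining.
#' @param join_neighbors merge adjacent same-group segments.
#' @param seed seed for the k-means restarts.
#' @return `data.table` of class `segment_table`: `segment_id`, `start`,
#'   `end` (0-based half-open genome span), `n_positions`, `mean_beta`,
#'   `group`.
#' @export
segment_track <- function(track, penalty_lambda = 2.0, min_size = 5L,
                          n_groups = 4L, join_neighbors = TRUE, seed = 1L) {
  stopifnot(all(c("position", "beta") %in% names(track)))
  o <- order(track$position)
  pos <- track$position[o]
  b <- track$beta[o]
  n <- length(b)
  if (n == 0L) stop("segment_track: empty track", call. = FALSE)
  bounds <- binary_segment(b, penalty_lambda, min_size)
  # bounds: sorted vector of segment start indices (1-based), first is 1
  starts <- bounds
  ends <- c(bounds[-1L] - 1L, n)
  seg <- data.table::data.table(
    start_idx = starts, end_idx = ends,
    n_positions = ends - starts + 1L,
    mean_beta = vapply(seq_along(starts),
                       function(i) mean(b[starts[i]:ends[i]]), numeric(1)))
  k <- min(n_groups, nrow(seg), length(unique(round(seg$mean_beta, 9))))
  if (nrow(seg) > 1L && k > 1L) {
    if (k >= nrow(seg)) {
      # as many groups as segments: each segment is its own group
      seg[, group := rank(mean_beta, ties.method = "first")]
    } else {
      km <- with_seed_local(seed, stats::kmeans(seg$mean_beta, centers = k,
                                                nstart = 20L))
      # relabel groups by ascending centre so labels are deterministic
      relab <- rank(km$centers[, 1], ties.method = "first")
      seg[, group := relab[km$cluster]]
    }
  } else {
    seg[, group := 1L]
  }
  if (join_neighbors && nrow(seg) > 1L) {
    run <- cumsum(c(TRUE, seg$group[-1L] != seg$group[-nrow(seg)]))
    seg <- seg[, .(start_idx = start_idx[1L],
                   end_idx = end_idx[.N],
                   n_positions = sum(n_positions),
                   mean_beta = sum(mean_beta * n_positions) / sum(n_positions),
                   group = group[1L]), by = .(run)][, run := NULL][]
  }
  out <- data.table::data.table(
    segment_id = seq_len(nrow(seg)),
    start = pos[seg$start_idx],
    end = pos[seg$end_idx] + 1L,
    n_positions = seg$n_positions,
    mean_beta = seg$mean_beta,
    group = seg$group)
  class(out) <- c("segment_table", class(out))
  out
}

# run code under a local seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# recursive binary segmentation on values v; returns 1-based segment start
# indices. A split is accepted when the SSE reduction exceeds
# lambda * log(n) * sigma2, with sigma2 the noise variance estimated from
# the median absolute successive difference (diffs of iid noise have twice
# the variance; 0.6745 is the normal MAD consistency constant).
binary_segment <- function(v, lambda, min_size) {
  n <- length(v)
  if (n < 2L * min_size) return(1L)
  sigma2 <- (stats::median(abs(diff(v))) / 0.6745)^2 / 2
  thresh <- max(lambda * log(n) * sigma2, 1e-8)
  if (!is.finite(thresh)) thresh <- 1e-8
  rec <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_size) return(integer(0))
    x <- v[lo:hi]
    cs <- cumsum(x); tot <- cs[m]
    css <- cumsum(x^2)
    i <- seq_len(m - 1L)
    # SSE reduction of splitting after local index i
    sse_left <- css[i] - cs[i]^2 / i
    sse_right <- (css[m] - css[i]) - (tot - cs[i])^2 / (m - i)
    sse_all <- css[m] - tot^2 / m
    red <- sse_all - (sse_left + sse_right)
    ok <- i >= min_size & (m - i) >= min_size
    if (!any(ok)) return(integer(0))
    red[!ok] <- -Inf
    bi <- which.max(red)
    if (red[bi] <= thresh) return(integer(0))
    cut <- lo + bi                       # global start index of right child
    c(rec(lo, cut - 1L), cut, rec(cut, hi))
  }
  sort(c(1L, rec(1L, n)))
}

#' Mean beta of a sample track within reference segments
#'
#' The comparison currency across treatments: the unweighted mean of a
#' sample's per-position betas over each reference segment's span; segments
#' with no covered position give NA.
#'
#' @param segments a [segment_track()] result.
#' @param sample_track a [beta_track()] `data.table`.
#' @return numeric vector of per-segment means, aligned with `segments`.
#' @export
segment_means <- function(segments, sample_track) {
  pos <- sample_track$position
  beta <- sample_track$beta
  vapply(seq_len(nrow(segments)), function(i) {
    sel <- pos >= segments$start[i] & pos < segments$end[i]
    if (!any(sel)) NA_real_ else mean(beta[sel])
  }, numeric(1))
}

#' Decile histogram of beta values
#'
#' Ten right-closed bins (0,10], (10,20], ..., (90,100]; a beta of exactly 0
#' is assigned to the first bin. Frequencies are counts over the total.
#'
#' @param values beta percentages in \[0, 100\].
#' @return `data.table` of class `beta_histogram` with `bin` (1..10),
#'   `lower`, `upper`, `frequency`; attribute `empty` when no value was
#'   supplied.
#' @export
bin_histogram <- function(values) {
  if (any(!is.na(values) & (values < 0 | values > 100)))
    stop("bin_histogram: values must lie in [0, 100]", call. = FALSE)
  values <- values[!is.na(values)]
  idx <- pmax(1L, as.integer(ceiling(values / 10)))
  counts <- tabulate(idx, nbins = 10L)
  out <- data.table::data.table(
    bin = 1:10, lower = seq(0, 90, 10), upper = seq(10, 100, 10),
    frequency = if (length(values)) counts / length(values) else rep(0, 10))
  data.table::setattr(out, "empty", length(values) == 0L)
  class(out) <- c("beta_histogram", class(out))
  out
}

#' Hierarchically cluster sample beta tracks over shared segments
#'
#' Pairwise Euclidean distance between samples over the segments where every
#' sample has a value (columns with any NA are dropped), followed by
#' average-linkage agglomerative clustering. Samples are ordered by name
#' first so the leaf order is deterministic under distance ties.
#'
#' @param segment_mean_matrix numeric matrix, samples x segments, possibly
#'   with NA entries; rownames are sample names.
#' @return list with `distances` (a `dist`), `hclust` (the merge tree) and
#'   `leaf_order` (sample names in dendrogram order).
#' @export
cluster_tracks <- function(segment_mean_matrix) {
  m <- segment_mean_matrix
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  if (nrow(m) < 2L) stop("cluster_tracks: need >= 2 samples", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  complete <- colSums(is.na(m)) == 0L
  if (sum(complete) < 2L)
    stop("cluster_tracks: fewer than 2 complete segments", call. = FALSE)
  m <- m[, complete, drop = FALSE]
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(distances = d, hclust = hc, leaf_order = hc$labels[hc$order])
}
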