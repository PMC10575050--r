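#' Sliding-window fragment dataset
#'
#' Cuts every labeled record into fixed-length fragments of `q` samples
#' taken every `s` samples: full fragments start at 0, s, 2s, ... while
#' they fit, and when the last full fragment does not end at the record's
#' final sample one extra fragment covering the last `q` samples is
#' appended. Records shorter than `q` are skipped. Fragments inherit the
#' record's label and remember which record they came from, so train/test
#' splits can be grouped by record.
#'
#' @param records A record collection (see [record_collection()]); all
#'   records must track the same named target points.
#' @param q Window length, samples (>= 2).
#' @param s Step between window starts, samples (1 <= s <= q).
#' @return A `window_dataset`: list with `fragments` (array
#'   `n x m x q x 3`), `labels` (factor), `provenance` (record ids),
#'   `points`, `q`, `s`, `dt`, and `skipped` (record ids too short to
#'   window).
#' @export
make_windows <- function(records, q, s) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  q <- as.integer(q); s <- as.integer(s)
  if (q < 2L) stop("window length `q` must be >= 2", call. = FALSE)
  if (s < 1L || s > q) stop("step `s` must satisfy 1 <= s <= q", call. = FALSE)
  points <- unique(records$data[[1]]$point)
  m <- length(points)
  frag_list <- list(); labels <- character(0); prov <- integer(0)
  skipped <- integer(0)
  dt <- attr(records$data[[1]], "dt")
  for (r in seq_len(nrow(records))) {
    ts <- records$data[[r]]
    if (!setequal(unique(ts$point), points))
      stop("all records must track the same target points", call. = FALSE)
    trajs <- set_points(ts)[points]
    n <- nrow(trajs[[1]])
    if (n < q) { skipped <- c(skipped, records$record[r]); next }
    starts <- seq.int(0L, n - q, by = s)
    if (starts[length(starts)] + q < n) starts <- c(starts, n - q)
    mats <- lapply(trajs, traj_matrix)
    for (st in starts) {
      frag <- array(0, c(m, q, 3))
      for (p in seq_len(m)) frag[p, , ] <- mats[[p]][(st + 1):(st + q), ]
      frag_list[[length(frag_list) + 1L]] <- frag
      labels <- c(labels, records$label[r])
      prov <- c(prov, records$record[r])
    }
  }
  nf <- length(frag_list)
  fragments <- array(0, c(nf, m, q, 3))
  for (i in seq_len(nf)) fragments[i, , , ] <- frag_list[[i]]
  structure(list(fragments = fragments, labels = factor(labels),
                 provenance = prov, points = points, q = q, s = s, dt = dt,
                 skipped = skipped),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "# Window dataset: %d fragments (q = %d, s = %d, %d point%s) over %d classes\n",
    dim(x$fragments)[1], x$q, x$s, length(x$points),
    if (length(x$points) == 1) "" else "s", nlevels(x$labels)))
  invisible(x)
}

#' Number of fragments a record of length n yields
#'
#' Closed-form count under the start rule of [make_windows()]: full
#' fragments every `s` samples plus one trailing last-`q` fragment when
#' needed; 0 when `n < q`.
#'
#' @param n Record length, samples.
#' @param q,s Window length and step.
#' @return Integer fragment count.
#' @export
window_count <- function(n, q, s) {
  if (n < q) return(0L)
  starts <- seq.int(0L, n - q, by = s)
  if (starts[length(starts)] + q < n) starts <- c(starts, n - q)
  length(starts)
}

#' Flatten fragments for tabular classifiers
#'
#' Reshapes each `m x q x 3` fragment into one row of `m * q * 3`
#' features in row-major (last-index-fastest) order; the operation is
#' invertible given `(m, q)` via [unflatten_windows()].
#'
#' @param ds A `window_dataset` (or a bare fragment array).
#' @return A numeric matrix `n_fragments x (m * q * 3)`.
#' @export
flatten_for_tabular <- function(ds) {
  arr <- if (inherits(ds, "window_dataset")) ds$fragments else ds
  stopifnot(length(dim(arr)) == 4L)
  d <- dim(arr)
  # row-major flatten of each fragment: reverse the per-fragment axes
  out <- matrix(aperm(arr, c(4, 3, 2, 1)), nrow = d[1], byrow = TRUE)
  colnames(out) <- sprintf("f%04d", seq_len(ncol(out)))
  out
}

#' @rdname flatten_for_tabular
#' @param mat Matrix produced by [flatten_for_tabular()].
#' @param m,q Number of target points and window length.
#' @return The `n x m x q x 3` fragment array.
#' @export
unflatten_windows <- function(mat, m, q) {
  stopifnot(ncol(mat) == m * q * 3L)
  arr <- array(t(mat), c(3, q, m, nrow(mat)))
  aperm(arr, c(4, 3, 2, 1))
}

#' Add a trailing channel axis for attention backends
#'
#' @param ds A `window_dataset` (or fragment array).
#' @return Array of shape `n x m x q x 3 x 1` with unchanged values.
#' @export
expand_for_attention <- function(ds) {
  arr <- if (inherits(ds, "window_dataset")) ds$fragments else ds
  stopifnot(length(dim(arr)) == 4L)
  array(arr, c(dim(arr), 1L))
}
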