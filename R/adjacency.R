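#' Electrode montage constructor
#'
#' A montage holds the 2-D projected scalp positions of the EEG electrodes
#' together with a hemisphere tag per channel. Row order defines node order in
#' every adjacency matrix built from the montage.
#'
#' @param labels character vector of unique channel identifiers.
#' @param coords numeric matrix with one `(x, y)` row per channel; positions on
#'   the projected scalp plane (unitless). Negative `x` is the left hemisphere.
#' @param hemisphere character vector, one of `"left"`, `"right"`, `"midline"`
#'   per channel.
#' @return An object of class `electrode_montage`: a data frame with columns
#'   `label`, `x`, `y`, `hemisphere`.
#' @export
electrode_montage <- function(labels, coords, hemisphere) {
  labels <- as.character(labels)
  stop_if(anyDuplicated(labels) > 0, "channel labels must be unique")
  coords <- as.matrix(coords)
  stop_if(ncol(coords) != 2, "coords must have two columns (x, y)", "mdgraph_shape_error")
  stop_if(nrow(coords) != length(labels) || length(hemisphere) != length(labels),
          "labels, coords and hemisphere must have identical length",
          "mdgraph_shape_error")
  stop_if(any(!is.finite(coords)), "montage coordinates must be finite")
  stop_if(!all(hemisphere %in% c("left", "right", "midline")),
          "hemisphere tags must be 'left', 'right' or 'midline'")
  out <- data.frame(label = labels, x = coords[, 1], y = coords[, 2],
                    hemisphere = as.character(hemisphere),
                    stringsAsFactors = FALSE)
  class(out) <- c("electrode_montage", class(out))
  out
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("Electrode montage: %d channels (%d left, %d right, %d midline)\n",
              nrow(x), sum(x$hemisphere == "left"), sum(x$hemisphere == "right"),
              sum(x$hemisphere == "midline")))
  invisible(x)
}

#' Local EEG connectivity from electrode positions
#'
#' Connects each electrode to its `k` nearest neighbours by Euclidean distance
#' on the projected 2-D montage coordinates, then symmetrizes (an edge is kept
#' if either endpoint selects it). Distance ties are broken in favour of the
#' lower channel index, so the result is deterministic for duplicated
#' coordinates.
#'
#' @param montage an [electrode_montage()].
#' @param k number of nearest neighbours per electrode; must satisfy
#'   `1 <= k < n`.
#' @return A binary, symmetric, zero-diagonal adjacency matrix with channel
#'   labels as dimnames.
#' @export
build_local_adjacency <- function(montage, k = 4) {
  n <- nrow(montage)
  stop_if(length(k) != 1 || !is.finite(k) || k <= 0 || k >= n || k != round(k),
          sprintf("k must be a positive integer < n = %d", n),
          "mdgraph_parameter_error")
  D <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  A <- matrix(0, n, n, dimnames = list(montage$label, montage$label))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is stable: equal distances resolve to the lower index
    nb <- order(d)[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))   # symmetrize: keep edge if either direction selected it
  diag(A) <- 0
  A
}

#' Hemispheric-symmetry edges
#'
#' Builds the adjacency matrix whose only edges connect listed left/right
#' electrode pairs, capturing inter-hemispheric symmetry of homologous scalp
#' regions.
#'
#' @param montage an [electrode_montage()].
#' @param pairs a two-column data frame or matrix of `(left_label, right_label)`
#'   channel-label pairs, e.g. from [default_symmetric_pairs()] or
#'   [read_symmetric_pairs()].
#' @return A binary symmetric adjacency matrix with an entry 1 exactly at the
#'   listed pairs (both orientations).
#' @export
build_symmetric_adjacency <- function(montage, pairs) {
  n <- nrow(montage)
  A <- matrix(0, n, n, dimnames = list(montage$label, montage$label))
  if (is.null(pairs) || NROW(pairs) == 0) return(A)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stop_if(ncol(pairs) < 2, "pairs must have two columns", "mdgraph_shape_error")
  lookup <- stats::setNames(seq_len(n), montage$label)
  key <- paste(pairs[[1]], pairs[[2]])
  stop_if(anyDuplicated(key) > 0, "duplicate symmetric pairs")
  for (r in seq_len(nrow(pairs))) {
    l <- as.character(pairs[[1]][r]); rr <- as.character(pairs[[2]][r])
    for (lab in c(l, rr)) {
      stop_if(is.na(lookup[lab]),
              sprintf("unknown channel label '%s' in symmetric pairs", lab),
              "mdgraph_lookup_error")
    }
    il <- lookup[[l]]; ir <- lookup[[rr]]
    stop_if(montage$hemisphere[il] == montage$hemisphere[ir],
            sprintf("pair (%s, %s) lies within one hemisphere", l, rr),
            "mdgraph_validation_error")
    stop_if(montage$hemisphere[il] != "left" || montage$hemisphere[ir] != "right",
            sprintf("pair (%s, %s): first member must be left, second right", l, rr),
            "mdgraph_validation_error")
    A[il, ir] <- 1
    A[ir, il] <- 1
  }
  A
}

#' Combine local and symmetric adjacency
#'
#' Elementwise union of two binary adjacency matrices: the sum clipped back to
#' `{0, 1}`. An edge present in both inputs stays a single binary edge, because
#' downstream degree normalization expects a connectivity pattern, not edge
#' multiplicities.
#'
#' @param a_init,a_sym binary adjacency matrices of identical size.
#' @return The binary union adjacency.
#' @export
combine_adjacency <- function(a_init, a_sym) {
  check_binary_adjacency(a_init, "a_init")
  check_binary_adjacency(a_sym, "a_sym")
  stop_if(nrow(a_init) != nrow(a_sym), "adjacency sizes differ", "mdgraph_shape_error")
  pmin(a_init + a_sym, 1)
}

#' Temporal chain adjacency for audio slices
#'
#' Audio recordings are cut into `n` equal-duration slices; slice `j` is a graph
#' node connected to its temporal neighbours, i.e. `A[j, k] = 1` iff
#' `|j - k| = 1`.
#'
#' @param n number of slices (nodes); `n >= 1`.
#' @return An `n x n` binary chain adjacency with `2(n - 1)` nonzero entries.
#' @export
build_chain_adjacency <- function(n) {
  stop_if(length(n) != 1 || !is.finite(n) || n < 1 || n != round(n),
          "n must be a positive integer", "mdgraph_parameter_error")
  A <- matrix(0, n, n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    A[cbind(idx, idx + 1)] <- 1
    A[cbind(idx + 1, idx)] <- 1
  }
  A
}

#' Default left/right symmetric pairs from mirrored coordinates
#'
#' For each left-hemisphere channel, reflects its position across the midline
#' (`x -> -x`) and picks the right-hemisphere channel closest to that mirror
#' image. Each right channel is used at most once (greedy, in montage order by
#' increasing distance), so the returned pair list has no duplicates.
#'
#' @param montage an [electrode_montage()].
#' @param max_pairs optional cap on the number of pairs returned (closest
#'   mirror matches first); `NULL` returns all matches.
#' @return Data frame with columns `left`, `right`.
#' @export
default_symmetric_pairs <- function(montage, max_pairs = NULL) {
  left <- which(montage$hemisphere == "left")
  right <- which(montage$hemisphere == "right")
  if (length(left) == 0 || length(right) == 0) {
    return(data.frame(left = character(0), right = character(0),
                      stringsAsFactors = FALSE))
  }
  # distance from each left channel's mirror image to each right channel
  d <- outer(seq_along(left), seq_along(right), function(i, j) {
    sqrt((-montage$x[left[i]] - montage$x[right[j]])^2 +
           (montage$y[left[i]] - montage$y[right[j]])^2)
  })
  cand <- data.frame(li = rep(seq_along(left), times = length(right)),
                     ri = rep(seq_along(right), each = length(left)),
                     d = as.vector(d))
  cand <- cand[order(cand$d, cand$li, cand$ri), ]
  used_l <- logical(length(left)); used_r <- logical(length(right))
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    li <- cand$li[r]; ri <- cand$ri[r]
    if (!used_l[li] && !used_r[ri]) {
      used_l[li] <- TRUE; used_r[ri] <- TRUE
      keep <- c(keep, r)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  if (!is.null(max_pairs)) cand <- utils::head(cand, max_pairs)
  out <- data.frame(left = montage$label[left[cand$li]],
                    right = montage$label[right[cand$ri]],
                    stringsAsFactors = FALSE)
  out[order(out$left), , drop = FALSE]
}

#' Read / write montage tables
#'
#' Montages are exchanged as CSV/TSV with columns `label,x,y,hemisphere`, one
#' row per channel.
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `read_montage()` returns an [electrode_montage()].
#' @export
read_montage <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stop_if(!all(c("label", "x", "y", "hemisphere") %in% names(df)),
          "montage file must have columns label,x,y,hemisphere")
  electrode_montage(df$label, cbind(df$x, df$y), df$hemisphere)
}

#' @rdname read_montage
#' @param montage the montage to write.
#' @export
write_montage <- function(montage, path, sep = ",") {
  # 17 significant digits so coordinates survive the round trip exactly
  lines <- c(paste(c("label", "x", "y", "hemisphere"), collapse = sep),
             sprintf("%s%s%.17g%s%.17g%s%s", montage$label, sep, montage$x,
                     sep, montage$y, sep, montage$hemisphere))
  writeLines(lines, path)
  invisible(path)
}

#' Read a symmetric-pair file
#'
#' Two-column CSV `left_label,right_label` (header optional but recommended).
#'
#' @param path file path.
#' @param sep field separator.
#' @return Data frame with columns `left`, `right`.
#' @export
read_symmetric_pairs <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stop_if(ncol(df) < 2, "pair file must have two columns")
  data.frame(left = as.character(df[[1]]), right = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write / read adjacency matrices
#'
#' The interchange format is an edge-list TSV with header `i j w`, one row per
#' undirected edge with `i < j` (1-based node indices) and weight 1; the node
#' count is recorded in a `# n=<count>` comment on the first line so that the
#' round trip is lossless even for isolated trailing nodes. `write_adjacency()`
#' can additionally emit a dense CSV.
#'
#' @param A binary adjacency matrix.
#' @param path output path for the edge list.
#' @param dense_path optional path for a dense CSV copy.
#' @return `read_adjacency()` returns the reconstructed matrix.
#' @export
write_adjacency <- function(A, path, dense_path = NULL) {
  check_binary_adjacency(A)
  n <- nrow(A)
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  con <- file(path, "w")
  writeLines(sprintf("# n=%d", n), con)
  writeLines("i\tj\tw", con)
  if (nrow(ut) > 0) {
    writeLines(sprintf("%d\t%d\t1", ut[, 1], ut[, 2]), con)
  }
  close(con)
  if (!is.null(dense_path)) {
    utils::write.table(A, dense_path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1)
  stop_if(!grepl("^# n=\\d+$", first), "missing '# n=' header in edge list")
  n <- as.integer(sub("^# n=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  A <- matrix(0, n, n)
  if (nrow(df) > 0) {
    A[cbind(df$i, df$j)] <- df$w
    A[cbind(df$j, df$i)] <- df$w
  }
  A
}
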