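#' Cost matrix between a standard and a test sequence
#'
#' Entry \code{(i, j)} is the aggregated joint-angle difference between
#' standard frame i and test frame j under the given feature-vector set:
#' the angle between each same-named bone vector in the two frames is
#' taken, and the resulting set is reduced by \code{agg}. All entries are
#' in degrees and non-negative; for \code{mean} and \code{max} every entry
#' is at most 180, for \code{sum} at most \code{180 * V}.
#'
#' @param std,test \code{skeleton_sequence} objects (standard rows, test
#'   columns)
#' @param vset a \code{feature_vector_set} from \code{\link{vector_set_for}}
#' @param agg aggregation attribute, \code{"sum"}, \code{"mean"} or
#'   \code{"max"}
#' @param degenerate zero-length bone-vector policy, see
#'   \code{\link{angle_between}}
#' @return numeric matrix \code{n_frames(std) x n_frames(test)}.
#' @export
build_cost_matrix <- function(std, test, vset, agg = c("sum", "mean", "max"),
                              degenerate = "lenient") {
  agg <- match.arg(agg)
  su <- .sequence_units(std, vset, degenerate = degenerate)
  tu <- .sequence_units(test, vset, degenerate = degenerate)
  szero <- attr(su, "zero"); tzero <- attr(tu, "zero")
  n <- dim(su)[1]; m <- dim(tu)[1]; V <- vset$V
  acc <- NULL
  for (k in seq_len(V)) {
    sk <- matrix(su[, k, ], nrow = n)  # n x 3 unit vectors
    tk <- matrix(tu[, k, ], nrow = m)
    cosang <- tcrossprod(sk, tk)
    # clamp for floating-point safety; snap within numerical resolution of
    # +/-1 so a self-comparison scores an exactly zero cost
    cosang[cosang > 1 - 1e-12] <- 1
    cosang[cosang < -1 + 1e-12] <- -1
    ang <- acos(cosang) * (180 / pi)
    ang[cosang == -1] <- 180
    # a degenerate vector on either side contributes 0 degrees (lenient)
    if (any(szero[, k])) ang[szero[, k], ] <- 0
    if (any(tzero[, k])) ang[, tzero[, k]] <- 0
    if (agg == "max") {
      acc <- if (is.null(acc)) ang else pmax(acc, ang)
    } else {
      acc <- if (is.null(acc)) ang else acc + ang
    }
  }
  if (agg == "mean") acc <- acc / V
  acc
}

#' Accumulate a DTW cost matrix
#'
#' Dynamic-programming recurrence under the boundary, monotonicity and
#' continuity constraints:
#' \code{D(i,j) = min(D(i-1,j-1), D(i-1,j), D(i,j-1)) + C(i,j)} with
#' \code{D(1,1) = C(1,1)} and out-of-range predecessors at +Inf. The
#' terminal entry \code{D(n, m)} is the DTW value: the minimum cumulative
#' cost over all monotone, continuous, boundary-respecting warping paths.
#'
#' @param cost a non-empty numeric cost matrix
#' @return list with \code{acc} (accumulated matrix) and \code{dtw_value}
#'   (its terminal entry).
#' @export
dtw_accumulate <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) == 0L || ncol(cost) == 0L) stop("empty cost matrix")
  acc <- dtw_accumulate_cpp(cost)
  list(acc = acc, dtw_value = acc[nrow(acc), ncol(acc)])
}

#' Recover the optimal warping path
#'
#' Backtracks from the terminal cell of the accumulated matrix, at each
#' step moving to the predecessor that realized the minimum; ties are
#' broken diagonal, then vertical, then horizontal, which picks the
#' shortest path among equal-cost alternatives. The summed cost along the
#' returned path equals the DTW value.
#'
#' @param acc result of \code{\link{dtw_accumulate}} (or its \code{acc}
#'   matrix)
#' @param cost the cost matrix the accumulation came from
#' @return list with \code{steps} (an \code{l x 2} matrix of 1-based
#'   (i, j) pairs), \code{length_l}, and \code{path_cost}.
#' @export
optimal_path <- function(acc, cost) {
  if (is.list(acc)) acc <- acc$acc
  steps <- dtw_backtrack_cpp(acc)
  colnames(steps) <- c("i", "j")
  list(steps = steps, length_l = nrow(steps),
       path_cost = sum(cost[steps]))
}

#' Similarity score from a DTW alignment
#'
#' Maps the optimal-path cumulative cost to a fraction in \code{[0, 1]}
#' via \code{1 - dtw_value / normalizer}. Two normalizers are offered:
#' \describe{
#'   \item{\code{bounded} (default)}{the per-step theoretical maximum of
#'     the aggregated cost times the path length \code{l}: \code{180*V*l}
#'     for \code{sum}, \code{180*l} for \code{mean} and \code{max}. The
#'     score then always lies in \code{[0, 1]} and reaches 0 only for a
#'     worst-case alignment.}
#'   \item{\code{paper_literal}}{\code{180*V*l} for every aggregation,
#'     clamped to \code{[0, 1]}. Under \code{mean}/\code{max} the per-step
#'     cost cannot exceed 180, so this floor the score at \code{1 - 1/V};
#'     it is kept for comparability with the published formula.}
#' }
#'
#' @param dtw_value cumulative cost of the optimal path, degrees
#' @param V number of feature vectors
#' @param l warping-path length (number of matched index pairs)
#' @param agg aggregation attribute used to build the cost
#' @param mode \code{"bounded"} or \code{"paper_literal"}
#' @return similarity as a fraction in \code{[0, 1]}.
#' @export
#' @examples
#' similarity_score(0, V = 3, l = 300, agg = "max")           # 1
#' similarity_score(3, V = 3, l = 3, agg = "max")             # 1 - 3/540
similarity_score <- function(dtw_value, V, l, agg = c("sum", "mean", "max"),
                             mode = c("bounded", "paper_literal")) {
  agg <- match.arg(agg)
  mode <- match.arg(mode)
  if (!is.numeric(V) || V < 1) stop("V must be a positive count")
  if (!is.numeric(l) || l < 1) stop("l must be a positive count")
  if (dtw_value < 0) stop("dtw_value must be non-negative")
  denom <- if (mode == "paper_literal" || agg == "sum") 180 * V * l else 180 * l
  max(0, min(1, 1 - dtw_value / denom))
}

#' Brute-force DTW by exhaustive path enumeration
#'
#' Test oracle: enumerates every monotone, continuous,
#' boundary-respecting warping path of a small cost matrix and returns
#' the minimum cumulative cost together with the first minimizing path in
#' (diagonal, vertical, horizontal) successor order. Guarded to small
#' inputs; independent of the dynamic-programming implementation.
#'
#' @param cost numeric cost matrix with \code{nrow + ncol <= 14}
#' @return list with \code{dtw_value} and \code{steps}.
#' @export
dtw_brute_force <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) stop("empty cost matrix")
  if (n + m > 14L) stop("dtw_brute_force guard exceeded (nrow + ncol must be <= 14)")
  best <- list(dtw_value = Inf, steps = NULL)
  # depth-first enumeration from (1,1); successor order diag, down, right
  recurse <- function(i, j, acc, path) {
    if (i == n && j == m) {
      if (acc < best$dtw_value) {
        best <<- list(dtw_value = acc, steps = path)
      }
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc + cost[i + 1, j + 1],
                                rbind(path, c(i + 1, j + 1)))
    if (i < n) recurse(i + 1, j, acc + cost[i + 1, j], rbind(path, c(i + 1, j)))
    if (j < m) recurse(i, j + 1, acc + cost[i, j + 1], rbind(path, c(i, j + 1)))
  }
  recurse(1L, 1L, cost[1, 1], matrix(c(1L, 1L), 1))
  colnames(best$steps) <- c("i", "j")
  best
}
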