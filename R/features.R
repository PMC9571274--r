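#' @name feature-vocabulary
#' @title Scheme, aggregation and action vocabularies
#'
#' @description
#' Four bone-vector selection schemes are supported. The two
#' \emph{adjacent-joint} schemes connect anatomically neighbouring joints
#' (shoulder to elbow, elbow to wrist, ...); the two \emph{pelvis-divergence}
#' schemes anchor every vector at the pelvis (code \code{O}) and point it at
#' a selected joint, which is more robust to body-shape differences and
#' trunk offset. Either family comes in an \emph{overall} variant (one
#' shared whole-body vector set) and a \emph{local} variant (an
#' action-specific set covering only that action's high-frequency joints).
#'
#' Per frame pair the set of joint-angle differences is reduced to one
#' scalar by an aggregation attribute: \code{sum}, \code{mean} or
#' \code{max} (experiment groups A, B and C).
NULL

#' @rdname feature-vocabulary
#' @export
vector_schemes <- function() {
  c("overall_adjacent", "overall_pelvis", "local_adjacent", "local_pelvis")
}

#' @rdname feature-vocabulary
#' @export
angle_aggregations <- function() c("sum", "mean", "max")

#' @rdname feature-vocabulary
#' @export
unsafe_actions <- function() {
  c("punch", "one_armed_call_for_help", "arms_for_help",
    "trip_forward", "trip_backwards")
}

#' @rdname feature-vocabulary
#' @export
safe_actions <- function() c("stand", "squat")

#' @rdname feature-vocabulary
#' @export
all_actions <- function() c(unsafe_actions(), safe_actions())

# local vector sets, written in joint-code pairs exactly as published
.local_sets <- list(
  local_adjacent = list(
    punch = c("AB", "BC"),
    one_armed_call_for_help = c("AB", "BC"),
    arms_for_help = c("AB", "BC", "DE", "EF"),
    trip_forward = c("PA", "QD", "OG", "OH"),
    trip_backwards = c("PA", "QD", "OG", "OH")
  ),
  local_pelvis = list(
    punch = c("OA", "OB", "OC"),
    one_armed_call_for_help = c("OA", "OB", "OC"),
    arms_for_help = c("OA", "OB", "OC", "OD", "OE", "OF"),
    trip_forward = c("OA", "OP", "OQ", "OD", "OG", "OH"),
    trip_backwards = c("OA", "OP", "OQ", "OD", "OG", "OH")
  )
)

.overall_sets <- list(
  overall_adjacent = c("AB", "BC", "DE", "EF", "GI", "IK", "HJ", "JL"),
  overall_pelvis = c("OA", "OB", "OC", "OD", "OE", "OF",
                     "OG", "OH", "OI", "OJ", "OK", "OL")
)

.pairs_from_codes <- function(codes) {
  start <- joint_from_code(substr(codes, 1, 1))
  end <- joint_from_code(substr(codes, 2, 2))
  structure(
    list(codes = codes, start = start, end = end, V = length(codes)),
    class = "feature_vector_set"
  )
}

#' @export
print.feature_vector_set <- function(x, ...) {
  cat(sprintf("<feature_vector_set: V=%d [%s]>\n", x$V,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

#' Bone feature-vector set for a (scheme, action)
#'
#' Returns the ordered joint pairs whose difference vectors form the
#' feature set for one scheme/action combination. Overall schemes share
#' one whole-body set across all actions; local schemes are defined only
#' for the five unsafe actions, each with its own set. \code{V}, the
#' number of vectors, enters the similarity normalizer \code{180 * V * l}.
#'
#' @param scheme one of \code{vector_schemes()}
#' @param action an action name; ignored by overall schemes
#' @return a \code{feature_vector_set}: list with \code{codes} (letter
#'   pairs), \code{start}/\code{end} joint names, and \code{V}.
#' @export
#' @examples
#' vector_set_for("local_pelvis", "punch")   # OA, OB, OC
#' vector_set_for("overall_adjacent", "stand")$V  # 8
vector_set_for <- function(scheme, action = NULL) {
  scheme <- match.arg(scheme, vector_schemes())
  if (scheme %in% names(.overall_sets)) {
    return(.pairs_from_codes(.overall_sets[[scheme]]))
  }
  if (is.null(action) || !action %in% names(.local_sets[[scheme]])) {
    stop(sprintf("no local vector set for (%s, %s): local sets exist only for the five unsafe actions",
                 scheme, if (is.null(action)) "<none>" else action))
  }
  .pairs_from_codes(.local_sets[[scheme]][[action]])
}

#' Bone vectors of one frame under a feature-vector set
#'
#' @param frame a frame as returned by \code{\link{skeleton_frame}}
#' @param vset a \code{feature_vector_set}
#' @return a \code{V x 3} matrix; row k is
#'   \code{position(end_k) - position(start_k)} in millimetres.
#' @export
bone_vectors <- function(frame, vset) {
  need <- unique(c(vset$start, vset$end))
  bad <- need[!frame$valid[need]]
  if (length(bad)) {
    stop("feature extraction failed: joint(s) missing in frame: ",
         paste(bad, collapse = ", "))
  }
  out <- frame$positions[vset$end, , drop = FALSE] -
    frame$positions[vset$start, , drop = FALSE]
  rownames(out) <- vset$codes
  out
}

#' Angle between two 3-D vectors (degrees)
#'
#' Computed from the cosine rule,
#' \code{theta = acos((u . v) / (|u| |v|))}, with the cosine argument
#' clamped to \code{[-1, 1]} for floating-point safety. A vector whose
#' norm is below \code{eps} has no direction: in \code{"strict"} mode this
#' raises an error; in the default \code{"lenient"} mode 0 degrees is
#' substituted with a warning, matching the observation that coincident
#' joints merely degrade similarity.
#'
#' @param u,v numeric length-3 vectors
#' @param degenerate \code{"lenient"} or \code{"strict"}
#' @param eps norm threshold in millimetres
#' @return angle in degrees, in \code{[0, 180]}.
#' @export
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # 90
#' angle_between(c(1, 0, 0), c(1, 1, 0))  # 45
angle_between <- function(u, v, degenerate = c("lenient", "strict"),
                          eps = 1e-6) {
  degenerate <- match.arg(degenerate)
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu <= eps || nv <= eps) {
    if (degenerate == "strict") stop("degenerate (zero-length) bone vector")
    warning("zero-length bone vector; substituting 0 degrees")
    return(0)
  }
  ca <- max(-1, min(1, sum(u * v) / (nu * nv)))
  # snap cosines within numerical resolution of +/-1 so that identical
  # (or exactly opposite) vectors give exactly 0 / 180 degrees
  if (ca > 1 - 1e-12) return(0)
  if (ca < -1 + 1e-12) return(180)
  acos(ca) * 180 / pi
}

#' Joint-angle difference set between a standard and a test frame
#'
#' For each bone vector in \code{vset}, the angle between the same-named
#' vector in the standard frame and in the test frame. The result is
#' invariant to translating either skeleton and to uniformly scaling
#' either skeleton, but not to rigid rotation.
#'
#' @param std_frame,test_frame frames from \code{\link{skeleton_frame}}
#' @param vset a \code{feature_vector_set}
#' @inheritParams angle_between
#' @return numeric vector of length \code{V}, degrees in \code{[0, 180]}.
#' @export
frame_angle_set <- function(std_frame, test_frame, vset,
                            degenerate = c("lenient", "strict"), eps = 1e-6) {
  degenerate <- match.arg(degenerate)
  su <- bone_vectors(std_frame, vset)
  tu <- bone_vectors(test_frame, vset)
  vapply(seq_len(vset$V), function(k) {
    angle_between(su[k, ], tu[k, ], degenerate = degenerate, eps = eps)
  }, numeric(1))
}

#' Reduce an angle-difference set to a scalar feature
#'
#' @param angles numeric vector of angle differences in degrees
#' @param agg one of \code{"sum"}, \code{"mean"}, \code{"max"}
#' @return scalar feature in degrees.
#' @export
#' @examples
#' aggregate_angles(c(10, 20, 30), "mean")  # 20
aggregate_angles <- function(angles, agg = c("sum", "mean", "max")) {
  agg <- match.arg(agg)
  if (length(angles) == 0L) stop("empty angle set")
  switch(agg, sum = sum(angles), mean = mean(angles), max = max(angles))
}

# Unit bone vectors for every frame of a sequence: V x 3 x n array.
# Zero-norm vectors are flagged; lenient mode leaves a zero row which the
# cost kernel maps to 0 degrees.
.sequence_units <- function(seq, vset, degenerate = "lenient", eps = 1e-6) {
  if (!all(seq$valid)) {
    stop("feature extraction failed: sequence contains missing joints; run interpolate_missing() first")
  }
  si <- match(vset$start, joint_names())
  ei <- match(vset$end, joint_names())
  # n x V x 3 difference array
  d <- seq$positions[, ei, , drop = FALSE] - seq$positions[, si, , drop = FALSE]
  nrm <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  if (is.null(dim(nrm))) nrm <- matrix(nrm, nrow = dim(d)[1])
  zero <- nrm <= eps
  if (any(zero)) {
    if (degenerate == "strict") {
      stop("degenerate (zero-length) bone vector in sequence")
    }
    warning(sprintf("%d zero-length bone vector(s); their angle differences are taken as 0 degrees",
                    sum(zero)))
    nrm[zero] <- 1
  }
  for (k in 1:3) d[, , k] <- d[, , k] / nrm
  for (k in 1:3) d[, , k][zero] <- 0
  attr(d, "zero") <- zero
  d
}
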