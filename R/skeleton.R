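#' Construct a skeleton motion sequence
#'
#' A \code{skeleton_sequence} holds an ordered series of frames, each frame
#' giving the 3-D camera-space position (millimetres) of the 32 tracked
#' joints. This is the in-memory form of both the standard (template) and
#' test sequences that the recognizer aligns with dynamic time warping.
#'
#' @param positions numeric array of dimension \code{c(n_frames, 32, 3)}
#'   (joints in canonical \code{\link{joint_table}} order) or a list of
#'   32x3 per-frame matrices.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing. Defaults to \code{(0:(n-1))/fps}.
#' @param fps nominal frame rate, frames per second (default 30, the
#'   capture rate of the sensor protocol).
#' @param valid logical matrix \code{n_frames x 32}; \code{FALSE} marks a
#'   joint as untracked/missing in that frame. Defaults to all valid.
#' @param label optional action name.
#' @param subject_id optional subject identifier.
#'
#' @return An object of class \code{skeleton_sequence}.
#' @export
skeleton_sequence <- function(positions, timestamps = NULL, fps = 30,
                              valid = NULL, label = NULL, subject_id = NULL) {
  if (is.list(positions)) {
    n <- length(positions)
    arr <- array(NA_real_, dim = c(n, 32L, 3L))
    for (i in seq_len(n)) arr[i, , ] <- as.matrix(positions[[i]])
    positions <- arr
  }
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[2] != 32L || dim(positions)[3] != 3L) {
    stop("positions must be an n x 32 x 3 array")
  }
  n <- dim(positions)[1]
  if (n < 2L) stop("a skeleton_sequence needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / fps
  if (length(timestamps) != n) stop("timestamps length must match frame count")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (any(timestamps < 0)) stop("timestamps must be >= 0")
  if (is.null(valid)) {
    valid <- matrix(TRUE, n, 32L)
  } else {
    valid <- as.matrix(valid)
    if (!identical(dim(valid), c(n, 32L))) stop("valid must be n x 32 logical")
    mode(valid) <- "logical"
  }
  dimnames(positions) <- list(NULL, joint_names(), c("x", "y", "z"))
  colnames(valid) <- joint_names()
  structure(
    list(positions = positions, timestamps = as.numeric(timestamps),
         fps = fps, valid = valid, label = label, subject_id = subject_id),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence: %d frames @ %g fps%s%s>\n",
              n_frames(x), x$fps,
              if (is.null(x$label)) "" else paste0(", action=", x$label),
              if (is.null(x$subject_id)) "" else paste0(", subject=", x$subject_id)))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a \code{skeleton_sequence}
#' @return integer frame count
#' @export
n_frames <- function(seq) dim(seq$positions)[1]

#' Extract one frame as a 32 x 3 joint-position matrix
#'
#' @param seq a \code{skeleton_sequence}
#' @param i frame index (1-based)
#' @return list with \code{positions} (32 x 3 matrix, rows named by joint)
#'   and \code{valid} (named logical vector).
#' @export
skeleton_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  pos <- seq$positions[i, , , drop = TRUE]
  dim(pos) <- c(32L, 3L)
  dimnames(pos) <- list(joint_names(), c("x", "y", "z"))
  list(positions = pos, valid = stats::setNames(seq$valid[i, ], joint_names()))
}

#' Validate a skeleton sequence
#'
#' Reports, per frame, joints that are marked missing or carry non-finite
#' coordinates. A sequence passes when it satisfies the structural
#' invariants (>= 2 frames, increasing timestamps) and every defect is
#' recoverable by \code{\link{interpolate_missing}} -- i.e. no missing run
#' touches the first or last frame and no coordinate is non-finite after
#' masking missing joints.
#'
#' @param seq a \code{skeleton_sequence}
#' @return list with \code{pass} (logical), \code{n_defects}, and
#'   \code{defects}, a data.frame of (frame, joint, reason).
#' @export
validate_sequence <- function(seq) {
  defects <- list()
  add <- function(frame, joint, reason) {
    defects[[length(defects) + 1L]] <<- data.frame(
      frame = frame, joint = joint, reason = reason, stringsAsFactors = FALSE)
  }
  structural <- character(0)
  n <- dim(seq$positions)[1]
  if (n < 2L) structural <- c(structural, "fewer than 2 frames")
  if (any(diff(seq$timestamps) <= 0)) {
    structural <- c(structural, "timestamps not strictly increasing")
  }
  nonfinite <- !apply(is.finite(seq$positions), c(1, 2), all)
  missing <- !seq$valid
  for (j in seq_len(32L)) {
    for (i in which(missing[, j])) add(i, joint_names()[j], "missing")
    for (i in which(nonfinite[, j] & !missing[, j])) {
      add(i, joint_names()[j], "non-finite coordinates")
    }
  }
  defects <- if (length(defects)) do.call(rbind, defects) else
    data.frame(frame = integer(0), joint = character(0), reason = character(0))
  # recoverable iff interior missing runs only, and nothing non-finite among
  # valid joints
  recoverable <- !any(nonfinite & !missing)
  if (any(missing[1, ]) || any(missing[n, ])) recoverable <- FALSE
  pass <- length(structural) == 0L && recoverable
  list(pass = pass, n_defects = nrow(defects), defects = defects,
       structural = structural)
}

#' Fill missing joints by linear interpolation
#'
#' Each joint marked missing is replaced, per coordinate, by linear
#' interpolation in time between the nearest valid observations of that
#' joint. A missing run that touches the first or last frame has no
#' bracketing observation and is an unrecoverable gap.
#'
#' @param seq a \code{skeleton_sequence}
#' @return a \code{skeleton_sequence} with all joints valid.
#' @export
interpolate_missing <- function(seq) {
  if (all(seq$valid)) return(seq)
  n <- n_frames(seq)
  pos <- seq$positions
  for (j in which(colSums(!seq$valid) > 0L)) {
    ok <- seq$valid[, j]
    if (!ok[1] || !ok[n]) {
      stop(sprintf("unrecoverable gap: joint %s missing at a sequence boundary",
                   joint_names()[j]))
    }
    for (k in 1:3) {
      pos[, j, k] <- stats::approx(seq$timestamps[ok], pos[ok, j, k],
                                   xout = seq$timestamps)$y
    }
  }
  skeleton_sequence(pos, timestamps = seq$timestamps, fps = seq$fps,
                    label = seq$label, subject_id = seq$subject_id)
}

#' Mirror a sequence left-to-right
#'
#' Swaps every left/right joint pair and negates the x (lateral)
#' coordinate, turning e.g. a right-handed punch into its left-handed
#' mirror image. Mirroring twice returns the original sequence.
#'
#' @param seq a \code{skeleton_sequence}
#' @return the mirrored \code{skeleton_sequence}.
#' @export
mirror_sequence <- function(seq) {
  perm <- match(.mirror_pairs, joint_names())
  pos <- seq$positions[, perm, , drop = FALSE]
  pos[, , 1] <- -pos[, , 1]
  skeleton_sequence(pos, timestamps = seq$timestamps, fps = seq$fps,
                    valid = seq$valid[, perm, drop = FALSE],
                    label = seq$label, subject_id = seq$subject_id)
}

#' Resample a sequence to a new frame rate
#'
#' Joint trajectories are linearly interpolated in time onto a uniform
#' grid at \code{target_fps} starting at the first timestamp; the grid
#' extends as far as the original last timestamp, so total duration is
#' preserved to within one frame period.
#'
#' @param seq a \code{skeleton_sequence} (all joints valid)
#' @param target_fps requested frame rate, > 0
#' @return the resampled \code{skeleton_sequence}.
#' @export
resample <- function(seq, target_fps) {
  stopifnot(is.numeric(target_fps), length(target_fps) == 1L, target_fps > 0)
  if (!all(seq$valid)) stop("resample requires a fully valid sequence; run interpolate_missing() first")
  t0 <- seq$timestamps[1]
  t1 <- seq$timestamps[n_frames(seq)]
  ts <- seq(t0, t1 + 1e-9, by = 1 / target_fps)
  if (length(ts) < 2L) ts <- c(t0, t1)
  n <- length(ts)
  pos <- array(NA_real_, dim = c(n, 32L, 3L))
  for (j in 1:32) for (k in 1:3) {
    pos[, j, k] <- stats::approx(seq$timestamps, seq$positions[, j, k],
                                 xout = pmin(ts, t1))$y
  }
  skeleton_sequence(pos, timestamps = ts, fps = target_fps,
                    label = seq$label, subject_id = seq$subject_id)
}
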