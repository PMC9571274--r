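#' Joint table for the 32-joint depth-sensor skeleton
#'
#' The Azure-Kinect body model tracks 32 named joints. Fifteen of them --
#' the joints that carry most of the motion signal (pelvis, clavicles,
#' shoulders, elbows, wrists, hips, knees, ankles) -- additionally carry a
#' single-letter code used to name bone feature vectors compactly
#' (e.g. the vector \code{OA} runs from the pelvis \code{O} to the right
#' shoulder \code{A}).
#'
#' @return A data.frame with columns \code{index} (1..32, canonical order),
#'   \code{code} (single letter or \code{NA}), and \code{name}.
#' @export
#' @examples
#' jt <- joint_table()
#' jt[!is.na(jt$code), c("code", "name")]
joint_table <- function() {
  .joint_table
}

# canonical order; codes cover the 15 "lettered" joints
.joint_table <- data.frame(
  index = 1:32,
  code = c("O", NA, NA, NA, "Q", "D", "E", "F", NA, NA, NA,
           "P", "A", "B", "C", NA, NA, NA,
           "H", "J", "L", NA, "G", "I", "K", NA,
           NA, NA, NA, NA, NA, NA),
  name = c("PELVIS", "SPINE_NAVAL", "SPINE_CHEST", "NECK",
           "CLAVICLE_LEFT", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
           "HAND_LEFT", "HANDTIP_LEFT", "THUMB_LEFT",
           "CLAVICLE_RIGHT", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
           "HAND_RIGHT", "HANDTIP_RIGHT", "THUMB_RIGHT",
           "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
           "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
           "HEAD", "NOSE", "EYE_LEFT", "EAR_LEFT", "EYE_RIGHT", "EAR_RIGHT"),
  stringsAsFactors = FALSE
)

#' @rdname joint_table
#' @export
joint_names <- function() .joint_table$name

#' Resolve a single-letter joint code to its joint name
#'
#' @param code character vector of single-letter codes (e.g. \code{"O"},
#'   \code{"A"}).
#' @return character vector of joint names.
#' @export
#' @examples
#' joint_from_code(c("O", "A", "Q"))
joint_from_code <- function(code) {
  tab <- .joint_table[!is.na(.joint_table$code), ]
  idx <- match(code, tab$code)
  if (anyNA(idx)) {
    stop("unknown joint code(s): ", paste(code[is.na(idx)], collapse = ", "))
  }
  tab$name[idx]
}

# left/right partner of every lateral joint; midline joints map to themselves
.mirror_pairs <- local({
  nm <- .joint_table$name
  out <- nm
  left <- grep("_LEFT$", nm, value = TRUE)
  right <- sub("_LEFT$", "_RIGHT", left)
  stopifnot(all(right %in% nm))
  out[match(left, nm)] <- right
  out[match(right, nm)] <- left
  names(out) <- nm
  out
})
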