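# shared fixture builders -- everything is generated in code

# a small all-valid sequence with smoothly moving joints (not a scripted
# action; used where any well-formed kinematic input will do)
toy_sequence <- function(n = 5, fps = 30) {
  base <- matrix(seq_len(32 * 3) * 10, nrow = 32)  # distinct static pose
  pos <- array(NA_real_, dim = c(n, 32, 3))
  for (i in seq_len(n)) {
    pos[i, , ] <- base + (i - 1) * matrix(c(1, 2, 3), 32, 3, byrow = TRUE)
  }
  skeleton_sequence(pos, fps = fps)
}

# template library of noise-free scripted actions at reduced length
tiny_library <- function(frames = 40) {
  tpl <- lapply(stats::setNames(nm = unsafe_actions()), function(a) {
    generate_action(a, noise_mm = 0, frames = frames)
  })
  template_library(tpl)
}

# apply a rigid/affine map to every joint position
transform_sequence <- function(seq, f) {
  pos <- seq$positions
  for (i in seq_len(n_frames(seq))) {
    pos[i, , ] <- f(pos[i, , , drop = TRUE])
  }
  skeleton_sequence(pos, timestamps = seq$timestamps, fps = seq$fps,
                    valid = seq$valid, label = seq$label,
                    subject_id = seq$subject_id)
}

rotate_y_90 <- function(p) cbind(p[, 3], p[, 2], -p[, 1])

expected_code_map <- c(
  O = "PELVIS", Q = "CLAVICLE_LEFT", D = "SHOULDER_LEFT", E = "ELBOW_LEFT",
  F = "WRIST_LEFT", P = "CLAVICLE_RIGHT", A = "SHOULDER_RIGHT",
  B = "ELBOW_RIGHT", C = "WRIST_RIGHT", H = "HIP_LEFT", J = "KNEE_LEFT",
  L = "ANKLE_LEFT", G = "HIP_RIGHT", I = "KNEE_RIGHT", K = "ANKLE_RIGHT")
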