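# Forward-kinematic generator of synthetic skeleton sequences for the
# five unsafe behaviors (punch, one-armed call for help, arms for help,
# trip forward, trip backwards) and two safe behaviors (stand, squat).
# Poses are scripted as joint-angle trajectories on a rigid segment model,
# so noise-free frames conserve segment lengths exactly; subject-to-subject
# variation enters through a body-scale factor, per-subject style offsets
# on the key pose angles, tempo jitter, and i.i.d. Gaussian joint noise.

#' Parametric body model for the synthetic generator
#'
#' Segment lengths in millimetres for a nominal adult, all multiplied by
#' \code{scale}. Lengths are held exactly constant within a noise-free
#' generated sequence.
#'
#' @param scale global body-scale factor (cohort default range 0.85-1.15)
#' @param handedness \code{"right"} or \code{"left"}; left-handed bodies
#'   are produced by mirroring the right-handed motion
#' @param upper_arm,forearm,thigh,shank,torso_lower,torso_mid,torso_upper,
#'   neck_head,clavicle_out,shoulder_out,pelvis_half_width segment lengths
#'   in mm before scaling
#' @return a \code{body_model} list.
#' @export
body_model <- function(scale = 1, handedness = c("right", "left"),
                       upper_arm = 280, forearm = 250, thigh = 440,
                       shank = 420, torso_lower = 150, torso_mid = 150,
                       torso_upper = 120, neck_head = 120,
                       clavicle_out = 60, shoulder_out = 110,
                       pelvis_half_width = 100) {
  handedness <- match.arg(handedness)
  stopifnot(scale > 0, upper_arm > 0, forearm > 0, thigh > 0, shank > 0)
  structure(list(
    scale = scale, handedness = handedness,
    upper_arm = upper_arm, forearm = forearm, thigh = thigh, shank = shank,
    torso_lower = torso_lower, torso_mid = torso_mid,
    torso_upper = torso_upper, neck_head = neck_head,
    clavicle_out = clavicle_out, shoulder_out = shoulder_out,
    pelvis_half_width = pelvis_half_width
  ), class = "body_model")
}

# evaluate code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# limb direction in the body frame from elevation (0 = hanging straight
# down, 90 = horizontal, 180 = straight up) and azimuth (0 = sagittal /
# forward, positive = outward-lateral for the given side)
.limb_dir <- function(elev, azim, side) {
  e <- elev * pi / 180; a <- azim * pi / 180
  cbind(side * sin(e) * sin(a), -cos(e), sin(e) * cos(a))
}

.smoothstep <- function(p, a, b) {
  x <- pmin(1, pmax(0, (p - a) / (b - a)))
  x * x * (3 - 2 * x)
}

# Per-frame pose parameters (degrees / mm) for one action. `p` is the
# normalized script phase in [0, 1]; `style` carries per-subject angle
# offsets. Returns a list of numeric vectors, one value per frame.
.action_script <- function(action, p, style) {
  n <- length(p)
  z <- numeric(n)
  # neutral standing pose
  par <- list(
    pitch = z, drop = z, shift = z,
    r_elev = z + 15, r_azim = z + 12, r2_elev = z + 20, r2_azim = z + 12,
    l_elev = z + 15, l_azim = z + 12, l2_elev = z + 20, l2_azim = z + 12,
    rl_elev = z + 3, rl_azim = z + 4, rl2_elev = z + 3, rl2_azim = z + 4,
    ll_elev = z + 3, ll_azim = z + 4, ll2_elev = z + 3, ll2_azim = z + 4
  )
  if (action == "stand") {
    # static; tiny postural sway so frames are not bit-identical
    par$r_elev <- par$r_elev + 2 * sin(2 * pi * p)
    par$l_elev <- par$l_elev + 2 * sin(2 * pi * p + 1)
  } else if (action == "squat") {
    s <- .smoothstep(p, 0.15, 0.45) - .smoothstep(p, 0.75, 0.95)
    par$drop <- 340 * s
    par$rl_elev <- par$ll_elev <- 3 + 82 * s      # thighs swing forward
    par$rl2_elev <- par$ll2_elev <- 3 + 40 * s    # shanks trail backward
    par$rl2_azim <- par$ll2_azim <- 4 + 176 * s
    par$pitch <- 5 * s                            # slight forward lean
  } else if (action == "punch") {
    # guard stance with three jab cycles of the punching arm
    ext <- sin(pi * ((p * 3) %% 1))^2
    par$r_elev <- 72 + 18 * ext
    par$r_azim <- 10 - 8 * ext
    par$r2_elev <- 112 - 22 * ext
    par$r2_azim <- 10 - 8 * ext
    par$l_elev <- z + 60; par$l_azim <- z + 15
    par$l2_elev <- z + 105; par$l2_azim <- z + 8
  } else if (action == "one_armed_call_for_help") {
    up <- .smoothstep(p, 0, 0.15)
    wave <- sin(2 * pi * 3 * p)
    par$r_elev <- 15 + up * (145 + 8 * wave)
    par$r_azim <- 12 + up * (-12 + 30 * wave)
    par$r2_elev <- 20 + up * (148 + 10 * wave)
    par$r2_azim <- 12 + up * (-12 + 42 * wave)
  } else if (action == "arms_for_help") {
    up <- .smoothstep(p, 0, 0.15)
    wave <- sin(2 * pi * 2 * p)
    for (s in c("r", "l")) {
      par[[paste0(s, "_elev")]] <- 15 + up * (122 + 5 * wave)
      par[[paste0(s, "_azim")]] <- 12 + up * (16 + 8 * wave)
      par[[paste0(s, "2_elev")]] <- 20 + up * (128 + 6 * wave)
      par[[paste0(s, "2_azim")]] <- 12 + up * (20 + 10 * wave)
    }
  } else if (action %in% c("trip_forward", "trip_backwards")) {
    fwd <- action == "trip_forward"
    s <- .smoothstep(p, 0.12, 0.38)   # fall early, stay down
    par$pitch <- (if (fwd) 88 else -80) * s
    par$drop <- 520 * s
    par$shift <- (if (fwd) 320 else -320) * s
    # arms reach out to break the fall
    par$r_elev <- par$l_elev <- 15 + (if (fwd) 75 else 55) * s
    par$r_azim <- par$l_azim <- 12 + 8 * s
    par$r2_elev <- par$l2_elev <- 20 + (if (fwd) 72 else 50) * s
    # legs buckle slightly
    par$rl_elev <- par$ll_elev <- 3 + 25 * s
    par$rl2_elev <- par$ll2_elev <- 3 + 30 * s
    par$rl2_azim <- par$ll2_azim <- 4 + 176 * s
  } else {
    stop("unknown action: ", action)
  }
  # per-subject style: constant offsets on the arm and trunk angles
  if (!is.null(style)) {
    for (f in c("r_elev", "l_elev")) par[[f]] <- par[[f]] + style$arm_elev
    for (f in c("r_azim", "l_azim")) par[[f]] <- par[[f]] + style$arm_azim
    for (f in c("r2_elev", "l2_elev")) par[[f]] <- par[[f]] + style$arm_elev
    par$pitch <- par$pitch + style$trunk_pitch
  }
  par
}

# assemble the 32-joint world positions for scripted pose parameters
.pose_frames <- function(body, par, n) {
  b <- body
  sc <- b$scale
  H <- 900 * sc                       # standing pelvis height
  jn <- joint_names()
  pos <- array(NA_real_, dim = c(n, 32L, 3L))
  put <- function(name, xyz) pos[, match(name, jn), ] <<- xyz
  phi <- par$pitch * pi / 180
  # body frame -> world: pitch about the lateral (x) axis, forward = +z
  rot <- function(pmat) {
    cbind(pmat[, 1],
          cos(phi) * pmat[, 2] - sin(phi) * pmat[, 3],
          sin(phi) * pmat[, 2] + cos(phi) * pmat[, 3])
  }
  origin <- cbind(0, H - par$drop, 2500 + par$shift)
  place <- function(name, pmat) put(name, origin + rot(pmat))
  cvec <- function(x, y, z) cbind(rep(x, n), rep(y, n), rep(z, n))

  place("PELVIS", cvec(0, 0, 0))
  naval <- cvec(0, b$torso_lower * sc, 0)
  chest <- naval + cvec(0, b$torso_mid * sc, 0)
  neck <- chest + cvec(0, b$torso_upper * sc, 0)
  head <- neck + cvec(0, b$neck_head * sc, 0)
  place("SPINE_NAVAL", naval); place("SPINE_CHEST", chest)
  place("NECK", neck); place("HEAD", head)
  place("NOSE", head + cvec(0, 20 * sc, 90 * sc))
  place("EYE_LEFT", head + cvec(-30 * sc, 40 * sc, 70 * sc))
  place("EYE_RIGHT", head + cvec(30 * sc, 40 * sc, 70 * sc))
  place("EAR_LEFT", head + cvec(-70 * sc, 30 * sc, 0))
  place("EAR_RIGHT", head + cvec(70 * sc, 30 * sc, 0))

  for (side in c(1, -1)) {
    sfx <- if (side == 1) "RIGHT" else "LEFT"
    pfx <- if (side == 1) "r" else "l"
    lfx <- if (side == 1) "rl" else "ll"
    clav <- chest + cvec(side * b$clavicle_out * sc, 30 * sc, 0)
    shoulder <- clav + cvec(side * b$shoulder_out * sc, 0, 0)
    u1 <- .limb_dir(par[[paste0(pfx, "_elev")]], par[[paste0(pfx, "_azim")]], side)
    u2 <- .limb_dir(par[[paste0(pfx, "2_elev")]], par[[paste0(pfx, "2_azim")]], side)
    elbow <- shoulder + b$upper_arm * sc * u1
    wrist <- elbow + b$forearm * sc * u2
    place(paste0("CLAVICLE_", sfx), clav)
    place(paste0("SHOULDER_", sfx), shoulder)
    place(paste0("ELBOW_", sfx), elbow)
    place(paste0("WRIST_", sfx), wrist)
    place(paste0("HAND_", sfx), wrist + 80 * sc * u2)
    place(paste0("HANDTIP_", sfx), wrist + 150 * sc * u2)
    place(paste0("THUMB_", sfx), wrist + cvec(-side * 40 * sc, 0, 20 * sc))
    hip <- cvec(side * b$pelvis_half_width * sc, -20 * sc, 0)
    v1 <- .limb_dir(par[[paste0(lfx, "_elev")]], par[[paste0(lfx, "_azim")]], side)
    v2 <- .limb_dir(par[[paste0(lfx, "2_elev")]], par[[paste0(lfx, "2_azim")]], side)
    knee <- hip + b$thigh * sc * v1
    ankle <- knee + b$shank * sc * v2
    place(paste0("HIP_", sfx), hip)
    place(paste0("KNEE_", sfx), knee)
    place(paste0("ANKLE_", sfx), ankle)
    place(paste0("FOOT_", sfx), ankle + cvec(0, -20 * sc, 150 * sc))
  }
  pos
}

#' Generate one synthetic action sequence
#'
#' Evaluates the action's motion script at \code{frames} time points,
#' poses the rigid body model by forward kinematics, then adds i.i.d.
#' Gaussian position noise. Deterministic for fixed arguments (the seed
#' drives all randomness through a private RNG stream).
#'
#' @param action one of \code{\link{all_actions}()}
#' @param body a \code{\link{body_model}}
#' @param frames frame count (default 300: the 10-second capture
#'   protocol at 30 f/s)
#' @param fps frames per second (default 30)
#' @param noise_mm standard deviation of the per-joint, per-frame
#'   Gaussian position noise (default 10 mm, a plausible consumer depth
#'   sensor tracking error)
#' @param tempo execution-speed factor; the script phase is
#'   \code{min(1, tempo * t / duration)}, so tempo > 1 finishes the
#'   movement early and holds the final pose
#' @param seed integer seed for the noise stream (\code{NULL} uses the
#'   current RNG state)
#' @param style optional per-subject style offsets, a list with
#'   \code{arm_elev}, \code{arm_azim}, \code{trunk_pitch} in degrees
#' @param subject_id optional subject tag stored on the sequence
#' @return a labelled \code{\link{skeleton_sequence}}.
#' @export
#' @examples
#' s <- generate_action("punch", seed = 1, noise_mm = 0)
#' s
generate_action <- function(action, body = body_model(), frames = 300,
                            fps = 30, noise_mm = 10, tempo = 1,
                            seed = NULL, style = NULL, subject_id = NULL) {
  action <- match.arg(action, all_actions())
  if (frames < 2 || fps <= 0) stop("frames must be >= 2 and fps > 0")
  if (noise_mm < 0 || tempo <= 0) stop("noise_mm must be >= 0 and tempo > 0")
  t <- (seq_len(frames) - 1) / fps
  p <- pmin(1, tempo * t / t[frames])
  par <- .action_script(action, p, style)
  pos <- .pose_frames(body, par, frames)
  if (noise_mm > 0) {
    pos <- pos + .with_seed(seed, array(stats::rnorm(length(pos), 0, noise_mm),
                                        dim = dim(pos)))
  }
  out <- skeleton_sequence(pos, timestamps = t, fps = fps, label = action,
                           subject_id = subject_id)
  if (body$handedness == "left") {
    lab <- out$label; sid <- out$subject_id
    out <- mirror_sequence(out)
    out$label <- lab; out$subject_id <- sid
  }
  out
}

#' Generate a labelled synthetic cohort plus its template library
#'
#' Emulates the source capture protocol: one designated standard subject
#' (nominal body, no noise, unit tempo) provides the template per unsafe
#' action, and \code{n_subjects} test subjects perform every action
#' \code{reps_per_action} times with per-subject body scale and style
#' variation, per-repetition tempo jitter, and position noise. All seeds
#' are derived from \code{base_seed}; the same arguments always
#' regenerate the identical cohort.
#'
#' @param n_subjects number of test subjects (default 6)
#' @param reps_per_action repetitions of each action per subject
#'   (default 10, giving 60 test sequences per action)
#' @param actions actions performed by the test subjects (default: all
#'   seven; templates are built only for the five unsafe actions)
#' @param frames,fps capture length and rate per sequence
#' @param base_seed master seed
#' @param noise_mm test-sequence position-noise standard deviation, mm
#' @param tempo_jitter half-width of the uniform tempo variation
#'   (default 0.15: tempo in [0.85, 1.15])
#' @param scale_range range of the per-subject body-scale factor
#' @param style_sd standard deviation, degrees, of the per-subject style
#'   offsets on arm elevation/azimuth and trunk pitch
#' @param dir if non-NULL, write template CSVs, a template manifest, all
#'   test CSVs and a cohort manifest into this directory
#' @return list with \code{library} (a \code{template_library}),
#'   \code{cohort} (list of labelled sequences), and \code{manifest}
#'   (every parameter and derived seed, for exact regeneration).
#' @export
generate_cohort <- function(n_subjects = 6, reps_per_action = 10,
                            actions = all_actions(), frames = 300, fps = 30,
                            base_seed = 42, noise_mm = 10,
                            tempo_jitter = 0.15, scale_range = c(0.85, 1.15),
                            style_sd = 4, dir = NULL) {
  if (n_subjects < 1 || reps_per_action < 1) {
    stop("n_subjects and reps_per_action must be positive")
  }
  actions <- match.arg(actions, all_actions(), several.ok = TRUE)
  tmpl_actions <- unsafe_actions()  # safe behaviors have no templates
  templates <- stats::setNames(lapply(tmpl_actions, function(a) {
    generate_action(a, body_model(), frames = frames, fps = fps,
                    noise_mm = 0, tempo = 1, subject_id = "standard")
  }), tmpl_actions)
  library <- template_library(templates, fps = fps)

  subjects <- .with_seed(base_seed, lapply(seq_len(n_subjects), function(s) {
    list(id = sprintf("S%02d", s),
         scale = stats::runif(1, scale_range[1], scale_range[2]),
         style = list(arm_elev = stats::rnorm(1, 0, style_sd),
                      arm_azim = stats::rnorm(1, 0, style_sd),
                      trunk_pitch = stats::rnorm(1, 0, style_sd / 2)))
  }))

  cohort <- list()
  records <- list()
  for (s in seq_len(n_subjects)) {
    sub <- subjects[[s]]
    body <- body_model(scale = sub$scale)
    for (a in seq_along(actions)) {
      for (r in seq_len(reps_per_action)) {
        seed <- base_seed + 100000L + s * 1000L + a * 100L + r
        tempo <- .with_seed(seed + 50L,
                            stats::runif(1, 1 - tempo_jitter, 1 + tempo_jitter))
        seq <- generate_action(actions[a], body, frames = frames, fps = fps,
                               noise_mm = noise_mm, tempo = tempo,
                               seed = seed, style = sub$style,
                               subject_id = sub$id)
        key <- sprintf("%s_%s_r%02d", sub$id, actions[a], r)
        cohort[[key]] <- seq
        records[[key]] <- list(subject = sub$id, action = actions[a],
                               rep = r, seed = seed, tempo = tempo,
                               scale = sub$scale)
      }
    }
  }
  manifest <- list(
    n_subjects = n_subjects, reps_per_action = reps_per_action,
    actions = actions, frames = frames, fps = fps, base_seed = base_seed,
    noise_mm = noise_mm, tempo_jitter = tempo_jitter,
    scale_range = scale_range, style_sd = style_sd,
    subjects = subjects, sequences = records)
  if (!is.null(dir)) {
    .write_cohort(dir, library, cohort, manifest)
  }
  list(library = library, cohort = cohort, manifest = manifest)
}

.write_cohort <- function(dir, library, cohort, manifest) {
  dir.create(file.path(dir, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "tests"), recursive = TRUE, showWarnings = FALSE)
  tmpl_entries <- lapply(names(library$templates), function(a) {
    f <- file.path("templates", paste0(a, "_std.csv"))
    write_sequence_csv(library$templates[[a]], file.path(dir, f))
    list(action = a, file = f)
  })
  jsonlite::write_json(list(fps = library$fps, templates = tmpl_entries),
                       file.path(dir, "templates.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  for (key in names(cohort)) {
    write_sequence_csv(cohort[[key]],
                       file.path(dir, "tests", paste0(key, ".csv")))
    manifest$sequences[[key]]$file <- file.path("tests", paste0(key, ".csv"))
  }
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(dir)
}

#' Load a cohort written by \code{\link{generate_cohort}}
#'
#' @param dir cohort directory containing \code{templates.json},
#'   \code{cohort.json}, and the referenced CSVs
#' @return list with \code{library}, \code{cohort}, \code{manifest}.
#' @export
load_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                  simplifyVector = FALSE)
  library <- load_template_library(file.path(dir, "templates.json"))
  cohort <- lapply(manifest$sequences, function(rec) {
    read_sequence_csv(file.path(dir, rec$file), fps = manifest$fps,
                      label = rec$action, subject_id = rec$subject)
  })
  list(library = library, cohort = cohort, manifest = manifest)
}
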