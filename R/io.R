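# Canonical on-disk format for a sequence: one CSV row per frame with
# header frame,timestamp_s,<JOINT>_x,<JOINT>_y,<JOINT>_z[,<JOINT>_conf]
# for the 32 joints in canonical order; mm / seconds, '.' decimal.

.csv_header <- function(conf = TRUE) {
  jn <- joint_names()
  h <- c("frame", "timestamp_s",
         as.vector(t(outer(jn, c("_x", "_y", "_z"), paste0))))
  if (conf) h <- c(h, paste0(jn, "_conf"))
  h
}

#' Read a skeleton sequence from CSV
#'
#' Expects the package's canonical dialect: a header row
#' \code{frame,timestamp_s,<JOINT>_x,<JOINT>_y,<JOINT>_z} for the 32
#' joints in canonical order, optionally followed by 32
#' \code{<JOINT>_conf} columns (1 = tracked, 0 = missing; absent
#' confidence columns mark every joint valid). Units are millimetres and
#' seconds.
#'
#' @param path CSV file path
#' @param fps frame rate recorded in the returned sequence when the file's
#'   timestamps do not determine one (default: inferred from timestamps,
#'   falling back to 30)
#' @param label,subject_id optional metadata attached to the sequence
#' @return a \code{\link{skeleton_sequence}}.
#' @export
read_sequence_csv <- function(path, fps = NULL, label = NULL,
                              subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  h96 <- .csv_header(conf = FALSE)
  h128 <- .csv_header(conf = TRUE)
  if (identical(names(df), h128)) {
    has_conf <- TRUE
  } else if (identical(names(df), h96)) {
    has_conf <- FALSE
  } else {
    stop(sprintf("parse error in %s: expected %d or %d columns in the canonical joint order, found %d (header mismatch starts at column %d)",
                 path, length(h96), length(h128), ncol(df),
                 { m <- min(length(names(df)), length(h128))
                   w <- which(names(df)[seq_len(m)] != h128[seq_len(m)])
                   if (length(w)) w[1] else m + 1L }))
  }
  n <- nrow(df)
  if (n < 2L) stop("parse error in ", path, ": a sequence needs at least 2 data rows")
  num <- df[, setdiff(names(df), "frame")]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    stop("parse error in ", path, ": non-numeric cell(s) in column(s) ",
         paste(names(num)[bad], collapse = ", "))
  }
  pos <- array(NA_real_, dim = c(n, 32L, 3L))
  for (j in seq_len(32L)) {
    base <- 2L + (j - 1L) * 3L
    pos[, j, ] <- as.matrix(df[, base + (1:3)])
  }
  valid <- if (has_conf) {
    as.matrix(df[, 98L + seq_len(32L)]) > 0
  } else NULL
  ts <- df$timestamp_s
  if (is.null(fps)) {
    fps <- if (n >= 2L && all(diff(ts) > 0)) (n - 1) / (ts[n] - ts[1]) else 30
  }
  skeleton_sequence(pos, timestamps = ts, fps = fps, valid = valid,
                    label = label, subject_id = subject_id)
}

#' Write a skeleton sequence to CSV
#'
#' Emits the canonical dialect (see \code{\link{read_sequence_csv}}),
#' including the 32 confidence columns, with coordinates fixed to six
#' decimal places so that identical sequences always produce
#' byte-identical files and a write/read round trip preserves positions
#' to 1e-6 mm.
#'
#' @param seq a \code{\link{skeleton_sequence}}
#' @param path output file path
#' @return invisibly, \code{path}.
#' @export
write_sequence_csv <- function(seq, path) {
  if (!inherits(seq, "skeleton_sequence")) stop("seq must be a skeleton_sequence")
  n <- n_frames(seq)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.csv_header(conf = TRUE), collapse = ","), con)
  coords <- matrix(NA_real_, n, 96L)
  for (j in seq_len(32L)) coords[, (j - 1L) * 3L + (1:3)] <- seq$positions[, j, ]
  for (i in seq_len(n)) {
    row <- c(sprintf("%d", i - 1L),
             sprintf("%.6f", seq$timestamps[i]),
             sprintf("%.6f", coords[i, ]),
             sprintf("%d", as.integer(seq$valid[i, ])))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Convert a spreadsheet recording to the canonical CSV
#'
#' Convenience import for recordings saved as .xlsx with the same column
#' layout as the canonical CSV. Requires the \pkg{readxl} package.
#'
#' @param xlsx_path input workbook (first sheet is read)
#' @param csv_path output CSV path
#' @return invisibly, \code{csv_path}.
#' @export
convert_xlsx_to_csv <- function(xlsx_path, csv_path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("xlsx import needs the 'readxl' package")
  }
  df <- as.data.frame(readxl::read_excel(xlsx_path))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  seq <- read_sequence_csv(tmp)
  unlink(tmp)
  write_sequence_csv(seq, csv_path)
}

#' Build a template library from in-memory sequences
#'
#' @param templates named list of \code{skeleton_sequence} objects, one
#'   per action; names must be distinct known actions
#' @param fps nominal frame rate of the library
#' @param defaults optional list of default model settings (scheme,
#'   aggregation, mode, threshold) carried as metadata
#' @return a \code{template_library}.
#' @export
template_library <- function(templates, fps = 30, defaults = NULL) {
  acts <- names(templates)
  if (length(acts) != length(unique(acts))) {
    stop("duplicate action name(s) in template library")
  }
  bad <- setdiff(acts, all_actions())
  if (length(bad)) {
    stop("unknown action name(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(all_actions(), collapse = ", "), ")")
  }
  structure(list(templates = templates, fps = fps, defaults = defaults),
            class = "template_library")
}

#' Load a template library from a JSON manifest
#'
#' The manifest maps action names to standard-sequence CSV files:
#' \preformatted{
#' {"fps": 30,
#'  "templates": [{"action": "punch", "file": "punch_std.csv"}, ...]}
#' }
#' File paths are resolved relative to the manifest's directory. Every
#' referenced file must exist, parse, and pass validation; action names
#' must be unique and drawn from the supported repertoire.
#'
#' @param manifest path to the manifest JSON
#' @return a \code{template_library} with all sequences loaded.
#' @export
load_template_library <- function(manifest) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  spec <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  fps <- if (!is.null(spec$fps)) spec$fps else 30
  entries <- spec$templates
  if (is.null(entries)) entries <- list()
  acts <- vapply(entries, function(e) e$action, character(1))
  if (anyDuplicated(acts)) {
    stop("duplicate action name(s) in manifest: ",
         paste(unique(acts[duplicated(acts)]), collapse = ", "))
  }
  base <- dirname(manifest)
  templates <- list()
  for (e in entries) {
    f <- e$file
    if (!file.exists(f)) f <- file.path(base, e$file)
    if (!file.exists(f)) stop("template file not found: ", e$file)
    s <- read_sequence_csv(f, fps = fps, label = e$action)
    v <- validate_sequence(s)
    if (!v$pass) {
      stop("template for '", e$action, "' fails validation (",
           v$n_defects, " defect(s))")
    }
    templates[[e$action]] <- s
  }
  template_library(templates, fps = fps, defaults = spec$defaults)
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library: %d action(s) @ %g fps>\n",
              length(x$templates), x$fps))
  for (a in names(x$templates)) {
    cat(sprintf("  %-25s %d frames\n", a, n_frames(x$templates[[a]])))
  }
  invisible(x)
}
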