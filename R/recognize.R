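#' Recognition model configuration
#'
#' A model is one cell of the 3 x 4 experiment grid: an aggregation
#' attribute (sum = group A, mean = group B, max = group C) crossed with a
#' vector-selection scheme (1 = overall adjacent, 2 = overall pelvis,
#' 3 = local adjacent, 4 = local pelvis), giving model ids A1..C4. The
#' best-performing cell in the source experiments is C4 (local pelvis
#' divergence + maximum angle difference), which is the default.
#'
#' @param scheme one of \code{\link{vector_schemes}()}
#' @param agg one of \code{\link{angle_aggregations}()}
#' @param mode similarity normalizer, see \code{\link{similarity_score}}
#' @param threshold unsafe-warning threshold as a fraction in (0, 1);
#'   a best similarity strictly above it raises the red warning
#' @return a \code{model_config} list, including the derived
#'   \code{model_id}.
#' @export
#' @examples
#' model_config("local_pelvis", "max")$model_id  # "C4"
model_config <- function(scheme = "local_pelvis", agg = "max",
                         mode = c("bounded", "paper_literal"),
                         threshold = 0.75) {
  scheme <- match.arg(scheme, vector_schemes())
  agg <- match.arg(agg, angle_aggregations())
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  structure(
    list(scheme = scheme, agg = agg, mode = mode, threshold = threshold,
         model_id = model_id(scheme, agg)),
    class = "model_config"
  )
}

#' @rdname model_config
#' @export
model_id <- function(scheme, agg) {
  paste0(c(sum = "A", mean = "B", max = "C")[[agg]],
         match(scheme, vector_schemes()))
}

#' @rdname model_config
#' @export
model_grid <- function(mode = "bounded", threshold = 0.75) {
  out <- list()
  for (agg in angle_aggregations()) {
    for (scheme in vector_schemes()) {
      cfg <- model_config(scheme, agg, mode = mode, threshold = threshold)
      out[[cfg$model_id]] <- cfg
    }
  }
  out
}

#' Similarity between a standard and a test sequence for one action
#'
#' Runs the full pipeline: select the action's feature-vector set under
#' the configured scheme, build the aggregated angle-difference cost
#' matrix, align with DTW, and convert the optimal-path cost to a
#' similarity fraction.
#'
#' @param std,test \code{skeleton_sequence} objects
#' @param action the action whose vector set to use (relevant for local
#'   schemes)
#' @param config a \code{\link{model_config}}
#' @param details if \code{TRUE}, also return the DTW value, path length
#'   and V
#' @return similarity fraction in \code{[0, 1]} (or a list when
#'   \code{details = TRUE}).
#' @export
compare <- function(std, test, action, config = model_config(),
                    details = FALSE) {
  vset <- vector_set_for(config$scheme, action)
  cost <- build_cost_matrix(std, test, vset, agg = config$agg)
  dp <- dtw_accumulate(cost)
  path <- optimal_path(dp, cost)
  sim <- similarity_score(dp$dtw_value, V = vset$V, l = path$length_l,
                          agg = config$agg, mode = config$mode)
  if (!details) return(sim)
  list(similarity = sim, dtw_value = dp$dtw_value, V = vset$V,
       l = path$length_l, model_id = config$model_id,
       agg = config$agg, scheme = config$scheme, mode = config$mode)
}

#' Recognize a test sequence against a template library
#'
#' Scores the test sequence against every template (each action using its
#' own vector set under local schemes, the shared set under overall
#' schemes), picks the best-matching action, and raises the unsafe
#' warning when the best similarity strictly exceeds the threshold. Safe
#' behaviors have no templates: they are recognized implicitly when every
#' similarity stays below the threshold (green light).
#'
#' @param test a \code{skeleton_sequence}
#' @param library a \code{template_library} from
#'   \code{\link{load_template_library}} or \code{\link{template_library}}
#' @param config a \code{\link{model_config}}
#' @return a \code{recognition_result}: list with \code{per_action}
#'   (named similarity vector), \code{best_action}, \code{best_similarity},
#'   \code{unsafe}, and \code{warning_light} (\code{"red"}/\code{"green"}).
#' @export
recognize <- function(test, library, config = model_config()) {
  acts <- names(library$templates)
  if (length(acts) == 0L) stop("empty template library")
  sims <- vapply(acts, function(a) {
    compare(library$templates[[a]], test, action = a, config = config)
  }, numeric(1))
  best <- which.max(sims)  # ties: first in library declaration order
  unsafe <- sims[[best]] > config$threshold
  structure(
    list(per_action = sims, best_action = acts[[best]],
         best_similarity = sims[[best]], unsafe = unsafe,
         warning_light = if (unsafe) "red" else "green",
         model_id = config$model_id, threshold = config$threshold),
    class = "recognition_result"
  )
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("<recognition [%s]: best=%s %.1f%% -> %s light>\n",
              x$model_id, x$best_action, 100 * x$best_similarity,
              x$warning_light))
  for (a in names(x$per_action)) {
    cat(sprintf("  %-25s %5.1f%%\n", a, 100 * x$per_action[[a]]))
  }
  invisible(x)
}

#' Evaluate labelled sequences under one or more model configurations
#'
#' For each configuration, every cohort sequence is recognized against
#' the library. The report gives, per action: the number of tests, the
#' mean same-action similarity (for actions that have a template), the
#' count of correct judgments, and the red/green warning counts. A test
#' counts as correct when an unsafe-labelled sequence is flagged red
#' \emph{and} attributed to its own action, or a safe-labelled sequence
#' stays green. Overall accuracy is correct judgments over total tests.
#'
#' @param cohort list of labelled \code{skeleton_sequence} objects (each
#'   must carry \code{label})
#' @param library a template library
#' @param configs a single \code{\link{model_config}} or a list of them
#' @return an \code{evaluation_report}: per-model list with
#'   \code{per_action} data.frame, \code{confusion} matrix,
#'   \code{accuracy}, and the model configuration.
#' @export
evaluate <- function(cohort, library, configs = model_config()) {
  if (inherits(configs, "model_config")) configs <- list(configs)
  labels <- vapply(cohort, function(s) {
    if (is.null(s$label)) stop("every cohort sequence needs a label")
    s$label
  }, character(1))
  known <- c(names(library$templates), safe_actions())
  if (!all(labels %in% known)) {
    stop("cohort label(s) not in library or safe-action list: ",
         paste(setdiff(labels, known), collapse = ", "))
  }
  out <- list()
  for (cfg in configs) {
    results <- lapply(cohort, recognize, library = library, config = cfg)
    pred <- vapply(results, `[[`, character(1), "best_action")
    best <- vapply(results, `[[`, numeric(1), "best_similarity")
    red <- vapply(results, `[[`, logical(1), "unsafe")
    own <- vapply(seq_along(cohort), function(i) {
      if (labels[i] %in% names(library$templates)) {
        results[[i]]$per_action[[labels[i]]]
      } else NA_real_
    }, numeric(1))
    correct <- ifelse(labels %in% safe_actions(),
                      !red, red & pred == labels)
    acts <- unique(labels)
    per_action <- do.call(rbind, lapply(acts, function(a) {
      sel <- labels == a
      data.frame(
        action = a,
        n = sum(sel),
        correct = sum(correct[sel]),
        mean_similarity = if (all(is.na(own[sel]))) mean(best[sel]) else
          mean(own[sel]),
        red = sum(red[sel]), green = sum(!red[sel]),
        stringsAsFactors = FALSE)
    }))
    confusion <- table(factor(labels, levels = c(names(library$templates),
                                                 safe_actions())),
                       factor(pred, levels = names(library$templates)))
    out[[cfg$model_id]] <- list(
      model_id = cfg$model_id, scheme = cfg$scheme, agg = cfg$agg,
      mode = cfg$mode, threshold = cfg$threshold,
      per_action = per_action, confusion = confusion,
      accuracy = mean(correct), n_tests = length(cohort))
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (blk in x) {
    cat(sprintf("== model %s (%s, %s, %s) accuracy %.1f%% on %d tests ==\n",
                blk$model_id, blk$scheme, blk$agg, blk$mode,
                100 * blk$accuracy, blk$n_tests))
    df <- blk$per_action
    for (r in seq_len(nrow(df))) {
      cat(sprintf("  %-25s n=%-3d correct=%-3d mean similarity %5.1f%%  (%d red / %d green)\n",
                  df$action[r], df$n[r], df$correct[r],
                  100 * df$mean_similarity[r], df$red[r], df$green[r]))
    }
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes one CSV per model (action, n, correct, mean similarity,
#' red/green counts) and a single JSON file holding the confusion
#' matrices and accuracies.
#'
#' @param report an \code{evaluation_report}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  js <- list()
  for (blk in report) {
    df <- blk$per_action
    df$mean_similarity_pct <- sprintf("%.1f", 100 * df$mean_similarity)
    df$mean_similarity <- NULL
    p <- file.path(dir, paste0("model_", blk$model_id, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    js[[blk$model_id]] <- list(
      scheme = blk$scheme, agg = blk$agg, mode = blk$mode,
      threshold = blk$threshold, accuracy = blk$accuracy,
      n_tests = blk$n_tests,
      confusion = as.data.frame.matrix(unclass(blk$confusion)))
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(paths, jp))
}
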