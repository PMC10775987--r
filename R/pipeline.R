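#' Run the full model-comparison analysis
#'
#' Orchestrates the whole pipeline: maze -> labeled graph -> multi-restart
#' embedding -> shortcut predictions -> local-frame prediction errors ->
#' circular statistics -> BIC. Estimates may be supplied (e.g. loaded with
#' [load_deposited_estimates()]) or generated synthetically from one
#' model's predictions with von Mises noise.
#'
#' Prediction errors are, by default, computed in the local reference
#' frame of each starting arm (the embedding has no global reference
#' direction); a global-frame mode exists for Euclidean control runs.
#' Group-level tests follow the per-subject structure: each subject's
#' trial errors are reduced to a circular mean, Rayleigh and
#' Watson-Williams tests act on those per-subject means (so two models
#' with n subjects each give df = (1, 2n - 2)), and the within-subject
#' angular deviation is each subject's AD across their own trials,
#' averaged. Model likelihoods use a per-model von Mises noise fit over
#' all trial errors, with n = the number of measurements.
#'
#' @param maze a [maze_spec()] (possibly two-variant) or path to a maze
#'   JSON file.
#' @param variant maze variant to analyze.
#' @param design a [study_design()].
#' @param estimates an `estimate_table`, or `NULL` to generate synthetic
#'   estimates from `generative_model`'s predictions.
#' @param generative_model model whose predictions seed the synthetic
#'   estimates (`"embedded"`, `"nonmetric"` or `"ground_truth"`).
#' @param kappa_within,kappa_between,data_seed synthetic-noise parameters,
#'   see [generate_estimates()].
#' @param models models to score (subset of `"nonmetric"`, `"embedded"`).
#' @param embed_restarts,embed_seed,lambda1,lambda2 embedding
#'   configuration, see [embed_graph()].
#' @param minimum which local minimum the embedded model uses (1 = lowest
#'   stress). Every distinct minimum's stress is reported regardless.
#' @param frame `"local"` (default) or `"global"` error frame.
#' @param angle_convention label-counting convention for the non-metric
#'   model's parameters, see [count_parameters()].
#' @param alpha two-tailed test level (recorded in the report).
#' @param out_dir optional directory; when given, all artifacts (maze,
#'   graph, embedding, predictions, estimates, report, log) are written
#'   there.
#' @return An object of class `comparison_report`; see
#'   [print.comparison_report()], [residuals.comparison_report()].
#' @export
run_analysis <- function(maze, variant = c("wormhole", "control"),
                         design = study_design("rips_folds"),
                         estimates = NULL, generative_model = "embedded",
                         kappa_within = 4, kappa_between = Inf,
                         data_seed = 1,
                         models = c("nonmetric", "embedded"),
                         embed_restarts = 100, embed_seed = 1,
                         lambda1 = 1, lambda2 = 1, minimum = 1,
                         frame = c("local", "global"),
                         angle_convention = "ordered", alpha = 0.05,
                         out_dir = NULL) {
  variant <- match.arg(variant)
  frame <- match.arg(frame)
  models <- match.arg(models, c("nonmetric", "embedded"), several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(maze)) maze <- stage("maze", read_maze_json(maze))
  stage("maze", validate_maze(maze))
  m <- maze_variant(maze, variant)
  say("maze: %d corners, %d wormholes (%s variant)",
      nrow(m$corners), length(m$wormholes), variant)

  graph <- stage("graph", build_graph(maze, variant))
  say("graph: %d vertices, %d edges, %d triplets",
      length(graph$vertices), nrow(graph$edges), nrow(graph$triplets))

  fit <- stage("embed",
    embed_graph(graph, n_restarts = embed_restarts, seed = embed_seed,
                lambda1 = lambda1, lambda2 = lambda2))
  for (i in seq_along(fit$minima))
    say("embedding minimum %d: stress %.6g (%d restarts)", i,
        fit$minima[[i]]$stress, fit$minima[[i]]$count)
  say("embedded model uses minimum %d (stress %.6g); embed seed %d",
      minimum, fit$minima[[minimum]]$stress, embed_seed)

  pred_models <- union(models, "ground_truth")
  preds <- stage("predict",
    shortcut_predictions(graph, m, design$pairs,
                         X = coef(fit, minimum = minimum),
                         models = pred_models))

  if (is.null(estimates)) {
    gen <- preds[preds$model == generative_model, , drop = FALSE]
    if (!nrow(gen)) stop("[data] no predictions for generative model '",
                         generative_model, "'")
    estimates <- stage("data",
      generate_estimates(gen, design, kappa_within = kappa_within,
                         seed = data_seed, kappa_between = kappa_between))
    say("synthetic estimates: model %s, kappa_within %g, seed %d",
        generative_model, kappa_within, data_seed)
  } else {
    generative_model <- attr(estimates, "generative_model") %||% "supplied"
    say("estimates supplied: %d rows", nrow(estimates))
  }
  if (nrow(estimates) != design$n_measurements)
    stop("[data] estimate table has ", nrow(estimates),
         " rows but the design expects ", design$n_measurements)

  errors <- stage("score", score_errors(preds, estimates, models, frame))
  model_stats <- list()
  for (mod in models) {
    e <- errors[errors$model == mod, , drop = FALSE]
    sm <- subject_means(e)
    btw <- circ_summary(sm$mean_error)
    within <- vapply(split(e$error, e$subject),
                     function(z) circ_summary(z)$ad, 0)
    vm <- fit_von_mises(e$error)
    k <- count_parameters(mod, graph, angle_convention = angle_convention)
    ll <- vm_loglik(e$error, vm$mu, vm$kappa)
    model_stats[[mod]] <- list(
      model = mod,
      mean_error = btw$mu, between_ad = btw$ad,
      within_ad_mean = mean(within),
      rayleigh = rayleigh_test(sm$mean_error),
      vm = vm,
      score = bic_score(k, nrow(e), ll),
      subject_means = sm)
    say("%s: mean error %.2f deg, between AD %.2f, within AD %.2f, BIC %.2f",
        mod, btw$mu, btw$ad, mean(within), model_stats[[mod]]$score$bic)
  }

  tests <- NULL
  if (length(models) >= 2) {
    cmb <- utils::combn(models, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      m1 <- cmb[1, i]; m2 <- cmb[2, i]
      g1 <- model_stats[[m1]]$subject_means$mean_error
      g2 <- model_stats[[m2]]$subject_means$mean_error
      ww <- watson_williams(list(g1, g2))
      data.frame(model1 = m1, model2 = m2, F = ww$statistic,
                 df1 = ww$df[1], df2 = ww$df[2], p = ww$p_value,
                 d = cohens_d_circular(g1, g2))
    }))
  }

  report <- structure(
    list(models = model_stats, tests = tests,
         embedding = list(
           stress = vapply(fit$minima, `[[`, 0, "stress"),
           counts = vapply(fit$minima, `[[`, 0L, "count"),
           selected = minimum,
           n_restarts = embed_restarts),
         errors = errors, predictions = preds, estimates = estimates,
         design = design, frame = frame, alpha = alpha,
         generative_model = generative_model,
         provenance = list(variant = variant, embed_seed = embed_seed,
                           data_seed = data_seed,
                           kappa_within = kappa_within,
                           kappa_between = kappa_between,
                           angle_convention = angle_convention),
         log = log_lines, fit = fit, maze = m, graph = graph),
    class = "comparison_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_maze_json(maze, file.path(out_dir, "maze.json"))
    write_graph_json(graph, file.path(out_dir, "graph.json"))
    write_embedding_csv(fit, file.path(out_dir, "embedding.csv"),
                        minimum = minimum)
    write_predictions_csv(preds, file.path(out_dir, "predictions.csv"))
    write_estimates_csv(estimates, file.path(out_dir, "estimates.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-trial prediction errors in the requested frame
score_errors <- function(preds, estimates, models, frame) {
  out <- list()
  for (mod in models) {
    p <- preds[preds$model == mod, , drop = FALSE]
    pk <- paste(p$start, p$goal)
    i <- match(paste(estimates$start, estimates$goal), pk)
    if (anyNA(i))
      stop("no ", mod, " prediction for pair ",
           paste(estimates$start[is.na(i)][1], estimates$goal[is.na(i)][1]))
    err <- if (frame == "local") {
      est_local <- to_local_reference(estimates$estimate_deg,
                                      p$start_arm_gt[i])
      wrap180(est_local - p$direction_local[i])
    } else {
      wrap180(estimates$estimate_deg - p$direction_global[i])
    }
    out[[mod]] <- data.frame(model = mod,
                             subject = estimates$subject,
                             start = estimates$start,
                             goal = estimates$goal,
                             estimate_deg = estimates$estimate_deg,
                             error = err)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

subject_means <- function(e) {
  sp <- split(e$error, e$subject)
  data.frame(subject = names(sp),
             mean_error = vapply(sp, circ_mean, 0),
             n = vapply(sp, length, 0L))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Cognitive-map model comparison  (%s design, %d measurements, %s frame)\n",
              x$design$tag, nrow(x$estimates), x$frame))
  cat(sprintf("Embedding: %d distinct local minim%s, stress %s; scoring minimum %d\n",
              length(x$embedding$stress),
              if (length(x$embedding$stress) == 1) "um" else "a",
              paste(sprintf("%.4g", x$embedding$stress), collapse = " / "),
              x$embedding$selected))
  tab <- do.call(rbind, lapply(x$models, function(s)
    data.frame(model = s$model,
               mean_error = round(s$mean_error, 2),
               between_AD = round(s$between_ad, 2),
               within_AD = round(s$within_ad_mean, 2),
               rayleigh_z = round(s$rayleigh$statistic, 2),
               rayleigh_p = signif(s$rayleigh$p_value, 3),
               k = s$score$k,
               BIC = round(s$score$bic, 2))))
  rownames(tab) <- NULL
  print(tab)
  if (!is.null(x$tests)) {
    cat("Pairwise Watson-Williams:\n")
    tt <- x$tests
    tt$F <- round(tt$F, 3); tt$p <- signif(tt$p, 3); tt$d <- round(tt$d, 3)
    print(tt)
  }
  invisible(x)
}

#' @export
summary.comparison_report <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Trial-level prediction errors of a fitted comparison
#'
#' @param object a `comparison_report`.
#' @param ... ignored.
#' @return Data frame with one row per model and measurement: `model`,
#'   `subject`, `start`, `goal`, `estimate_deg`, `error` (degrees, in the
#'   report's frame).
#' @export
residuals.comparison_report <- function(object, ...) object$errors

#' Write a comparison report as JSON (plus a per-model CSV)
#'
#' @param report a `comparison_report`.
#' @param path JSON output path; a sibling `<path>.csv` holds the
#'   per-model summary table.
#' @export
write_report_json <- function(report, path) {
  per_model <- lapply(report$models, function(s)
    list(mean_error = s$mean_error, between_ad = s$between_ad,
         within_ad_mean = s$within_ad_mean,
         rayleigh_z = s$rayleigh$statistic,
         rayleigh_p = s$rayleigh$p_value,
         vm_mu = s$vm$mu, vm_kappa = s$vm$kappa,
         k = s$score$k, n = s$score$n, loglik = s$score$loglik,
         bic = s$score$bic))
  doc <- list(design = report$design$tag,
              n_measurements = nrow(report$estimates),
              frame = report$frame, alpha = report$alpha,
              models = per_model, tests = report$tests,
              embedding = report$embedding[c("stress", "counts",
                                             "selected", "n_restarts")],
              provenance = report$provenance)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  tab <- do.call(rbind, lapply(report$models, function(s)
    data.frame(model = s$model, mean_error = s$mean_error,
               between_ad = s$between_ad,
               within_ad_mean = s$within_ad_mean,
               rayleigh_z = s$rayleigh$statistic,
               rayleigh_p = s$rayleigh$p_value,
               k = s$score$k, bic = s$score$bic)))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Write or read embedding coordinates as CSV
#'
#' Coordinates as `vertex_id,x,y` with a JSON sidecar (`<path>.json`)
#' recording stress, seed, restart index and convergence.
#'
#' @param fit a `cogmap_embedding` (or bare coordinate matrix).
#' @param path CSV path.
#' @param minimum which local minimum to write.
#' @export
write_embedding_csv <- function(fit, path, minimum = 1) {
  if (inherits(fit, "cogmap_embedding")) {
    m <- fit$minima[[minimum]]
    X <- m$X
    meta <- list(stress = m$stress, seed = fit$seed, restart = m$restart,
                 converged = m$converged, grad_norm = m$grad_norm)
  } else {
    X <- as.matrix(fit)
    meta <- NULL
  }
  df <- data.frame(vertex_id = rownames(X), x = X[, 1], y = X[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  X <- as.matrix(df[, c("x", "y")])
  rownames(X) <- df$vertex_id
  X
}

#' Load a deposited directional-estimate table
#'
#' Column-map-driven adapter for externally deposited estimate files. The
#' caller names the columns holding subject, start object, goal object and
#' angle, and states whether angles are global directions or differences
#' relative to the ground-truth straight-line direction (in which case the
#' maze converts them to global).
#'
#' @param path delimited text file (comma-separated by default).
#' @param column_map named list or vector with entries `subject`, `start`,
#'   `goal`, `angle` giving the corresponding column names in the file.
#' @param angles `"global"` or `"ground_truth_relative"`.
#' @param maze required for `"ground_truth_relative"`: the concrete
#'   [maze_spec()] whose object positions define the straight-line
#'   directions.
#' @param sep field separator.
#' @return An `estimate_table` with global `estimate_deg` in [0, 360).
#' @export
load_deposited_estimates <- function(path, column_map,
                                     angles = c("global",
                                                "ground_truth_relative"),
                                     maze = NULL, sep = ",") {
  angles <- match.arg(angles)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "start", "goal", "angle")
  miss <- setdiff(need, names(column_map))
  if (length(miss))
    stop("column_map is missing entries: ", paste(miss, collapse = ", "))
  for (f in need) {
    if (!column_map[[f]] %in% names(df))
      stop("column '", column_map[[f]], "' (", f, ") not found; ",
           "available headers: ", paste(names(df), collapse = ", "))
  }
  out <- data.frame(subject = as.character(df[[column_map$subject]]),
                    start = as.character(df[[column_map$start]]),
                    goal = as.character(df[[column_map$goal]]),
                    estimate_deg = as.numeric(df[[column_map$angle]]))
  if (angles == "ground_truth_relative") {
    if (is.null(maze))
      stop("ground-truth-relative angles need the maze")
    gt <- mapply(function(s, g) {
      ps <- object_position(maze, s); pg <- object_position(maze, g)
      vec_dir(pg[1] - ps[1], pg[2] - ps[2])
    }, out$start, out$goal)
    out$estimate_deg <- wrap360(gt + out$estimate_deg)
  } else {
    out$estimate_deg <- wrap360(out$estimate_deg)
  }
  class(out) <- c("estimate_table", "data.frame")
  out
}
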