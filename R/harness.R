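#' Experiment configuration
#'
#' Bundles the split, classifier choice and bookkeeping hyperparameters. The
#' learning-rate grid and step count are recorded for parity with deep
#' fine-tuning protocols but are inert for the built-in logistic baseline.
#'
#' @param split_fraction held-out fraction when a split must be drawn;
#'   default 0.2.
#' @param learning_rate one of 0.1, 0.01, 0.001 (recorded).
#' @param steps training steps (recorded); default 2000.
#' @param threshold probability threshold for the confusion matrix.
#' @param seed integer seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(split_fraction = 0.2, learning_rate = 0.1,
                              steps = 2000, threshold = 0.5, seed = 1) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            learning_rate %in% c(0.1, 0.01, 0.001))
  structure(list(split_fraction = split_fraction,
                 learning_rate = learning_rate, steps = steps,
                 threshold = threshold, seed = as.integer(seed)),
            class = "experiment_config")
}

# intensity-summary features of a crop: resolution-agnostic and deterministic
.crop_features <- function(img) {
  v <- if (length(dim(img)) == 3) img[, , 1] else img
  n <- nrow(v)
  ctr <- v[round(n * 0.3):round(n * 0.7), round(n * 0.3):round(n * 0.7)]
  ring <- mean(v) * length(v) - sum(ctr)
  ring <- ring / (length(v) - length(ctr))
  c(mean = mean(v), sd = stats::sd(as.numeric(v)),
    q = stats::quantile(v, c(.1, .25, .5, .75, .9), names = FALSE),
    center_excess = mean(ctr) - ring,
    grad = mean(abs(diff(v))))
}

#' Train the baseline crop classifier
#'
#' A deterministic stand-in for the deep transfer-learning path: intensity
#' summary features (moments, quantiles, centre-vs-periphery excess,
#' gradient energy) feeding a logistic regression. Reproducible given the
#' config seed; the same interface accepts any drop-in model exposing a
#' score method via [predict_baseline()].
#'
#' @param crops list of intensity arrays.
#' @param labels logical vector (`TRUE` = nodular).
#' @param config an [experiment_config()].
#' @return object of class `baseline_classifier` (fitted model + scaling).
#' @export
train_baseline <- function(crops, labels, config = experiment_config()) {
  stopifnot(length(crops) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes")
  if (min(table(labels)) < 2)
    stop("need at least 2 examples per class")
  X <- t(vapply(crops, .crop_features, numeric(9)))
  mu <- colMeans(X); sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- scale(X, mu, sdev)
  df <- data.frame(y = labels, Xs)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  log_line("train", sprintf(
    "n=%d pos=%d lr=%g steps=%d seed=%d deviance=%.4f",
    length(labels), sum(labels), config$learning_rate, config$steps,
    config$seed, fit$deviance))
  structure(list(fit = fit, mu = mu, sd = sdev, config = config),
            class = "baseline_classifier")
}

#' @rdname train_baseline
#' @param model a `baseline_classifier`.
#' @return `predict_baseline` returns scores in \[0, 1\].
#' @export
predict_baseline <- function(model, crops) {
  stopifnot(inherits(model, "baseline_classifier"))
  X <- t(vapply(crops, .crop_features, numeric(9)))
  Xs <- scale(X, model$mu, model$sd)
  as.numeric(suppressWarnings(
    stats::predict(model$fit, newdata = data.frame(Xs), type = "response")))
}

# one structured line per pipeline stage
log_line <- function(stage, msg, file = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  else message(line)
  invisible(line)
}

#' Run the end-to-end screening experiment
#'
#' Orchestrates synthetic generation, candidate detection, crop extraction,
#' class-specific augmentation, baseline training and evaluation, writing a
#' deterministic results layout (`regions.json`, `metrics.json`, `log.txt`)
#' under `out_dir`.
#'
#' @param config list (or JSON/YAML file path) with optional elements
#'   `n_patients`, `nodular_fraction`, `synth` (overrides for
#'   [synth_config()]), `l`, `selem_radius`, `experiment` (overrides for
#'   [experiment_config()]), `seed`.
#' @param out_dir results directory (created).
#' @return list with `regions_per_patient`, `metrics` (NULL when no nodular
#'   candidates exist, e.g. fully symmetric data) and the paths written.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  seed <- config$seed %||% 1
  n_pat <- config$n_patients %||% 6
  frac <- config$nodular_fraction %||% 0.5
  synth_args <- config$synth %||% list()
  # benign vascular streaks populate the non-nodular candidate class
  if (is.null(synth_args$benign_spots)) synth_args$benign_spots <- 2
  scf <- do.call(synth_config, synth_args)
  l <- config$l %||% 0.3
  selem <- config$selem_radius %||% 3
  ecf <- do.call(experiment_config,
                 c(config$experiment %||% list(), list(seed = seed)))

  log_line("config", sprintf("n_patients=%d l=%g selem=%d seed=%d",
                             n_pat, l, selem, seed), logf)
  n_nod <- round(n_pat * frac)
  all_regions <- list()
  crops <- list(); labels <- logical()
  for (i in seq_len(n_pat)) {
    cf <- scf
    cf$seed <- .derive_seed(seed, i)
    cf$delta_t <- if (i <= n_nod) scf$delta_t else 0
    sy <- synth_thermogram(cf)
    det <- detect_candidates(sy$tg, sy$roi_mask, l = l,
                             selem_radius = selem)
    lab <- vapply(det$regions, function(r) {
      if (!length(sy$regions)) return(FALSE)
      max(vapply(sy$regions, function(tr) mask_iou(r$mask, tr$mask), 0)) > 0.3
    }, logical(1))
    for (j in seq_along(det$regions)) {
      det$regions[[j]]$label <- if (lab[j]) "nodular" else "non_nodular"
      crops[[length(crops) + 1]] <-
        crop_resize_normalize(det$roi, det$regions[[j]], size = 64)
      labels <- c(labels, lab[j])
    }
    all_regions[[i]] <- det$regions
    log_line("detect", sprintf("patient=%d regions=%d nodular=%d",
                               i, length(det$regions), sum(lab)), logf)
  }
  write_regions(do.call(c, all_regions) %||% list(),
                file.path(out_dir, "regions.json"))

  metrics <- NULL
  if (length(crops) >= 6 && length(unique(labels)) == 2 &&
      min(table(labels)) >= 3) {
    idx <- seq_along(crops)
    # deterministic stratified split
    pos <- idx[labels]; neg <- idx[!labels]
    te <- c(pos[seq_len(max(1, floor(length(pos) * ecf$split_fraction)))],
            neg[seq_len(max(1, floor(length(neg) * ecf$split_fraction)))])
    tr <- setdiff(idx, te)
    aug_n <- augment(crops[tr][labels[tr]], augmentation_plan("nodular"))
    aug_b <- augment(crops[tr][!labels[tr]],
                     augmentation_plan("non_nodular"))
    model <- train_baseline(c(aug_n, aug_b),
                            rep(c(TRUE, FALSE),
                                c(length(aug_n), length(aug_b))), ecf)
    m <- evaluate(predict_baseline(model, crops[te]), labels[te],
                  ecf$threshold)
    write_metrics(m, file.path(out_dir, "metrics.json"))
    metrics <- m
    log_line("eval", sprintf("test_n=%d acc=%.3f", m$n, m$accuracy), logf)
  } else {
    log_line("eval", "skipped: not enough labelled candidates", logf)
  }
  list(regions_per_patient = all_regions, metrics = metrics,
       out_dir = out_dir)
}
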