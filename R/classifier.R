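# ---- pluggable per-event classifier ----------------------------------------
# A classifier plug-in is a list with two functions:
#   fit(x, y, n_classes, seed) -> handle
#   predict(handle, x) -> integer labels in 1..n_classes
# The reference implementation below is multinomial logistic regression
# (nnet, single-layer softmax network with skip connections only), chosen to
# be deterministic under a fixed seed and fast on one CPU. Heavier sequence
# models (e.g. convolutional/recurrent networks) can be plugged in behind the
# same contract.

#' Reference classifier: multinomial logistic regression
#'
#' Returns the default classifier plug-in used by [stigmar()]. Features are
#' rescaled column-wise by their maximum absolute training value; training is
#' deterministic given `seed`. A degenerate single-class training set yields
#' a constant predictor with a warning.
#'
#' @param maxit maximum optimizer iterations.
#' @param decay L2 weight decay (regularization) of the softmax weights.
#' @return list with `fit` and `predict` functions (the plug-in contract).
#' @export
reference_classifier <- function(maxit = 150, decay = 1e-4) {
  list(
    fit = function(x, y, n_classes, seed = 1) {
      if (!nrow(x)) stopf("classifier fit: empty training set")
      if (nrow(x) != length(y)) stopf("classifier fit: feature/label length mismatch")
      classes <- sort(unique(y))
      if (length(classes) == 1L) {
        warnf("classifier fit: single-class training set; constant predictor")
        return(structure(list(kind = "constant", level = classes,
                              p = ncol(x)), class = "stigmar_clf"))
      }
      scale <- apply(abs(x), 2, max)
      scale[scale == 0] <- 1
      xs <- sweep(x, 2, scale, "/")
      yi <- nnet::class.ind(factor(y, levels = classes))
      net <- with_seed(seed,
        nnet::nnet(xs, yi, size = 0, skip = TRUE, softmax = TRUE,
                   maxit = maxit, decay = decay, trace = FALSE,
                   MaxNWts = 1e6))
      structure(list(kind = "multinom", net = net, scale = scale,
                     classes = classes, p = ncol(x)), class = "stigmar_clf")
    },
    predict = function(handle, x) {
      if (ncol(x) != handle$p)
        stopf("classifier predict: feature dimension %d does not match training dimension %d",
              ncol(x), handle$p)
      if (handle$kind == "constant") return(rep(handle$level, nrow(x)))
      xs <- sweep(x, 2, handle$scale, "/")
      pr <- stats::predict(handle$net, xs)
      handle$classes[max.col(pr, ties.method = "first")]
    }
  )
}

resolve_maps <- function(stream, area_map, activity_area) {
  S <- length(sensor_catalog(stream))
  if (is.null(area_map)) area_map <- rep(1L, S) # one-zone home: spans pool globally
  list(area_map = as.integer(area_map), activity_area = activity_area)
}

# ---- the fitted recognizer --------------------------------------------------

#' Fit an online activity recognizer on a labeled sensor-event stream
#'
#' The full training pipeline of the method, in one call. The offline phase
#' fits the correlation model (SCM, SCT, MTI, MTS) on the training stream;
#' each event is then given its context window by the chosen segmentation
#' method, the window is converted to a stigmergic directed weighted network
#' (or the activation-duration baseline vector), and the per-event classifier
#' is trained on the flattened features against the events' activity labels.
#' `predict()` on new streaming data repeats segmentation and featurization
#' with the frozen offline model.
#'
#' @param stream a labeled [event_stream()]; [assign_labels()] is applied
#'   when the `label` column is absent.
#' @param segmentation `"dynamic"` (spatio-temporal windows), `"fixed"`
#'   (event count) or `"time"` (fixed interval).
#' @param feature `"dwn"` (stigmergic network) or `"fv"` (duration vector).
#' @param rho volatilization rate per time step for the stigmergic features,
#'   in `[0, 1)`; `rho = 0` disables decay.
#' @param time_step seconds per decay tick.
#' @param ws window size in events (fixed segmentation) .
#' @param dt window length in seconds (time segmentation).
#' @param scm_window sliding-window length (events) of the SCM.
#' @param key_sensor,sct_rank correlation-threshold mode, see [derive_sct()].
#' @param area_map integer vector mapping each sensor to its functional area;
#'   defaults to a single area (all spans pooled), appropriate only for
#'   small homes.
#' @param activity_area named integer vector mapping activity names to areas
#'   (partial maps completed by the majority rule, see [compute_mts()]).
#' @param n_areas number of functional areas.
#' @param max_lookback cap on dynamic window size (events).
#' @param sd_type standard-deviation form for the 2-sigma thresholds.
#' @param classifier a classifier plug-in (see [reference_classifier()]).
#' @param seed integer seed controlling classifier initialization.
#' @param ranges internal: restrict the offline phase and training targets to
#'   these index ranges (used by [cross_validate()]).
#' @return object of class `stigmar` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
stigmar <- function(stream,
                    segmentation = c("dynamic", "fixed", "time"),
                    feature = c("dwn", "fv"),
                    rho = 0.1, time_step = 1, ws = 20, dt = 60,
                    scm_window = 15, key_sensor = NULL, sct_rank = 1,
                    area_map = NULL, activity_area = NULL,
                    n_areas = NULL, max_lookback = 200L,
                    sd_type = "population",
                    classifier = reference_classifier(),
                    seed = 1, ranges = NULL) {
  segmentation <- match.arg(segmentation)
  feature <- match.arg(feature)
  if (all(is.na(stream$label))) stream <- assign_labels(stream)
  maps <- resolve_maps(stream, area_map, activity_area)
  n_areas <- n_areas %||% max(maps$area_map)

  model <- NULL
  if (segmentation == "dynamic")
    model <- fit_correlation_model(stream, area_map = maps$area_map,
                                   activity_area = maps$activity_area,
                                   n_areas = n_areas, ws = scm_window,
                                   key_sensor = key_sensor, sct_rank = sct_rank,
                                   ranges = ranges, sd_type = sd_type)

  targets <- if (is.null(ranges)) seq_len(nrow(stream))
             else sort(unlist(lapply(ranges, function(r) r[1]:r[2])))
  win <- segment_stream(stream, method = segmentation, model = model,
                        ws = ws, dt = dt, targets = targets,
                        max_lookback = max_lookback)
  if (!is.null(ranges)) {
    # drop training targets whose window reaches outside the training blocks
    ok <- vapply(seq_len(nrow(win)), function(k)
      any(vapply(ranges, function(r) win$first[k] >= r[1] && win$target[k] <= r[2],
                 logical(1))), logical(1))
    win <- win[ok, , drop = FALSE]
  }
  fx <- featurize_stream(stream, win, feature = feature, rho = rho,
                         time_step = time_step)
  acat <- activity_catalog(stream)
  n_classes <- max(length(acat), fx$labels)
  handle <- classifier$fit(fx$features, fx$labels, n_classes, seed = seed)
  train_pred <- classifier$predict(handle, fx$features)

  structure(list(
    correlation = model,
    classifier = handle,
    plugin = classifier,
    config = list(segmentation = segmentation, feature = feature, rho = rho,
                  time_step = time_step, ws = ws, dt = dt,
                  scm_window = scm_window, sct_rank = sct_rank,
                  key_sensor = key_sensor, max_lookback = max_lookback,
                  sd_type = sd_type, seed = seed),
    area_map = maps$area_map,
    activity_area = maps$activity_area,
    n_areas = n_areas,
    sensor_catalog = sensor_catalog(stream),
    activity_catalog = acat,
    n_classes = n_classes,
    training = list(n = nrow(win),
                    class_counts = table(factor(fx$labels, seq_len(n_classes))),
                    accuracy = mean(train_pred == fx$labels))),
    class = "stigmar")
}

#' Predict activity labels for streaming events
#'
#' Segments and featurizes `newdata` with the frozen offline model of the fit
#' and classifies every target event (or the subset in `targets`).
#'
#' @param object a fitted [stigmar()] model.
#' @param newdata an [event_stream()] sharing the training sensor catalog.
#' @param targets event positions to classify (default: all).
#' @param ... unused.
#' @return integer vector of predicted activity indices (1..A).
#' @export
predict.stigmar <- function(object, newdata, targets = seq_len(nrow(newdata)), ...) {
  cfg <- object$config
  win <- segment_stream(newdata, method = cfg$segmentation,
                        model = object$correlation, ws = cfg$ws, dt = cfg$dt,
                        targets = targets, max_lookback = cfg$max_lookback)
  fx <- featurize_stream(newdata, win, feature = cfg$feature, rho = cfg$rho,
                         time_step = cfg$time_step)
  object$plugin$predict(object$classifier, fx$features)
}

#' @export
print.stigmar <- function(x, ...) {
  cat(sprintf("<stigmar> %s segmentation + %s features%s\n",
              x$config$segmentation, toupper(x$config$feature),
              if (x$config$feature == "dwn")
                sprintf(" (rho = %g)", x$config$rho) else ""))
  cat(sprintf("  %d sensors, %d areas, %d activity classes; trained on %d windows\n",
              length(x$sensor_catalog), x$n_areas, x$n_classes, x$training$n))
  invisible(x)
}

#' @export
summary.stigmar <- function(object, ...) {
  print(object)
  cat(sprintf("  resubstitution accuracy: %.4f\n", object$training$accuracy))
  if (!is.null(object$correlation)) {
    cat("  offline model: ")
    print(object$correlation)
  }
  cc <- object$training$class_counts
  nm <- names(object$activity_catalog)[match(seq_along(cc), object$activity_catalog)]
  cat("  training windows per class:\n")
  for (j in seq_along(cc)) if (cc[j] > 0)
    cat(sprintf("    %-20s %d\n", nm[j] %||% as.character(j), cc[j]))
  invisible(object)
}

#' @export
coef.stigmar <- function(object, ...) {
  if (object$classifier$kind != "multinom") return(NULL)
  object$classifier$net$wts
}

#' Plot method: sensor correlation matrix of the fitted offline model
#'
#' @param x a fitted `stigmar` object (dynamic segmentation).
#' @param ... passed to [graphics::image()].
#' @export
plot.stigmar <- function(x, ...) {
  if (is.null(x$correlation))
    stopf("plot.stigmar: no correlation model (non-dynamic segmentation)")
  m <- x$correlation$scm
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "sensor", ylab = "sensor",
                  main = "Sensor correlation matrix (windowed MI)", ...)
  invisible(x)
}

# ---- cross-validation -------------------------------------------------------

#' Contiguous-block cross-validation of the full pipeline
#'
#' Splits the stream into `folds` contiguous time blocks. For each fold the
#' offline correlation model and the classifier are fitted on the training
#' blocks only (windows crossing into the held-out block are dropped from
#' training); every event of the held-out block is then segmented,
#' featurized and classified online, with past events -- whichever fold they
#' belong to -- available as window context, as in deployment. Contiguous
#' blocks rather than shuffled folds prevent temporal leakage.
#'
#' @inheritParams stigmar
#' @param folds number of contiguous blocks (>= 2).
#' @param ... passed on to [stigmar()].
#' @return list of class `stigmar_cv`: `per_fold` (list of
#'   [weighted_metrics()] reports), `pooled` (one report over all held-out
#'   predictions), `folds` (block boundaries), `accuracy` (pooled accuracy).
#' @export
cross_validate <- function(stream, folds = 5, seed = 1, ...) {
  n <- nrow(stream)
  if (n < folds) stopf("cross_validate: stream shorter than the number of folds")
  if (all(is.na(stream$label))) stream <- assign_labels(stream)
  bounds <- floor(seq(0, n, length.out = folds + 1))
  acat <- activity_catalog(stream)
  A <- max(length(acat), stream$label)
  per_fold <- vector("list", folds)
  truth_all <- integer(0); pred_all <- integer(0)
  fold_tab <- data.frame(fold = seq_len(folds),
                         start = bounds[-length(bounds)] + 1L,
                         end = bounds[-1])
  for (f in seq_len(folds)) {
    te <- c(fold_tab$start[f], fold_tab$end[f])
    tr <- list()
    if (te[1] > 1L) tr <- c(tr, list(c(1L, te[1] - 1L)))
    if (te[2] < n) tr <- c(tr, list(c(te[2] + 1L, n)))
    fit <- stigmar(stream, seed = seed + f, ranges = tr, ...)
    truth <- stream$label[te[1]:te[2]]
    pred <- predict(fit, stream, targets = te[1]:te[2])
    per_fold[[f]] <- evaluate_labels(truth, pred, A)
    truth_all <- c(truth_all, truth); pred_all <- c(pred_all, pred)
  }
  pooled <- evaluate_labels(truth_all, pred_all, A)
  structure(list(per_fold = per_fold, pooled = pooled, folds = fold_tab,
                 accuracy = pooled$accuracy),
            class = "stigmar_cv")
}

#' @export
print.stigmar_cv <- function(x, ...) {
  cat(sprintf("<stigmar_cv> %d contiguous folds\n", nrow(x$folds)))
  for (f in seq_along(x$per_fold))
    cat(sprintf("  fold %d: accuracy %.4f, F1 %.4f\n", f,
                x$per_fold[[f]]$accuracy, x$per_fold[[f]]$f1))
  cat(sprintf("  pooled: accuracy %.4f, F1 %.4f\n", x$pooled$accuracy, x$pooled$f1))
  invisible(x)
}
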