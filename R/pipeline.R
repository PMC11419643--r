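# The strokerisk model: one fitting function over the staged pipeline -------
#
# Stage order: impute (HKGA) -> aggregate -> standardize -> ICA reduce ->
# T-test/Spearman filter -> UD-GSRBEHO wrapper selection -> fuzzy risk
# coding -> adaptive-weight Bi-LSTM -> metrics. Encryption of predictions is
# a separate, explicit step (encrypt_predictions).

#' Pipeline configuration
#'
#' Bundles one parameter block per stage. Every block must be present; a
#' missing block is a validation error naming it. One global seed derives
#' every stage seed deterministically (see [derive_seed()]).
#'
#' @param cohort a [cohort_spec()] used when no data is supplied.
#' @param hkga list: `k` (clusters, default 4), `ga` (a [ga_config()]),
#'   `mode` (`"impute"` or `"drop"`).
#' @param ica list: `n_components` (default: numerical rank), `threshold`
#'   (component filter, default 0.1), `max_iter`, `tol`.
#' @param selector a [gsrbeho_control()]; the pipeline default caps the
#'   wrapper at 30 iterations.
#' @param fuzzy list: `glucose_cut` (mg/dL) and optional fixed thresholds
#'   `xx`, `w`, `alpha0` (default: derived from cohort aggregates).
#' @param model a [train_config()] plus `target` (`"stroke"` or `"risk"`)
#'   and `crisp` (`"append"` or `"replace"`).
#' @param security list: `curve` (`"ss24"`, `"toy17"` or an [ec_curve()]),
#'   `kappa`, `salt_bytes`.
#' @param split training fraction for the stratified split.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            hkga = list(k = 4L, ga = ga_config(),
                                        mode = "impute"),
                            ica = list(n_components = NULL,
                                       threshold = 0.1,
                                       max_iter = 200L, tol = 1e-4),
                            selector = gsrbeho_control(iterations = 30L),
                            fuzzy = list(glucose_cut = 125),
                            model = c(train_config(),
                                      list(target = "stroke",
                                           crisp = "append")),
                            security = list(curve = "ss24", kappa = 64L,
                                            salt_bytes = 16L),
                            split = 0.8,
                            seed = 1L) {
  cfg <- structure(list(cohort = cohort, hkga = hkga, ica = ica,
                        selector = selector, fuzzy = fuzzy, model = model,
                        security = security, split = split,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  needed <- c("cohort", "hkga", "ica", "selector", "fuzzy", "model",
              "security", "split", "seed")
  for (blk in needed)
    if (is.null(cfg[[blk]]))
      stop_arg("pipeline config: missing stage block '%s'", blk)
  if (!inherits(cfg$cohort, "cohort_spec"))
    stop_arg("pipeline config: 'cohort' must be a cohort_spec")
  if (cfg$split <= 0 || cfg$split >= 1)
    stop_arg("pipeline config: split must be in (0, 1)")
  if (!cfg$model$target %in% c("stroke", "risk"))
    stop_arg("pipeline config: model$target must be 'stroke' or 'risk'")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Stage blocks mirror the [pipeline_config()] arguments; unknown keys are
#' rejected, absent blocks keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$hkga)) {
    hk <- list(k = y$hkga$k %||% 4L, mode = y$hkga$mode %||% "impute")
    hk$ga <- do.call(ga_config, y$hkga$ga %||% list())
    args$hkga <- hk
  }
  if (!is.null(y$ica)) args$ica <- utils::modifyList(
    list(n_components = NULL, threshold = 0.1, max_iter = 200L,
         tol = 1e-4), y$ica)
  if (!is.null(y$selector))
    args$selector <- do.call(gsrbeho_control, y$selector)
  if (!is.null(y$fuzzy)) args$fuzzy <- y$fuzzy
  if (!is.null(y$model)) {
    tc_args <- y$model[setdiff(names(y$model), c("target", "crisp"))]
    args$model <- c(do.call(train_config, tc_args),
                    list(target = y$model$target %||% "stroke",
                         crisp = y$model$crisp %||% "append"))
  }
  if (!is.null(y$security)) args$security <- y$security
  if (!is.null(y$split)) args$split <- y$split
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipeline_config, args)
}

# stratified train/test split by label
split_cohort <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(fraction * length(idx)))
      train[sample(idx, min(n_tr, length(idx)))] <- TRUE
    }
    list(train = which(train), test = which(!train))
  })
}

resolve_curve <- function(security) {
  cv <- security$curve %||% "ss24"
  if (inherits(cv, "ec_curve")) return(cv)
  switch(cv, ss24 = ec_curve_default(), toy17 = ec_curve_toy(),
         stop_arg("unknown curve '%s'", cv))
}

# fill masked cells of new data from the nearest stored cluster center
impute_newdata <- function(table, model) {
  if (!any(table$missing_mask)) return(table)
  X <- masked_matrix(table)
  D <- partial_dist2(X, model$centers)
  nearest <- max.col(-D, ties.method = "first")
  values <- table$values
  for (i in which(rowSums(table$missing_mask) > 0)) {
    miss <- table$missing_mask[i, ]
    values[i, miss] <- model$centers[nearest[i], miss]
  }
  feature_table(values, matrix(FALSE, nrow(values), ncol(values)),
                table$attribute_names, table$codebook, table$labels,
                table$record_ids)
}

#' Fit the stroke-risk model
#'
#' Runs the full modelling chain on a cohort: HKGA cluster imputation,
#' aggregation, standardization, ICA reduction with the 0.1 mean-activation
#' filter, the pooled T-test/Spearman candidate filter, UD-GSRBEHO wrapper
#' feature selection with Rand-index fitness (on the training split),
#' trapezoidal fuzzy comorbidity risk coding, and adaptive-weight Bi-LSTM
#' training. The fitted object carries everything needed to score new
#' cohorts.
#'
#' @param data a [feature_table()], a Kaggle-dialect `data.frame`, a CSV
#'   path, or `NULL` to simulate from `config$cohort`.
#' @param config a [pipeline_config()].
#' @return an object of class `strokerisk`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_spec(n_records = 300, seed = 1),
#'                        selector = gsrbeho_control(iterations = 5,
#'                                                   seed = 1),
#'                        model = c(train_config(epochs = 3),
#'                                  list(target = "stroke",
#'                                       crisp = "append")))
#' fit <- strokerisk(config = cfg)
#' print(fit)
#' }
#' @export
strokerisk <- function(data = NULL, config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  seed <- config$seed
  table <- if (is.null(data)) {
    sp <- config$cohort
    sp$seed <- derive_seed(seed, 0L)
    generate_cohort(sp)
  } else if (inherits(data, "feature_table")) data
  else if (is.character(data)) read_cohort(data)
  else if (is.data.frame(data)) cohort_from_frame(data)
  else stop_arg("data must be a feature_table, data frame, path or NULL")
  if (is.null(table$labels))
    stop_arg("fitting requires stroke labels")

  # stage 1: HKGA imputation
  ga <- config$hkga$ga
  ga$seed <- derive_seed(seed, 1L)
  hkga <- hkga_cluster(table, config$hkga$k %||% 4L, ga)
  complete <- impute_missing(table, hkga, config$hkga$mode %||% "impute")

  # stage 2: aggregation + standardization
  aggregates <- aggregate_stats(complete)
  scale_sd <- ifelse(aggregates$sd > 0, aggregates$sd, 1)
  Xstd <- sweep(sweep(complete$values, 2, aggregates$mean), 2, scale_sd,
                "/")

  # stage 3: ICA reduction
  ica <- ica_fit(Xstd, n_components = config$ica$n_components,
                 seed = derive_seed(seed, 2L),
                 max_iter = config$ica$max_iter %||% 200L,
                 tol = config$ica$tol %||% 1e-4)
  acts <- ica_activations(ica, Xstd)
  reduced <- select_components(ica, acts,
                               threshold = config$ica$threshold %||% 0.1)
  # map each retained component to its dominant original attribute
  loadings <- ica$unmixing %*% ica$whitening
  ica_set <- unique(apply(abs(loadings[attr(reduced, "selected"), ,
                                       drop = FALSE]), 1, which.max))

  # stage 4: candidate filter + wrapper selection on the training split
  split <- split_cohort(complete$labels, config$split,
                        derive_seed(seed, 3L))
  stats <- feature_stats(complete, complete$labels, mode = "class")
  candidates <- correlation_filter(stats, ica_set,
                                   ncol(complete$values))
  sel_ctl <- config$selector
  sel_ctl$seed <- derive_seed(seed, 4L)
  selection <- select_features(Xstd[split$train, , drop = FALSE],
                               complete$labels[split$train],
                               candidates, sel_ctl)

  # stage 5: fuzzy comorbidity risk coding
  rules <- NULL
  fz <- config$fuzzy
  if (!is.null(fz$xx))
    rules <- fuzzy_rule_base(xx = fz$xx, w = fz$w,
                             alpha0 = fz$alpha0,
                             glucose_cut = fz$glucose_cut %||% 125)
  fuzzy <- fuzzy_risk_codes(complete, rules)

  # stage 6: sequence construction + Bi-LSTM training
  crisp_center <- mean(fuzzy$crisp)
  crisp_scale <- max(stats::sd(fuzzy$crisp), 1e-8)
  seq_all <- build_sequences(Xstd, selection$selected, fuzzy$crisp,
                             crisp_center, crisp_scale,
                             config$model$crisp %||% "append")
  target <- config$model$target %||% "stroke"
  if (target == "stroke") {
    classes <- c(0L, 1L)
    targets <- complete$labels + 1L
  } else {
    classes <- 1:6
    targets <- fuzzy$codes
  }
  dflt <- train_config()
  tc <- train_config(
    epochs = config$model$epochs %||% dflt$epochs,
    learning_rate = config$model$learning_rate %||% dflt$learning_rate,
    hidden_size = config$model$hidden_size %||% dflt$hidden_size,
    batch_size = config$model$batch_size %||% dflt$batch_size,
    perturbation_scale = config$model$perturbation_scale %||%
      dflt$perturbation_scale,
    huber_delta = config$model$huber_delta %||% dflt$huber_delta,
    seed = derive_seed(seed, 5L))
  params <- bilstm_init(input_size = 1L, n_classes = length(classes),
                        hidden_size = tc$hidden_size, classes = classes,
                        seed = derive_seed(seed, 6L))
  trained <- adaptive_train(seq_all[split$train, , drop = FALSE],
                            targets[split$train], params, tc)

  # stage 7: held-out evaluation
  pred <- bilstm_predict(trained$params, seq_all[split$test, ,
                                                 drop = FALSE])
  actual <- classes[targets[split$test]]
  metrics <- if (length(classes) == 2) {
    metrics_report(confusion_counts(pred$codes, actual,
                                    positive_class = 1L))
  } else {
    multiclass_metrics(pred$codes, actual, "macro")
  }

  structure(list(config = config, table = table, hkga = hkga,
                 aggregates = aggregates, scale_sd = scale_sd,
                 ica = ica, ica_set = ica_set,
                 feature_stats = stats, candidates = candidates,
                 selection = selection, fuzzy = fuzzy,
                 crisp_center = crisp_center, crisp_scale = crisp_scale,
                 split = split, params = trained$params,
                 train_trace = trained$trace, classes = classes,
                 target = target, metrics = metrics,
                 test_predictions = pred$codes, test_actual = actual,
                 test_probabilities = pred$probabilities),
            class = "strokerisk")
}

build_sequences <- function(Xstd, selected, crisp, crisp_center,
                            crisp_scale, crisp_mode) {
  S <- Xstd[, selected, drop = FALSE]
  cz <- (crisp - crisp_center) / crisp_scale
  if (identical(crisp_mode, "replace")) matrix(cz, ncol = 1)
  else cbind(S, crisp = cz)
}

#' @export
print.strokerisk <- function(x, ...) {
  cat("Stroke-risk model (HKGA + ICA + UD-GSRBEHO + fuzzy + AWBi-LSTM)\n")
  cat(sprintf("  cohort: %d records, %d predictors (%d imputed cells)\n",
              nrow(x$table$values), ncol(x$table$values),
              sum(x$table$missing_mask)))
  cat(sprintf("  selected features (%d): %s\n",
              length(x$selection$selected),
              paste(x$table$attribute_names[x$selection$selected],
                    collapse = ", ")))
  cat(sprintf("  target: %s; held-out accuracy: %.4f\n", x$target,
              x$metrics$accuracy))
  invisible(x)
}

#' @export
summary.strokerisk <- function(object, ...) {
  print(object)
  cat(sprintf("  clustering: k = %d, objective %.4g\n", object$hkga$k,
              object$hkga$sse))
  cat(sprintf("  ICA: %d/%d components retained\n",
              length(object$ica_set), object$ica$n_components))
  cat(sprintf("  wrapper fitness (Rand index): %.4f\n",
              object$selection$fitness))
  cat("  held-out metrics:\n")
  print(object$metrics)
  invisible(object)
}

#' Predict stroke-risk codes for new records
#'
#' Applies the stored imputation model, standardization, fuzzy rules and
#' feature selection, then the trained Bi-LSTM.
#'
#' @param object a fitted [strokerisk()] model.
#' @param newdata a `feature_table`, dialect `data.frame` or CSV path;
#'   defaults to the held-out test split.
#' @param type `"code"` for hard classes, `"prob"` for the probability
#'   matrix.
#' @param ... unused.
#' @export
predict.strokerisk <- function(object, newdata = NULL,
                               type = c("code", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "code") return(object$test_predictions)
    return(object$test_probabilities)
  }
  table <- if (inherits(newdata, "feature_table")) newdata
  else if (is.character(newdata)) read_cohort(newdata)
  else cohort_from_frame(newdata)
  complete <- impute_newdata(table, object$hkga)
  Xstd <- sweep(sweep(complete$values, 2, object$aggregates$mean), 2,
                object$scale_sd, "/")
  fuzzy <- fuzzy_risk_codes(complete, object$fuzzy$rules)
  seqs <- build_sequences(Xstd, object$selection$selected, fuzzy$crisp,
                          object$crisp_center, object$crisp_scale,
                          object$config$model$crisp %||% "append")
  pred <- bilstm_predict(object$params, seqs)
  if (type == "code") pred$codes else pred$probabilities
}

#' @export
coef.strokerisk <- function(object, ...) {
  list(readout = object$params$V, bias = object$params$b)
}

#' @export
residuals.strokerisk <- function(object, ...) {
  Y <- matrix(0, nrow(object$test_probabilities),
              ncol(object$test_probabilities))
  Y[cbind(seq_len(nrow(Y)),
          match(object$test_actual, object$classes))] <- 1
  object$test_probabilities - Y
}

#' @export
plot.strokerisk <- function(x, ...) {
  tr <- x$train_trace
  graphics::plot(tr$epoch, tr$mean_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean batch loss",
                 main = "Adaptive-weight Bi-LSTM training", ...)
  invisible(x)
}

#' Encrypt predicted risk records
#'
#' Serializes each prediction as `id:<record id>;code:<predicted class>`
#' and encrypts it under a fresh MD5-salted EC-ElGamal key ring.
#'
#' @param object a fitted [strokerisk()] model.
#' @param path optional JSON-lines output path (see [persist_records()]).
#' @param seed RNG seed for key generation and ephemeral scalars.
#' @return list `records` (cipher records), `keys`, `curve`, `path`.
#' @export
encrypt_predictions <- function(object, path = NULL, seed = 1L) {
  curve <- resolve_curve(object$config$security)
  keys <- generate_keys(curve, seed = derive_seed(seed, 8L),
                        salt_bytes = object$config$security$salt_bytes %||%
                          16L)
  ids <- object$table$record_ids[object$split$test]
  kappa <- object$config$security$kappa %||% 64L
  records <- with_seed(derive_seed(seed, 9L),
    lapply(seq_along(ids), function(i)
      encrypt_record(sprintf("id:%d;code:%s", ids[i],
                             format(object$test_predictions[i])),
                     keys, curve, kappa, record_id = ids[i])))
  if (!is.null(path)) persist_records(records, path)
  list(records = records, keys = keys, curve = curve, path = path)
}

#' Run the full pipeline and write per-stage artifacts
#'
#' Fits the model, evaluates it, encrypts the held-out predictions and
#' writes: the imputed cohort CSV, the selected-feature JSON, the crisp
#' fuzzy values CSV, the model parameter JSON, the metrics JSON, the
#' ciphertext store, and a manifest with seeds and per-artifact MD5
#' digests. Any stage error aborts with the stage name; the partial
#' manifest is still written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param data optional input cohort (default: simulate per config).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir(),
                         data = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("strokerisk")),
                   seed = config$seed, stages = list())
  art <- function(name) file.path(out_dir, name)
  finish <- function() {
    digests <- tools::md5sum(list.files(out_dir, full.names = TRUE))
    manifest$digests <- as.list(stats::setNames(unname(digests),
                                                basename(names(digests))))
    jsonlite::write_json(manifest, art("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  stage <- "fit"
  fit <- tryCatch(strokerisk(data, config), error = function(e) {
    manifest$stages[[stage]] <<- paste("error:", conditionMessage(e))
    finish()
    stop_arg("pipeline aborted at stage '%s': %s", stage,
             conditionMessage(e))
  })
  complete <- impute_missing(fit$table, fit$hkga,
                             config$hkga$mode %||% "impute")
  write_cohort(complete, art("imputed.csv"))
  jsonlite::write_json(
    list(selected = fit$table$attribute_names[fit$selection$selected],
         indices = fit$selection$selected,
         fitness = fit$selection$fitness),
    art("selected_features.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(id = fit$table$record_ids,
                              code = fit$fuzzy$codes,
                              crisp = fit$fuzzy$crisp),
                   art("crisp_values.csv"), row.names = FALSE)
  save_bilstm(fit$params, art("model.json"))
  jsonlite::write_json(
    list(target = fit$target,
         accuracy = fit$metrics$accuracy,
         precision = fit$metrics$precision,
         recall = fit$metrics$recall,
         specificity = fit$metrics$specificity,
         f_measure = fit$metrics$f_measure,
         npv = fit$metrics$npv, mcc = fit$metrics$mcc),
    art("metrics.json"), auto_unbox = TRUE, digits = NA)
  enc <- encrypt_predictions(fit, art("ciphertext.jsonl"),
                             seed = config$seed)
  manifest$stages <- list(fit = "ok", artifacts = "ok",
                          encrypt = "ok")
  manifest$n_records <- nrow(fit$table$values)
  manifest$accuracy <- fit$metrics$accuracy
  out <- finish()
  attr(out, "fit") <- fit
  attr(out, "encryption") <- enc
  invisible(out)
}

# Bi-LSTM JSON serialization ---------------------------------------------------

#' Save / load Bi-LSTM parameters as JSON
#'
#' Shapes, flat arrays (full double precision), class labels and the seed
#' are stored; loading restores the parameter set.
#'
#' @param params a [bilstm_params()].
#' @param path JSON path.
#' @return `path` (save) / the restored `bilstm_params` (load).
#' @export
save_bilstm <- function(params, path) {
  ser_dir <- function(d) lapply(d, function(w)
    list(dim = dim(w) %||% length(w), data = as.numeric(w)))
  obj <- list(hidden_size = params$hidden_size,
              input_size = params$input_size,
              n_classes = params$n_classes,
              classes = params$classes, seed = params$seed,
              fwd = ser_dir(params$fwd), bwd = ser_dir(params$bwd),
              V = list(dim = dim(params$V), data = as.numeric(params$V)),
              b = as.numeric(params$b))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bilstm
#' @export
load_bilstm <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  deser <- function(l) {
    if (length(l$dim) == 2) matrix(l$data, l$dim[1], l$dim[2])
    else as.numeric(l$data)
  }
  des_dir <- function(d) lapply(d, deser)
  structure(list(fwd = des_dir(obj$fwd), bwd = des_dir(obj$bwd),
                 V = deser(obj$V), b = as.numeric(obj$b),
                 hidden_size = as.integer(obj$hidden_size),
                 input_size = as.integer(obj$input_size),
                 n_classes = as.integer(obj$n_classes),
                 classes = obj$classes, seed = as.integer(obj$seed)),
            class = "bilstm_params")
}
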