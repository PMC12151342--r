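#' Experiment-level train/test splits
#'
#' Random splits that always assign whole experiments to train or test,
#' stratified by condition so both classes are present on each side.
#'
#' @param exp_ids Character vector of unique experiment ids.
#' @param conditions Condition label per experiment (same order).
#' @param n_splits Number of random splits.
#' @param train_frac Fraction of experiments (per condition) used to train.
#' @param seed Seed.
#' @return List of `n_splits` lists with `train` and `test` id vectors.
#' @export
make_experiment_splits <- function(exp_ids, conditions, n_splits = 100,
                                   train_frac = 2 / 3, seed = 1) {
  stopifnot(length(exp_ids) == length(conditions), !anyDuplicated(exp_ids))
  set.seed(seed)
  purrr::map(seq_len(n_splits), function(i) {
    train <- unlist(purrr::map(unique(conditions), function(cc) {
      ids <- exp_ids[conditions == cc]
      if (length(ids) < 2) stop("need at least 2 experiments per condition")
      n_tr <- max(1L, min(length(ids) - 1L, round(length(ids) * train_frac)))
      sample(ids, n_tr)
    }))
    list(train = train, test = setdiff(exp_ids, train))
  })
}

# ridge-logistic fit with inner CV over the penalty grid, folds by experiment
ridge_logistic_auc <- function(features, labels, exp_id, split,
                               lambda_grid, inner_folds) {
  tr <- exp_id %in% split$train
  te <- exp_id %in% split$test
  tr_exps <- unique(exp_id[tr])
  foldid <- match(exp_id[tr], sample(tr_exps)) %% inner_folds + 1L
  fit <- glmnet::cv.glmnet(
    features[tr, , drop = FALSE], labels[tr],
    family = "binomial", alpha = 0, lambda = lambda_grid,
    foldid = foldid, type.measure = "deviance"
  )
  sc <- as.numeric(stats::predict(fit,
    newx = features[te, , drop = FALSE],
    s = "lambda.min"
  ))
  lab_te <- labels[te]
  exp_te <- exp_id[te]
  exp_scores <- tapply(sc, exp_te, mean)
  exp_labels <- tapply(lab_te, exp_te, function(x) x[1])
  list(
    auc_bin = roc_auc(sc, lab_te),
    auc_experiment = if (length(unique(exp_labels)) == 2) {
      roc_auc(as.numeric(exp_scores), as.numeric(exp_labels))
    } else {
      NA_real_
    },
    lambda = fit$lambda.min
  )
}

#' Decode feedback condition from features across random splits
#'
#' For every experiment-level split, fits a ridge-penalized logistic
#' regression of the per-bin condition label (plaid vs replay) on the
#' features, with the penalty chosen by inner cross-validation whose folds
#' are also cut by experiment, then scores the held-out experiments' bins.
#' Bin-level ROC-AUC is the primary readout; an experiment-level AUC (mean
#' score per experiment) is reported alongside.
#'
#' @param features Numeric matrix, one row per time bin.
#' @param labels Binary labels per bin (1 = plaid).
#' @param exp_id Experiment id per bin.
#' @param n_splits Number of train/test splits.
#' @param train_frac Fraction of experiments used to train.
#' @param lambda_grid Ridge penalty grid.
#' @param inner_folds Inner CV folds.
#' @param seed Seed (controls the splits unless `splits` is given).
#' @param splits Optional pre-computed splits from
#'   [make_experiment_splits()], to pair decoders on identical splits.
#' @return Tibble with `split`, `auc_bin`, `auc_experiment`, `lambda`.
#' @export
train_condition_decoder <- function(features, labels, exp_id, n_splits = 100,
                                    train_frac = 2 / 3,
                                    lambda_grid = 10^seq(3, -3, length.out = 7),
                                    inner_folds = 5, seed = 1, splits = NULL) {
  stopifnot(nrow(features) == length(labels), length(labels) == length(exp_id))
  if (is.null(splits)) {
    ue <- unique(exp_id)
    cond <- labels[match(ue, exp_id)]
    splits <- make_experiment_splits(ue, cond, n_splits, train_frac, seed)
  }
  set.seed(seed + 1L)
  res <- purrr::imap(splits, function(sp, i) {
    r <- ridge_logistic_auc(features, labels, exp_id, sp, lambda_grid, inner_folds)
    tibble::tibble(
      split = i, auc_bin = r$auc_bin,
      auc_experiment = r$auc_experiment, lambda = r$lambda
    )
  })
  dplyr::bind_rows(res)
}

#' Lagged raw-input design matrix
#'
#' Concatenates the four 5 Hz input channels over a trailing integration
#' window. A window of 0 s uses only the current bin (4 features, 5 model
#' parameters with the intercept); a 10 s window at 5 Hz uses 50 lags
#' (200 features, 201 parameters).
#'
#' @param binned Tibble from [bin_experiment()].
#' @param window_s Integration window in seconds.
#' @param rate Bin rate in Hz.
#' @return List with `features` (matrix), `bin` (sample bin indices) and
#'   `n_params` (feature count + intercept).
#' @export
lagged_input_features <- function(binned, window_s, rate = 5) {
  n_lags <- max(1L, round(window_s * rate))
  n <- nrow(binned)
  if (n_lags > n) stop("window exceeds experiment duration")
  ch <- as.matrix(binned[, c("temp", "bout_start", "displacement", "turn")])
  lagged <- purrr::map(seq_len(ncol(ch)), function(j) {
    stats::embed(ch[, j], n_lags) # current bin + n_lags-1 previous
  })
  feats <- do.call(cbind, lagged)
  list(
    features = feats,
    bin = binned$bin[n_lags:n],
    n_params = ncol(feats) + 1L
  )
}

#' Decode feedback condition directly from raw inputs
#'
#' Benchmarks the neuron-based decoder against logistic classifiers that see
#' the raw inputs (temperature, swim starts, displacement, turn angle) over
#' growing integration windows.
#'
#' @param binned_list Named list of [bin_experiment()] tibbles, one per
#'   experiment.
#' @param conditions Condition per experiment (1 = plaid, 0 = replay), in
#'   the order of `binned_list`.
#' @param windows_s Integration windows in seconds.
#' @param splits Splits from [make_experiment_splits()] (shared with the
#'   neuron decoder for paired comparisons).
#' @inheritParams train_condition_decoder
#' @return Tibble with `window_s`, `n_params`, `split`, `auc_bin`,
#'   `auc_experiment`.
#' @export
input_decoder <- function(binned_list, conditions, windows_s = c(0, 10),
                          splits, lambda_grid = 10^seq(3, -3, length.out = 7),
                          inner_folds = 5, seed = 1) {
  ids <- names(binned_list)
  stopifnot(!is.null(ids), length(conditions) == length(binned_list))
  purrr::map(windows_s, function(w) {
    parts <- purrr::imap(binned_list, function(b, id) {
      lf <- lagged_input_features(b, w)
      list(
        features = lf$features,
        labels = rep(conditions[match(id, ids)], nrow(lf$features)),
        exp_id = rep(id, nrow(lf$features)),
        n_params = lf$n_params
      )
    })
    features <- do.call(rbind, purrr::map(parts, "features"))
    labels <- unlist(purrr::map(parts, "labels"))
    exp_id <- unlist(purrr::map(parts, "exp_id"))
    train_condition_decoder(
      features, labels, exp_id,
      lambda_grid = lambda_grid,
      inner_folds = inner_folds, seed = seed, splits = splits
    ) |>
      dplyr::mutate(
        window_s = w,
        n_params = parts[[1]]$n_params, .before = 1
      )
  }) |>
    dplyr::bind_rows()
}

#' Summarize neuron decoder against input decoders
#'
#' Joins per-split AUCs of the neuron-activity decoder and the raw-input
#' decoders (same splits), reporting medians, the fraction of splits in
#' which the neuron decoder wins, and a percentile interval of the paired
#' split-wise differences.
#'
#' @param neuron_auc Tibble from [train_condition_decoder()] on neural
#'   features.
#' @param input_auc Tibble from [input_decoder()].
#' @param level Confidence level of the paired-difference interval.
#' @return Tibble with one row per window.
#' @export
compare_decoders <- function(neuron_auc, input_auc, level = 0.95) {
  a <- (1 - level) / 2
  input_auc |>
    dplyr::left_join(
      dplyr::select(neuron_auc, "split", neuron_auc_bin = "auc_bin"),
      by = "split"
    ) |>
    dplyr::group_by(.data$window_s, .data$n_params) |>
    dplyr::summarise(
      median_input_auc = stats::median(.data$auc_bin),
      median_neuron_auc = stats::median(.data$neuron_auc_bin),
      frac_neuron_wins = mean(.data$neuron_auc_bin > .data$auc_bin),
      diff_lo = stats::quantile(.data$neuron_auc_bin - .data$auc_bin, a),
      diff_hi = stats::quantile(.data$neuron_auc_bin - .data$auc_bin, 1 - a),
      .groups = "drop"
    )
}

#' Full feedback-condition decoding analysis on simulated pairs
#'
#' Assembles the complete decoding comparison from a cohort of yoked
#' experiment pairs: simulates mixed-selectivity neuron activity for every
#' experiment, reduces the pooled population with PCA, decodes plaid vs
#' replay from the retained components, and benchmarks raw-input decoders
#' with growing integration windows on identical experiment-level splits.
#'
#' @param pairs List of `experiment_pair` objects.
#' @param models Neuron population tibble; only rows with `mixed == TRUE`
#'   drive the neural decoder (the nonlinear mixed-selectivity subset).
#' @param n_components Principal components retained.
#' @param windows_s Input-decoder integration windows in seconds.
#' @param n_splits Random experiment-level train/test splits.
#' @param rate Neural/behavioral bin rate in Hz.
#' @param seed Seed (splits, neuron noise).
#' @return List with `neuron_auc`, `input_auc`, `comparison`,
#'   `variance_explained` and the splits used.
#' @export
decode_feedback_condition <- function(pairs, models = neuron_population(),
                                      n_components = 10,
                                      windows_s = c(0, 10), n_splits = 100,
                                      rate = 5, seed = 1) {
  mixed <- models[models$mixed, ]
  exps <- purrr::flatten(purrr::map(pairs, function(p) {
    list(plaid = p$plaid, replay = p$replay)
  }))
  ids <- purrr::map_chr(exps, ~ attr(.x, "id"))
  conditions <- as.integer(purrr::map_chr(exps, ~ attr(.x, "condition")) == "plaid")
  binned <- purrr::map(exps, bin_experiment, rate = rate)
  names(binned) <- ids
  activity <- purrr::imap(binned, function(b, id) {
    simulate_neurons(mixed, b$temp, b$bout_start,
      rate = rate,
      seed = seed + utf8ToInt(substr(id, nchar(id), nchar(id)))
    )
  })
  pooled <- do.call(rbind, activity)
  pc <- pca_reduce(pooled, n_components)
  features <- pc$scores
  labels <- rep(conditions, times = purrr::map_int(binned, nrow))
  exp_id <- rep(ids, times = purrr::map_int(binned, nrow))
  splits <- make_experiment_splits(ids, conditions, n_splits, seed = seed)
  neuron_auc <- train_condition_decoder(features, labels, exp_id,
    seed = seed, splits = splits
  )
  input_auc <- input_decoder(binned, conditions,
    windows_s = windows_s,
    splits = splits, seed = seed
  )
  list(
    neuron_auc = neuron_auc, input_auc = input_auc,
    comparison = compare_decoders(neuron_auc, input_auc),
    variance_explained = pc$variance_explained, splits = splits
  )
}
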