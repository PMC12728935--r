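# Data splitting, network training and evaluation.
#
# Architecture and schedule follow the published configuration: a fully
# connected feed-forward net with hidden layers 64/32/16, Leaky-ReLU
# activations, Adam with initial learning rate 0.01 halved (down to 1e-4)
# after 10 epochs without validation improvement, batch size 128, an
# imbalance-weighted MSE loss with elastic-net weight penalties, and early
# stopping with best-weight restoration.

#' Network / training configuration
#'
#' @param hidden Hidden layer sizes.
#' @param leaky_slope Negative-side slope of the Leaky-ReLU.
#' @param lr,lr_floor,lr_patience Initial learning rate, its floor, and the
#'   number of stagnant epochs before halving.
#' @param batch Minibatch size.
#' @param max_epochs Epoch cap.
#' @param es_patience,min_delta Early-stopping patience (epochs) and minimum
#'   validation-RMSE improvement (kJ/mol) that counts as progress.
#' @param l1,l2 Elastic-net penalty coefficients on the weights.
#' @param imbalance_bin Energy bin width (kJ/mol) for inverse-frequency
#'   sample weights; `NA` disables weighting.
#' @param imbalance_gamma Tempering exponent on the inverse frequencies
#'   (1 = raw inverse frequency, 0 = uniform). The tempered default keeps
#'   emphasis on rare strongly-bound poses without letting sparse
#'   repulsive-wall bins dominate the loss.
#' @param imbalance_clip Energies above this value (kJ/mol) are pooled into
#'   one bin for the weight computation (`NA` disables pooling); defaults to
#'   the +10 kJ/mol repulsion-exclusion threshold, beyond which predictions
#'   are filtered out in application anyway.
#' @param weight_cap Upper cap on a sample weight (after mean-1
#'   normalization), guarding against near-empty bins.
#' @param seed Weight-initialization / shuffling seed. Bit-reproducible on
#'   one platform; not guaranteed across BLAS builds.
#' @return Object of class `xb_model_config`.
#' @export
model_config <- function(hidden = c(64, 32, 16), leaky_slope = 0.01,
                         lr = 0.01, lr_floor = 1e-4, lr_patience = 10,
                         batch = 128, max_epochs = 500,
                         es_patience = 30, min_delta = 1e-4,
                         l1 = 1e-6, l2 = 1e-6,
                         imbalance_bin = 1.0, imbalance_gamma = 0.5,
                         imbalance_clip = 10, weight_cap = 20,
                         seed = 1) {
  stopifnot(all(hidden > 0), lr > 0, lr_floor <= lr, batch > 0)
  structure(as.list(environment()), class = "xb_model_config")
}

#' Stratified train/test split
#'
#' Per-stratum counts are proportional to `frac_test` within rounding
#' (plus/minus one element); reproducible under `seed`. Strata smaller than
#' 1/frac_test elements are assigned best-effort with a warning.
#'
#' @param strata Vector of stratum labels, one per row.
#' @param frac_test Test fraction.
#' @param seed RNG seed.
#' @return Character vector `"train"`/`"test"`.
#' @export
split_stratified <- function(strata, frac_test = 0.2, seed = 1) {
  strata <- as.character(strata)
  out <- rep("train", length(strata))
  old <- .Random.seed.exists()
  set.seed(seed)
  small <- FALSE
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_test <- round(length(idx) * frac_test)
    if (length(idx) < ceiling(1 / frac_test)) small <- TRUE
    if (n_test > 0) out[sample(idx, n_test)] <- "test"
  }
  .Random.seed.restore(old)
  if (small) warning("some strata are smaller than 1/frac_test; best-effort assignment")
  out
}

#' Stratified k-fold assignment
#'
#' @param strata Stratum labels.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer fold ids in 1..n_folds; the fold test partitions tile the
#'   data.
#' @export
assign_folds <- function(strata, n_folds = 5, seed = 1) {
  strata <- as.character(strata)
  out <- integer(length(strata))
  old <- .Random.seed.exists()
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    out[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  .Random.seed.restore(old)
  out
}

#' Build stratification labels from a dataset
#'
#' Strata are the halogen crossed with a binned halogen-to-plane distance
#' (the grid's own distances for grid data; `bin_width` bins otherwise).
#'
#' @param dataset Table with `halogen` and `d` (grid) or `y` (random) column.
#' @param bin_width Distance bin width in A for non-grid data.
#' @return Character stratum labels.
#' @export
make_strata <- function(dataset, bin_width = 0.25) {
  dcol <- if ("d" %in% names(dataset)) dataset[["d"]]
          else floor(dataset[["y"]] / bin_width) * bin_width
  paste(dataset[["halogen"]], dcol, sep = "|")
}

# tempered inverse-frequency weights over energy bins, normalized to mean 1
imbalance_weights <- function(y, bin, cap, gamma = 0.5, clip = 10) {
  if (is.na(bin) || gamma == 0) return(rep(1, length(y)))
  b <- floor(y / bin)
  if (!is.na(clip)) b <- pmin(b, floor(clip / bin))
  counts <- table(b)
  w <- as.numeric((length(y) / (length(counts) * counts[as.character(b)]))^gamma)
  w <- w / mean(w)
  pmin(w, cap)
}

#' Train the energy regression network
#'
#' Inputs are scaled features and energies in kJ/mol. The target is
#' internally standardized for conditioning and mapped back at prediction
#' time; reported RMSEs are in kJ/mol. Loss: mean over the batch of
#' w_i (y_i - yhat_i)^2 plus l1/l2 weight penalties, w_i inverse-frequency
#' weights over `imbalance_bin` kJ/mol energy bins.
#'
#' @param x_train,y_train Scaled feature matrix (n x 30) and energies.
#' @param x_val,y_val Validation partition (used for the schedule and early
#'   stopping).
#' @param config [model_config()].
#' @param scaler Optional fitted [fit_scaler()] to embed in the model so
#'   [predict.xb_model()] can accept raw features.
#' @return Object of class `xb_model` with weights, history (epoch, lr,
#'   train/val RMSE in kJ/mol) and the embedded scaler.
#' @export
train_model <- function(x_train, y_train, x_val, y_val,
                        config = model_config(), scaler = NULL) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  stopifnot(nrow(x_train) == length(y_train), nrow(x_val) == length(y_val))
  w <- imbalance_weights(y_train, config$imbalance_bin, config$weight_cap,
                         config$imbalance_gamma, config$imbalance_clip)
  y_mu <- mean(y_train)
  y_sd <- stats::sd(y_train)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  fit <- mlp_train(x_train, (y_train - y_mu) / y_sd, w,
                   x_val, (y_val - y_mu) / y_sd,
                   as.integer(config$hidden), config$leaky_slope,
                   config$lr, config$lr_floor, as.integer(config$lr_patience),
                   as.integer(config$batch), as.integer(config$max_epochs),
                   as.integer(config$es_patience), config$min_delta / y_sd,
                   config$l1, config$l2, as.integer(config$seed))
  history <- data.frame(epoch = fit$history[, 1], lr = fit$history[, 2],
                        train_rmse = fit$history[, 3] * y_sd,
                        val_rmse = fit$history[, 4] * y_sd)
  structure(list(W = fit$W, b = fit$b, config = config,
                 y_center = y_mu, y_scale = y_sd,
                 history = history, best_epoch = fit$best_epoch,
                 scaler = scaler, schema_id = FEATURE_SCHEMA_ID,
                 applicability = NULL),
            class = "xb_model")
}

#' @export
print.xb_model <- function(x, ...) {
  sizes <- c(nrow(x$W[[1]]), vapply(x$W, ncol, integer(1)))
  cat(sprintf("<xb_model: %s, %d epochs (best %d), val RMSE %.4f kJ/mol>\n",
              paste(sizes, collapse = "/"),
              nrow(x$history), x$best_epoch, min(x$history$val_rmse)))
  invisible(x)
}

#' Predict adduct formation energies
#'
#' @param object `xb_model`.
#' @param newdata Feature matrix (or table containing the 30 feature
#'   columns). Raw features if the model embeds a scaler, already-scaled
#'   otherwise.
#' @param scaled Set TRUE if `newdata` is already min-max scaled.
#' @param ... Unused.
#' @return Numeric vector of energies in kJ/mol; deterministic and
#'   batch-order independent.
#' @export
predict.xb_model <- function(object, newdata, scaled = is.null(object$scaler),
                             ...) {
  x <- if (is.data.frame(newdata))
         as.matrix(as.data.frame(newdata)[, feature_names(), drop = FALSE])
       else as.matrix(newdata)
  if (is.null(dim(x)) || ncol(x) == 1L && length(x) == 30L) x <- matrix(x, 1)
  if (ncol(x) != 30L) stop("feature width must be 30, got ", ncol(x))
  if (!scaled) {
    if (is.null(object$scaler)) stop("model has no embedded scaler; pass scaled features")
    x <- apply_scaler(x, object$scaler)
  }
  as.numeric(mlp_forward(x, object$W, object$b, object$config$leaky_slope)) *
    object$y_scale + object$y_center
}

#' Evaluate predictions against reference energies
#'
#' Reports R^2 (= 1 - SS_res/SS_tot), RMSE and MAE (kJ/mol), the per-record
#' energy difference dde = calc - pred, and its histogram in 0.5 kJ/mol bins
#' over \[-4, 4\] with out-of-range values clipped to the limits.
#'
#' @param calc,pred Numeric vectors of equal length >= 2.
#' @return List `r2`, `rmse`, `mae`, `dde`, `histogram` (data.frame with bin
#'   edges and counts summing to the record count).
#' @export
evaluate_predictions <- function(calc, pred) {
  stopifnot(length(calc) == length(pred), length(calc) >= 2)
  dde <- calc - pred
  ss_tot <- sum((calc - mean(calc))^2)
  r2 <- if (ss_tot == 0) { warning("zero-variance reference; R^2 undefined"); NA_real_ }
        else 1 - sum(dde^2) / ss_tot
  breaks <- seq(-4, 4, by = 0.5)
  clipped <- pmin(pmax(dde, -4), 4)
  # right = FALSE + include.lowest: bins [l, u) except the last, [3.5, 4]
  counts <- graphics::hist(clipped, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  list(r2 = r2,
       rmse = sqrt(mean(dde^2)),
       mae = mean(abs(dde)),
       dde = dde,
       histogram = data.frame(lower = breaks[-length(breaks)],
                              upper = breaks[-1], count = counts))
}

#' End-to-end training pipeline on a feature + energy table
#'
#' Stratifies by halogen and plane distance, performs the 80/20 outer
#' train/test split and the inner 80/20 train/validation split, fits the
#' min-max scaler on the model-training partition only, trains the network,
#' and evaluates on the held-out test partition. Also fits the
#' Mahalanobis applicability domain on the scaled training features.
#'
#' @param dataset Table from [generate_dataset()] (or equivalent with the 30
#'   feature columns plus `energy`).
#' @param config [model_config()].
#' @param frac_test,frac_val Outer / inner split fractions.
#' @param split_seed Seed for both splits.
#' @return List `model` (with scaler and applicability embedded), `split`
#'   (labels `"train"`, `"val"`, `"test"`), `report`
#'   ([evaluate_predictions()] on the test partition).
#' @export
train_energy_model <- function(dataset, config = model_config(),
                               frac_test = 0.2, frac_val = 0.2,
                               split_seed = 1) {
  strata <- make_strata(dataset)
  outer <- split_stratified(strata, frac_test, seed = split_seed)
  inner_idx <- which(outer == "train")
  inner <- split_stratified(strata[inner_idx], frac_val, seed = split_seed + 1)
  split <- outer
  split[inner_idx[inner == "test"]] <- "val"

  fmat <- as.matrix(as.data.frame(dataset)[, feature_names()])
  y <- dataset[["energy"]]
  tr <- split == "train"; va <- split == "val"; te <- split == "test"
  scaler <- fit_scaler(fmat[tr, , drop = FALSE])
  xs <- apply_scaler(fmat, scaler)
  model <- train_model(xs[tr, ], y[tr], xs[va, ], y[va], config, scaler = scaler)
  model$applicability <- fit_md(xs[tr, , drop = FALSE])
  pred <- predict(model, fmat[te, , drop = FALSE])
  list(model = model, split = split,
       report = evaluate_predictions(y[te], pred))
}
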