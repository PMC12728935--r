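# Single-file model checkpoints.
#
# A checkpoint is one JSON document holding the network weights, the
# min-max scaler, the descriptor schema id, the training configuration and
# history, and (when fitted) the applicability-domain parameters. Numbers
# are serialized at full precision so a reloaded model predicts
# identically.

#' Save a trained model to a JSON checkpoint
#'
#' @param model `xb_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "xb_model"))
  ap <- model$applicability
  doc <- list(
    format = "halopi-checkpoint-1",
    schema_id = model$schema_id,
    config = unclass(model$config),
    y_center = model$y_center, y_scale = model$y_scale,
    best_epoch = model$best_epoch,
    W = lapply(model$W, unclass),
    b = lapply(model$b, as.numeric),
    scaler = if (!is.null(model$scaler))
      list(min = as.numeric(model$scaler$min), max = as.numeric(model$scaler$max),
           names = model$scaler$names, schema_id = model$scaler$schema_id),
    applicability = if (!is.null(ap))
      list(mu = as.numeric(ap$mu), sigma = unclass(ap$sigma),
           keep = ap$keep, percentile = ap$percentile, scale = ap$scale,
           n_features = ap$n_features),
    history = model$history)
  # I(17) significant digits: exact binary round-trip for doubles
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return `xb_model` predicting identically to the saved one.
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "halopi-checkpoint-1"))
    stop("unsupported checkpoint format: ",
         if (is.null(doc$format)) "<missing>" else doc$format,
         " (expected halopi-checkpoint-1)")
  scaler <- NULL
  if (!is.null(doc$scaler)) {
    scaler <- structure(list(min = doc$scaler$min, max = doc$scaler$max,
                             names = doc$scaler$names,
                             schema_id = doc$scaler$schema_id),
                        class = "xb_scaler")
    names(scaler$min) <- scaler$names
    names(scaler$max) <- scaler$names
  }
  ap <- NULL
  if (!is.null(doc$applicability)) {
    a <- doc$applicability
    sigma <- as.matrix(a$sigma)
    eps <- 1e-8 * sum(diag(sigma)) / ncol(sigma)
    ap <- structure(list(mu = a$mu, sigma = sigma,
                         sigma_inv = solve(sigma + diag(eps, ncol(sigma))),
                         keep = a$keep, percentile = a$percentile,
                         scale = a$scale, n_features = a$n_features),
                    class = "xb_md_model")
  }
  cfg <- doc$config
  class(cfg) <- "xb_model_config"
  structure(list(W = lapply(doc$W, as.matrix),
                 b = lapply(doc$b, as.numeric),
                 config = cfg,
                 y_center = doc$y_center, y_scale = doc$y_scale,
                 history = as.data.frame(doc$history),
                 best_epoch = doc$best_epoch,
                 scaler = scaler, schema_id = doc$schema_id,
                 applicability = ap),
            class = "xb_model")
}
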