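#' Save / load a trained model as a JSON bundle
#'
#' Writes a single self-describing JSON file containing every parameter
#' matrix (row-major nested arrays), the batch-norm running statistics,
#' the training configuration, the feature schema version, and (optionally)
#' the min-max scaling statistics — enough for the explainer and evaluator
#' to reload the model without the training stack.
#'
#' @param model Trained `iws_lstm`.
#' @param path Output file path (`.json`).
#' @param scaling Optional `iws_scaling` to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, scaling = NULL) {
  stopifnot(inherits(model, "iws_lstm"))
  p <- model$params
  bundle <- list(
    format = "iwsrisk-lstm", format_version = 1L,
    schema_version = attr(feature_schema(), "version"),
    input_dim = p$input_dim, hidden_dim = p$hidden_dim,
    num_layers = p$num_layers,
    layers = lapply(p$layers, function(l) {
      list(Wx = unclass(l$Wx), Wh = unclass(l$Wh), b = l$b)
    }),
    head = p$head,
    bn = p$bn,
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    scaling = if (!is.null(scaling)) {
      list(min = scaling$min, max = scaling$max,
           feature_names = scaling$feature_names)
    })
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(b$format, "iwsrisk-lstm")) stop("not an iwsrisk model bundle")
  params <- list(
    layers = lapply(seq_len(b$num_layers), function(l) {
      lay <- b$layers[[l]]
      list(Wx = as.matrix(lay$Wx), Wh = as.matrix(lay$Wh), b = as.numeric(lay$b))
    }),
    head = list(w = as.numeric(b$head$w), b = as.numeric(b$head$b)),
    bn = list(gamma = as.numeric(b$bn$gamma), beta = as.numeric(b$bn$beta),
              mean = as.numeric(b$bn$mean), var = as.numeric(b$bn$var),
              eps = as.numeric(b$bn$eps)),
    input_dim = as.integer(b$input_dim), hidden_dim = as.integer(b$hidden_dim),
    num_layers = as.integer(b$num_layers))
  class(params) <- "iws_lstm_params"
  cfg <- b$config
  class(cfg) <- "iws_train_config"
  model <- list(params = params, config = cfg, history = NULL,
                best_epoch = b$best_epoch)
  class(model) <- "iws_lstm"
  if (!is.null(b$scaling)) {
    sc <- list(min = unlist(b$scaling$min), max = unlist(b$scaling$max),
               feature_names = b$scaling$feature_names)
    class(sc) <- "iws_scaling"
    attr(model, "scaling") <- sc
  }
  model
}
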