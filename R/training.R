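# Training loop (Adam + binary cross-entropy, seeded end to end) and
# prediction. All stochastic pieces (shuffling, dropout) draw from one RNG
# stream derived from the run seed, so a run is a pure function of
# (data, provider, config, seed).

encode_set_int <- function(data) {
  m <- t(vapply(data$sequence, encode_integers, integer(SEQ_LEN)))
  rownames(m) <- data$id
  m
}

# Stack per-sample (41, D) embeddings into one sample-major (n*41, D) matrix.
embed_stack <- function(provider, data) {
  mats <- embed_set(provider, data)
  do.call(rbind, mats)
}

model_needs <- function(model) {
  inputs <- vapply(model$branches, `[[`, character(1), "input")
  list(int = "int" %in% inputs, emb = "emb" %in% inputs)
}

prepare_inputs <- function(model, data, provider) {
  needs <- model_needs(model)
  list(
    int = if (needs$int) encode_set_int(data) else NULL,
    emb = if (needs$emb) {
      if (is.null(provider)) {
        stop("this model requires an embedding provider", call. = FALSE)
      }
      embed_stack(provider, data)
    } else NULL
  )
}

slice_batch <- function(inputs, idx) {
  list(
    int = if (!is.null(inputs$int)) inputs$int[idx, , drop = FALSE] else NULL,
    emb = if (!is.null(inputs$emb)) {
      rows <- as.vector(t(outer((idx - 1L) * SEQ_LEN, seq_len(SEQ_LEN), `+`)))
      inputs$emb[rows, , drop = FALSE]
    } else NULL
  )
}

bce_loss <- function(probs, y) {
  eps <- 1e-12
  -mean(y * log(probs + eps) + (1 - y) * log(1 - probs + eps))
}

#' Train the site classifier
#'
#' Optimizes binary cross-entropy with Adam at the configured learning rate
#' for `cfg$epochs` epochs in batches of `cfg$batch_size` (the last batch of
#' an epoch may be smaller), with gradient-norm clipping at
#' `cfg$max_grad_norm` (or a per-unit weight max-norm when
#' `cfg$l2_mode = "weight_maxnorm"`). Dropout is active only during training.
#' Batch order is reshuffled every epoch from the run seed. All embeddings
#' are materialized before the first step, so a provider missing any sample
#' fails before training starts.
#'
#' @param train_set A non-empty [sample_set()].
#' @param provider An `embedding_provider` (required unless no branch
#'   consumes provider embeddings).
#' @param cfg A [model_config()].
#' @param seed Integer run seed; initialization, shuffling and dropout all
#'   derive from it.
#' @param model Optional pre-built `site_model` (must match `cfg`); by
#'   default built fresh from `(cfg, seed)`.
#' @return A `trained_model`: list with `model`, `config`, `history`
#'   (per-epoch mean training loss) and `seed`.
#' @export
train_model <- function(train_set, provider = NULL, cfg = model_config(),
                        seed = 1L, model = NULL) {
  stopifnot(inherits(train_set, "sample_set"))
  if (nrow(train_set) == 0L) stop("training set is empty", call. = FALSE)
  if (is.null(model)) model <- build_model(cfg, seed = seed)
  inputs <- prepare_inputs(model, train_set, provider)
  y <- train_set$label
  n <- nrow(train_set)
  flat <- model_flat_params(model)
  opt <- adam_init(flat)
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(seed, "train_loop"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        batch <- slice_batch(inputs, idx)
        yb <- y[idx]
        fwd <- model_forward(model, batch, training = TRUE)
        loss <- bce_loss(fwd$probs, yb)
        ep_loss <- ep_loss + loss * length(idx)
        dlogits <- (fwd$probs - yb) / length(idx)
        g <- model_backward(model, fwd$cache, dlogits)
        grads <- model_flat_grads(model, g)
        if (cfg$l2_mode == "grad_clip") {
          grads <- clip_grad_norm(grads, cfg$max_grad_norm)
        }
        upd <- adam_update(opt, flat, grads, lr = cfg$learning_rate)
        opt <- upd$state
        flat <- upd$flat
        if (cfg$l2_mode == "weight_maxnorm") {
          flat <- apply_weight_maxnorm(flat, cfg$max_grad_norm)
        }
        model <- model_set_params(model, flat)
      }
      history[ep] <- ep_loss / n
    }
  })
  recalibrate_bn(model, inputs, n, cfg$batch_size)
  structure(list(model = model, config = cfg, history = history,
                 seed = as.integer(seed)),
            class = "trained_model")
}

# After the optimization loop, batch-norm running statistics are re-estimated
# over the training set with dropout disabled, so evaluation-mode
# normalization matches the inference-time activation distribution (the
# running averages accumulated during training reflect dropout-perturbed
# activations). Cumulative-average momentum 1/i makes the result the exact
# mean of the per-batch statistics, independent of batch order.
recalibrate_bn <- function(model, inputs, n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + batch_size - 1L, n)
    batch <- slice_batch(inputs, idx)
    ctx_flags <- list(no_dropout = TRUE, bn_momentum = 1 / i)
    model_forward(model, batch, training = TRUE, ctx_extra = ctx_flags)
  }
  invisible(model)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s, %d epochs (final loss %.4f), seed %d\n",
    x$config$branch_mode, length(x$history),
    x$history[length(x$history)], x$seed))
  invisible(x)
}

#' Predict site probabilities
#'
#' Runs the trained network in evaluation mode (dropout off, batch-norm
#' running statistics). Thresholding is a separate pure step
#' ([classify_probs()]).
#'
#' @param object A `trained_model`.
#' @param samples A [sample_set()].
#' @param provider An `embedding_provider` covering all sample ids.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Named numeric vector of probabilities in (0, 1).
#' @export
predict.trained_model <- function(object, samples, provider = NULL,
                                  batch_size = 500L, ...) {
  inputs <- prepare_inputs(object$model, samples, provider)
  n <- nrow(samples)
  probs <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- slice_batch(inputs, idx)
    probs[idx] <- model_forward(object$model, batch, training = FALSE)$probs
  }
  stats::setNames(probs, samples$id)
}

#' Threshold probabilities into class labels
#'
#' Probabilities greater than or equal to the threshold classify positive
#' (ties to positive).
#'
#' @param probs Numeric probabilities.
#' @param threshold Classification threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
classify_probs <- function(probs, threshold = 0.5) {
  as.integer(probs >= threshold)
}

#' Save a trained model checkpoint
#'
#' Serializes the weights, buffers, training history and seed, together with
#' a JSON rendering of the model configuration, into one checkpoint file that
#' reloads bit-exactly via [load_checkpoint()].
#'
#' @param trained A `trained_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(trained, path) {
  stopifnot(inherits(trained, "trained_model"))
  cfg_plain <- lapply(unclass(trained$config),
                      function(x) if (is.object(x)) unclass(x) else x)
  obj <- list(
    trained = trained,
    config_json = jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                                   digits = NA, null = "null")
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trained model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return The `trained_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$trained
}
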