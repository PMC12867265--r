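# The dual-branch site classifier: an inception branch over learned word
# embeddings and a transformer-encoder branch over provider embeddings, fused
# by a two-layer head ending in a sigmoid. Single-branch ablation variants and
# LSTM/RNN branch types (used for model selection) share the same surface.

#' Configure an inception module
#'
#' @param path_channels Four positive integers: output channels of the 1x1
#'   path, the 1x1-then-3 path, the 1x1-then-5 path, and the pool-then-1x1
#'   path. The module's output channel count is their sum.
#' @return An `inception_config` list.
#' @export
inception_config <- function(path_channels = c(16L, 16L, 16L, 16L)) {
  if (length(path_channels) != 4L || any(path_channels < 1L)) {
    stop("path_channels must be four positive integers", call. = FALSE)
  }
  structure(list(path_channels = as.integer(path_channels)),
            class = "inception_config")
}

#' Configure the site-classifier model
#'
#' Defaults follow the published training recipe: 32-dim word embeddings,
#' three inception modules, six transformer encoder layers, 256-dim branch
#' outputs, sigmoid output, Adam at learning rate 1e-5 for 18 epochs with
#' batch size 500, dropout 0.5 inside the inception branch and 0.3 elsewhere,
#' and a maximum L2 norm of 1 (enforced by gradient-norm clipping; a per-unit
#' weight max-norm is available via `l2_mode = "weight_maxnorm"`).
#'
#' @param embed_dim Dimension of the provider embeddings fed to branch 2
#'   (1280 for the full-scale language model).
#' @param word_embed_dim Learned word-embedding dimension (branch 1).
#' @param n_inception_modules Number of stacked inception modules.
#' @param inception InceptionConfig for each module ([inception_config()]).
#' @param transformer_layers Number of transformer encoder layers.
#' @param transformer_heads Attention heads (must divide `embed_dim`).
#' @param transformer_ffn_dim Width of the encoder feed-forward sublayer.
#' @param branch_output_dim Per-branch output dimension before fusion.
#' @param dropout_inception Dropout rate inside the inception branch.
#' @param dropout_other Dropout rate everywhere else.
#' @param learning_rate,epochs,batch_size,max_grad_norm Training recipe.
#' @param threshold Classification threshold on the output probability
#'   (ties classify positive).
#' @param branch_mode `"dual"`, `"inception_only"` or `"transformer_only"`.
#' @param branch1_type,branch2_type Branch architectures: `"inception"`,
#'   `"transformer"`, `"lstm"` or `"rnn"`. Branch 1 consumes integer-encoded
#'   sequences (through word embeddings); branch 2 consumes provider
#'   embeddings.
#' @param rnn_hidden Hidden size of the LSTM/RNN branch types.
#' @param l2_mode `"grad_clip"` (default) or `"weight_maxnorm"`.
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 1280L,
                         word_embed_dim = 32L,
                         n_inception_modules = 3L,
                         inception = inception_config(),
                         transformer_layers = 6L,
                         transformer_heads = 8L,
                         transformer_ffn_dim = 2048L,
                         branch_output_dim = 256L,
                         dropout_inception = 0.5,
                         dropout_other = 0.3,
                         learning_rate = 1e-5,
                         epochs = 18L,
                         batch_size = 500L,
                         max_grad_norm = 1,
                         threshold = 0.5,
                         branch_mode = c("dual", "inception_only",
                                         "transformer_only"),
                         branch1_type = "inception",
                         branch2_type = "transformer",
                         rnn_hidden = 128L,
                         l2_mode = c("grad_clip", "weight_maxnorm")) {
  branch_mode <- match.arg(branch_mode)
  l2_mode <- match.arg(l2_mode)
  types <- c("inception", "transformer", "lstm", "rnn")
  if (!branch1_type %in% types || !branch2_type %in% types) {
    stop("branch types must be one of: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(embed_dim >= 1L, word_embed_dim >= 1L, branch_output_dim >= 1L,
            transformer_layers >= 1L, epochs >= 1L, batch_size >= 1L)
  if (dropout_inception < 0 || dropout_inception >= 1 ||
      dropout_other < 0 || dropout_other >= 1) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (embed_dim %% transformer_heads != 0L) {
    stop("transformer_heads must divide embed_dim", call. = FALSE)
  }
  structure(list(
    embed_dim = as.integer(embed_dim),
    word_embed_dim = as.integer(word_embed_dim),
    n_inception_modules = as.integer(n_inception_modules),
    inception = inception,
    transformer_layers = as.integer(transformer_layers),
    transformer_heads = as.integer(transformer_heads),
    transformer_ffn_dim = as.integer(transformer_ffn_dim),
    branch_output_dim = as.integer(branch_output_dim),
    dropout_inception = dropout_inception,
    dropout_other = dropout_other,
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    max_grad_norm = max_grad_norm,
    threshold = threshold,
    branch_mode = branch_mode,
    branch1_type = branch1_type,
    branch2_type = branch2_type,
    rnn_hidden = as.integer(rnn_hidden),
    l2_mode = l2_mode
  ), class = "model_config")
}

#' Per-position dimension after the transformer branch's feature-axis pooling
#'
#' The transformer branch max-pools the per-position feature axis with kernel
#' `kernel` and stride `stride`; 1280-dim embeddings pool to 639.
#'
#' @param dim Input feature dimension.
#' @param kernel,stride Pooling parameters.
#' @return Integer output dimension.
#' @export
pooled_feature_dim <- function(dim, kernel = 3L, stride = 2L) {
  as.integer((dim - kernel) %/% stride + 1L)
}

#' Build one inception module
#'
#' Four parallel convolutional paths over a sequence tensor: a 1x1
#' convolution; 1x1 then kernel-3; 1x1 then kernel-5; and a length-preserving
#' max pool followed by 1x1. All paths preserve the sequence length; their
#' outputs are concatenated along channels, batch-normalized and passed
#' through ReLU.
#'
#' @param in_channels Input channel count.
#' @param cfg An [inception_config()].
#' @return A module usable inside [build_model()]'s branch stacks.
#' @export
build_inception_module <- function(in_channels, cfg = inception_config()) {
  if (in_channels < 1L) stop("in_channels must be >= 1", call. = FALSE)
  pc <- cfg$path_channels
  m <- new_mod("inception", path_channels = pc)
  m$sub <- list(
    p1 = nn_sequential(nn_conv1d(in_channels, pc[1L], 1L)),
    p2 = nn_sequential(nn_conv1d(in_channels, pc[2L], 1L), nn_relu(),
                       nn_conv1d(pc[2L], pc[2L], 3L)),
    p3 = nn_sequential(nn_conv1d(in_channels, pc[3L], 1L), nn_relu(),
                       nn_conv1d(pc[3L], pc[3L], 5L)),
    p4 = nn_sequential(nn_maxpool_len_same(),
                       nn_conv1d(in_channels, pc[4L], 1L)),
    bn = nn_batchnorm(sum(pc))
  )
  m
}

inception_forward <- function(mod, x, ctx) {
  paths <- c("p1", "p2", "p3", "p4")
  outs <- vector("list", 4L); caches <- vector("list", 4L)
  for (i in seq_along(paths)) {
    r <- mod_forward(mod$sub[[paths[i]]], x, ctx)
    outs[[i]] <- r$y; caches[[i]] <- r$cache
  }
  y <- do.call(cbind, outs)
  r_bn <- mod_forward(mod$sub$bn, y, ctx)
  act <- r_bn$y
  mask <- act > 0
  list(y = act * mask,
       cache = list(paths = caches, bn = r_bn$cache, mask = mask,
                    widths = vapply(outs, ncol, integer(1))),
       ctx = ctx)
}

inception_backward <- function(mod, cache, dy, ctx) {
  dy <- dy * cache$mask
  r_bn <- mod_backward(mod$sub$bn, cache$bn, dy, ctx)
  d_cat <- r_bn$dx
  paths <- c("p1", "p2", "p3", "p4")
  offs <- cumsum(c(0L, cache$widths))
  dx <- NULL
  g <- list(sub = list(bn = r_bn$g))
  for (i in seq_along(paths)) {
    cols <- (offs[i] + 1L):offs[i + 1L]
    r <- mod_backward(mod$sub[[paths[i]]], cache$paths[[i]],
                      d_cat[, cols, drop = FALSE], ctx)
    dx <- if (is.null(dx)) r$dx else dx + r$dx
    g$sub[[paths[i]]] <- r$g
  }
  list(dx = dx, g = g)
}

build_encoder_layer <- function(dim, heads, ffn_dim, dropout) {
  m <- new_mod("encoder", dim = dim)
  m$sub <- list(
    mha = nn_mha(dim, heads),
    dp1 = nn_dropout(dropout),
    ln1 = nn_layernorm(dim),
    ffn = nn_sequential(nn_linear(dim, ffn_dim), nn_relu(),
                        nn_linear(ffn_dim, dim)),
    dp2 = nn_dropout(dropout),
    ln2 = nn_layernorm(dim)
  )
  m
}

encoder_forward <- function(mod, x, ctx) {
  r_mha <- mod_forward(mod$sub$mha, x, ctx)
  r_dp1 <- mod_forward(mod$sub$dp1, r_mha$y, ctx)
  x1 <- x + r_dp1$y
  r_ln1 <- mod_forward(mod$sub$ln1, x1, ctx)
  h1 <- r_ln1$y
  r_ffn <- mod_forward(mod$sub$ffn, h1, ctx)
  r_dp2 <- mod_forward(mod$sub$dp2, r_ffn$y, ctx)
  x2 <- h1 + r_dp2$y
  r_ln2 <- mod_forward(mod$sub$ln2, x2, ctx)
  list(y = r_ln2$y,
       cache = list(mha = r_mha$cache, dp1 = r_dp1$cache, ln1 = r_ln1$cache,
                    ffn = r_ffn$cache, dp2 = r_dp2$cache, ln2 = r_ln2$cache),
       ctx = ctx)
}

encoder_backward <- function(mod, cache, dy, ctx) {
  r_ln2 <- mod_backward(mod$sub$ln2, cache$ln2, dy, ctx)
  d_x2 <- r_ln2$dx
  r_dp2 <- mod_backward(mod$sub$dp2, cache$dp2, d_x2, ctx)
  r_ffn <- mod_backward(mod$sub$ffn, cache$ffn, r_dp2$dx, ctx)
  d_h1 <- d_x2 + r_ffn$dx
  r_ln1 <- mod_backward(mod$sub$ln1, cache$ln1, d_h1, ctx)
  d_x1 <- r_ln1$dx
  r_dp1 <- mod_backward(mod$sub$dp1, cache$dp1, d_x1, ctx)
  r_mha <- mod_backward(mod$sub$mha, cache$mha, r_dp1$dx, ctx)
  dx <- d_x1 + r_mha$dx
  g <- list(sub = list(mha = r_mha$g, dp1 = r_dp1$g, ln1 = r_ln1$g,
                       ffn = r_ffn$g, dp2 = r_dp2$g, ln2 = r_ln2$g))
  list(dx = dx, g = g)
}

build_branch <- function(type, position, cfg) {
  stopifnot(position %in% c(1L, 2L))
  input <- if (position == 1L) "int" else "emb"
  out_dim <- cfg$branch_output_dim
  if (type == "inception") {
    if (input != "int") {
      stop("the inception branch consumes integer-encoded sequences ",
           "(branch 1 position only)", call. = FALSE)
    }
    ch <- sum(cfg$inception$path_channels)
    mods <- list(nn_embedding(4L, cfg$word_embed_dim))
    in_ch <- cfg$word_embed_dim
    for (i in seq_len(cfg$n_inception_modules)) {
      mods <- c(mods, list(build_inception_module(in_ch, cfg$inception)))
      in_ch <- ch
    }
    mods <- c(mods, list(nn_dropout(cfg$dropout_inception), nn_maxpool_len(),
                         nn_flatten(),
                         nn_linear(ch * (SEQ_LEN %/% 2L), out_dim),
                         nn_relu()))
    mod <- do.call(nn_sequential, mods)
  } else if (type == "transformer") {
    if (input != "emb") {
      stop("the transformer branch consumes provider embeddings ",
           "(branch 2 position only)", call. = FALSE)
    }
    enc <- lapply(seq_len(cfg$transformer_layers), function(i) {
      build_encoder_layer(cfg$embed_dim, cfg$transformer_heads,
                          cfg$transformer_ffn_dim, cfg$dropout_other)
    })
    dp <- pooled_feature_dim(cfg$embed_dim)
    mods <- c(enc, list(nn_maxpool_feat(3L, 2L), nn_flatten(),
                        nn_linear(SEQ_LEN * dp, 512L), nn_relu(),
                        nn_dropout(cfg$dropout_other),
                        nn_linear(512L, out_dim), nn_relu()))
    mod <- do.call(nn_sequential, mods)
  } else {  # lstm / rnn
    mods <- list()
    d_in <- if (input == "int") cfg$word_embed_dim else cfg$embed_dim
    if (input == "int") mods <- list(nn_embedding(4L, cfg$word_embed_dim))
    mods <- c(mods, list(nn_rnn(d_in, cfg$rnn_hidden, cell = type),
                         nn_linear(cfg$rnn_hidden, out_dim), nn_relu()))
    mod <- do.call(nn_sequential, mods)
  }
  list(type = type, input = input, mod = mod)
}

# Head order: linear, ReLU, dropout, then batch norm immediately before the
# zero-initialized output linear. Centring the pre-logit features keeps the
# 0.5 probability threshold at the class midpoint even when the short
# training schedule leaves the output bias essentially untrained.
build_head <- function(in_dim, cfg) {
  nn_sequential(
    nn_linear(in_dim, 128L),
    nn_relu(),
    nn_dropout(cfg$dropout_other),
    nn_batchnorm(128L),
    nn_linear(128L, 1L, zero_init = TRUE)
  )
}

#' Build the site-classifier network
#'
#' Assembles the dual-branch model (or a single-branch ablation variant)
#' under a seed that fully determines the initialization. In dual mode,
#' branch 1 consumes integer-encoded sequences and branch 2 consumes
#' (41, dim) provider embeddings; both emit `branch_output_dim`-vectors,
#' which are concatenated and passed through the fusion head (linear 128,
#' 1-D batch norm, ReLU, dropout, linear 1) ending in a sigmoid.
#'
#' The final output layer is zero-initialized so that early training is
#' driven by the data signal rather than by random projection noise; with
#' the short published training schedule this makes the learned decision
#' function dominate from the first optimizer step.
#'
#' @param cfg A [model_config()].
#' @param seed Integer initialization seed.
#' @return A `site_model`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(derive_seed(seed, "model_init"), {
    branches <- switch(cfg$branch_mode,
      dual = list(build_branch(cfg$branch1_type, 1L, cfg),
                  build_branch(cfg$branch2_type, 2L, cfg)),
      inception_only = list(build_branch("inception", 1L, cfg)),
      transformer_only = list(build_branch("transformer", 2L, cfg))
    )
    head_in <- length(branches) * cfg$branch_output_dim
    structure(list(cfg = cfg, branches = branches,
                   head = build_head(head_in, cfg), seed = as.integer(seed)),
              class = "site_model")
  })
}

#' @export
print.site_model <- function(x, ...) {
  types <- vapply(x$branches, `[[`, character(1), "type")
  cat(sprintf("<site_model> mode %s (%s), %s parameters\n",
              x$cfg$branch_mode, paste(types, collapse = " + "),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# batch: list(int = B x 41 integer matrix, emb = (B*41) x D matrix or NULL)
model_forward <- function(model, batch, training = FALSE, ctx_extra = NULL) {
  B <- nrow(batch$int) %||% (nrow(batch$emb) %/% SEQ_LEN)
  outs <- vector("list", length(model$branches))
  caches <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    br <- model$branches[[i]]
    x <- if (br$input == "int") batch$int else batch$emb
    if (is.null(x)) {
      stop("batch lacks the '", br$input, "' input required by the ",
           br$type, " branch", call. = FALSE)
    }
    ctx <- c(list(training = training, B = B,
                  L = if (br$input == "emb") SEQ_LEN else NULL), ctx_extra)
    r <- mod_forward(br$mod, x, ctx)
    outs[[i]] <- r$y; caches[[i]] <- r$cache
  }
  fused <- do.call(cbind, outs)
  ctx_h <- c(list(training = training, B = B, L = NULL), ctx_extra)
  r_head <- mod_forward(model$head, fused, ctx_h)
  logits <- as.numeric(r_head$y)
  probs <- sigmoid(logits)
  list(probs = probs, logits = logits,
       cache = list(branches = caches, head = r_head$cache, B = B,
                    widths = vapply(outs, ncol, integer(1)),
                    training = training))
}

model_backward <- function(model, cache, dlogits) {
  B <- cache$B
  ctx_h <- list(training = cache$training, B = B, L = NULL)
  r_head <- mod_backward(model$head, cache$head, matrix(dlogits, ncol = 1L),
                         ctx_h)
  d_fused <- r_head$dx
  offs <- cumsum(c(0L, cache$widths))
  g_branches <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    br <- model$branches[[i]]
    cols <- (offs[i] + 1L):offs[i + 1L]
    ctx <- list(training = cache$training, B = B,
                L = if (br$input == "emb") SEQ_LEN else NULL)
    r <- mod_backward(br$mod, cache$branches[[i]],
                      d_fused[, cols, drop = FALSE], ctx)
    g_branches[[i]] <- r$g
  }
  list(head = r_head$g, branches = g_branches)
}

model_flat_params <- function(model) {
  out <- list()
  for (i in seq_along(model$branches)) {
    out <- c(out, flatten_params(model$branches[[i]]$mod,
                                 prefix = sprintf("b%d.", i)))
  }
  c(out, flatten_params(model$head, prefix = "head."))
}

model_flat_grads <- function(model, g) {
  out <- list()
  for (i in seq_along(model$branches)) {
    out <- c(out, flatten_grads(g$branches[[i]], prefix = sprintf("b%d.", i)))
  }
  c(out, flatten_grads(g$head, prefix = "head."))
}

model_set_params <- function(model, flat) {
  for (i in seq_along(model$branches)) {
    model$branches[[i]]$mod <- set_params(model$branches[[i]]$mod, flat,
                                          prefix = sprintf("b%d.", i))
  }
  model$head <- set_params(model$head, flat, prefix = "head.")
  model
}

#' Count trainable parameters
#'
#' @param model A `site_model` or `trained_model`.
#' @return Integer: total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "trained_model")) model <- model$model
  sum(vapply(model_flat_params(model), length, integer(1)))
}
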