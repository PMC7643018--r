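# Two-stage multi-branch fusion classifier: one MLP per feature-set block
# (volume and thickness at three scales), whose 50-unit embeddings are
# concatenated and classified by a fusion MLP; 7 MLP blocks in total in the
# default six-set configuration. Branches are pretrained independently with
# temporary softmax heads, the fusion block is trained on frozen embeddings,
# and finally all parameters are fine-tuned jointly.

#' Branch hidden-layer sizes
#'
#' For an `N`-dimensional input block the branch MLP widens to `3N` (to
#' explore cross-patch correlations), narrows to `round(3N/4)` and ends in a
#' 50-unit embedding.
#'
#' @param N input dimension of the block.
#' @return integer vector `c(3N, round(3N/4), 50)`.
#' @export
branch_layer_sizes <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1)
  c(3L * N, as.integer(round(3 * N / 4)), 50L)
}

#' Fusion hidden-layer sizes
#'
#' The same widen-then-narrow rule applied to the concatenated embedding
#' (300-dimensional for six branches).
#' @param n_branches number of branch embeddings being fused.
#' @return integer vector of three hidden sizes.
#' @export
fusion_layer_sizes <- function(n_branches = 6L) branch_layer_sizes(50L * n_branches)

block_slices <- function(blocks) {
  lapply(seq_len(nrow(blocks)), function(i) blocks$start[i]:blocks$end[i])
}

#' Number of MLP blocks in a multibranch model
#' @param model a fitted or freshly constructed multibranch model.
#' @return integer (branches + 1 fusion block).
#' @export
n_mlp_blocks <- function(model) length(model$branches) + 1L

#' Construct an untrained multibranch model
#'
#' @param block_dims integer vector of block input dimensions (six entries in
#'   the default configuration).
#' @param K number of output classes (3, or 4 with the "fake" GAN channel).
#' @param seed integer seed for weight initialization.
#' @return object of class `multibranch_model` with untrained parameters.
#' @export
multibranch_new <- function(block_dims, K = 3L, seed = 1L) {
  K <- as.integer(K); block_dims <- as.integer(block_dims)
  branches <- lapply(seq_along(block_dims), function(b) {
    N <- block_dims[b]
    mlp_new(c(N, branch_layer_sizes(N)), out_activation = "relu",
            seed = seed + 1000L * b)
  })
  fus_in <- 50L * length(block_dims)
  fusion <- mlp_new(c(fus_in, fusion_layer_sizes(length(block_dims)), K),
                    out_activation = "softmax", seed = seed + 77L)
  structure(list(branches = branches, fusion = fusion,
                 block_dims = as.integer(block_dims), K = as.integer(K)),
            class = "multibranch_model")
}

#' @export
print.multibranch_model <- function(x, ...) {
  cat(sprintf("<multibranch_model> %d branches + fusion, K = %d\n",
              length(x$branches), x$K))
  for (b in seq_along(x$branches))
    cat(sprintf("  branch %d: %s\n", b,
                paste(x$branches[[b]]$sizes, collapse = "-")))
  cat(sprintf("  fusion:   %s\n", paste(x$fusion$sizes, collapse = "-")))
  invisible(x)
}

mb_embed <- function(model, X, slices, dropout = 0) {
  fws <- lapply(seq_along(model$branches), function(b)
    mlp_forward(model$branches[[b]], X[, slices[[b]], drop = FALSE],
                dropout = dropout))
  E <- do.call(cbind, lapply(fws, `[[`, "out"))
  list(fws = fws, E = E)
}

mb_forward <- function(model, X, slices, dropout = 0) {
  em <- mb_embed(model, X, slices, dropout = dropout)
  ff <- mlp_forward(model$fusion, em$E, dropout = dropout)
  list(branch_fws = em$fws, E = em$E, fusion_fw = ff, out = ff$out)
}

#' Pretrain the branch networks
#'
#' Stage one: each branch is trained independently on its own feature block
#' with a temporary K-way softmax head; the head is discarded and the 50-unit
#' rectified layer becomes the branch embedding.
#'
#' @param X numeric matrix of w-score rows (training split).
#' @param y integer labels in `1..K`.
#' @param blocks block table (`$blocks` of a [feature_table()]).
#' @param K number of classes.
#' @param cfg a [train_config()].
#' @param Xval,yval validation split used for early stopping.
#' @return list of branch extractor `mlp`s with attribute `histories`.
#' @export
pretrain_branches <- function(X, y, blocks, K, cfg, Xval, yval) {
  slices <- block_slices(blocks)
  W <- class_weights(y, K)
  histories <- list()
  branches <- lapply(seq_along(slices), function(b) {
    N <- length(slices[[b]])
    net <- mlp_new(c(N, branch_layer_sizes(N), K), out_activation = "softmax",
                   seed = cfg$seed + 1000L * b)
    cfg_b <- cfg; cfg_b$seed <- cfg$seed + 13L * b
    if (!is.null(cfg$pretrain_epochs)) cfg_b$max_epochs <- cfg$pretrain_epochs
    tr <- train_softmax_mlp(net, X[, slices[[b]], drop = FALSE], y, W,
                            Xval[, slices[[b]], drop = FALSE], yval, cfg_b)
    histories[[b]] <<- tr$history
    ext <- tr$net
    ext$W <- ext$W[-length(ext$W)]          # drop the temporary head
    ext$b <- ext$b[-length(ext$b)]
    ext$sizes <- ext$sizes[-length(ext$sizes)]
    ext$out <- "relu"
    ext
  })
  attr(branches, "histories") <- histories
  branches
}

# Joint fine-tuning pass over all parameters (stage 2b).
mb_finetune <- function(model, X, y, W, Xval, yval, cfg, slices) {
  opts <- lapply(model$branches, adam_new)
  opt_f <- adam_new(model$fusion)
  n <- nrow(X)
  set.seed(cfg$seed + 29L)
  best <- list(model = model, loss = Inf, epoch = 0L)
  val_losses <- numeric(0)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      fw <- mb_forward(model, X[idx, , drop = FALSE], slices,
                       dropout = cfg$dropout)
      yi <- y[idx]
      dZ <- (fw$out - one_hot(yi, model$K)) * (W[yi] / length(yi))
      gf <- mlp_backward(model$fusion, fw$fusion_fw, dZ)
      st <- adam_step(model$fusion, gf, opt_f, cfg$lr)
      model$fusion <- st$net; opt_f <- st$opt
      for (b in seq_along(model$branches)) {
        cols <- (b - 1L) * 50L + 1:50
        dE <- gf$dX[, cols, drop = FALSE]
        bf <- fw$branch_fws[[b]]
        dZb <- relu_bwd(dE, bf$Z[[length(bf$Z)]])  # embedding is rectified
        gb <- mlp_backward(model$branches[[b]], bf, dZb)
        stb <- adam_step(model$branches[[b]], gb, opts[[b]], cfg$lr)
        model$branches[[b]] <- stb$net; opts[[b]] <- stb$opt
      }
      tr_loss <- tr_loss + weighted_cross_entropy(fw$out, yi, W); nb <- nb + 1
    }
    vl <- weighted_cross_entropy(mb_forward(model, Xval, slices)$out, yval, W)
    if (!is.finite(vl)) stop("non-finite loss during fine-tuning")
    val_losses <- c(val_losses, vl)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss / nb,
                                         val_loss = vl))
    if (vl < best$loss) best <- list(model = model, loss = vl, epoch = epoch)
    es <- early_stopping_controller(val_losses, cfg$patience)
    if (epoch - es$best_epoch >= cfg$patience) break
  }
  model <- best$model
  model$finetune_history <- history
  model
}

#' Train the fusion block and fine-tune the whole network
#'
#' Stage two: the fusion MLP is first trained on the frozen branch
#' embeddings, then every parameter of the seven blocks is fine-tuned
#' jointly. Early stopping (validation loss, best-epoch restore) applies in
#' both phases.
#'
#' @param branches pretrained branch extractors ([pretrain_branches()]).
#' @param X,y,blocks,K,cfg,Xval,yval as in [pretrain_branches()].
#' @return a trained `multibranch_model`.
#' @export
train_fusion_and_finetune <- function(branches, X, y, blocks, K, cfg,
                                      Xval, yval) {
  slices <- block_slices(blocks)
  W <- class_weights(y, K)
  model <- structure(list(branches = branches, fusion = NULL,
                          block_dims = lengths(slices), K = as.integer(K)),
                     class = "multibranch_model")
  E <- mb_embed(model, X, slices)$E
  Eval <- mb_embed(model, Xval, slices)$E
  fusion <- mlp_new(c(ncol(E), fusion_layer_sizes(length(branches)), K),
                    out_activation = "softmax", seed = cfg$seed + 77L)
  cfg_f <- cfg; cfg_f$seed <- cfg$seed + 7L
  if (!is.null(cfg$fusion_epochs)) cfg_f$max_epochs <- cfg$fusion_epochs
  model$fusion <- train_softmax_mlp(fusion, E, y, W, Eval, yval, cfg_f)$net
  cfg_ft <- cfg
  if (!is.null(cfg$finetune_epochs)) cfg_ft$max_epochs <- cfg$finetune_epochs
  mb_finetune(model, X, y, W, Xval, yval, cfg_ft, slices)
}

#' Train a multibranch classifier end to end
#'
#' Convenience wrapper running branch pretraining then fusion training and
#' joint fine-tuning on an explicit train/validation split.
#'
#' @inheritParams pretrain_branches
#' @return a trained `multibranch_model`.
#' @export
fit_multibranch <- function(X, y, blocks, K = 3L, cfg = train_config(),
                            Xval, yval) {
  branches <- pretrain_branches(X, y, blocks, K, cfg, Xval, yval)
  train_fusion_and_finetune(branches, X, y, blocks, K, cfg, Xval, yval)
}

#' Predict class probabilities and labels
#'
#' Dropout is disabled at inference (all units retained); ties in the argmax
#' resolve to the lowest class index.
#'
#' @param model a trained `multibranch_model`.
#' @param X w-score matrix (or [feature_table()]).
#' @param blocks block table matching the model; defaults to contiguous
#'   blocks of `model$block_dims`.
#' @return list with `probs` (N x K) and `labels` (integer).
#' @export
mb_predict <- function(model, X, blocks = NULL) {
  if (inherits(X, "feature_table")) { blocks <- X$blocks; X <- X$X }
  if (is.null(blocks)) {
    dims <- model$block_dims
    blocks <- data.frame(start = cumsum(c(1L, dims[-length(dims)])),
                         end = cumsum(dims))
  }
  if (ncol(X) != sum(blocks$end - blocks$start + 1L))
    stop("input dimension does not match the model's blocks")
  probs <- mb_forward(model, X, block_slices(blocks))$out
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}
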