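# Minimal multilayer-perceptron engine: rectifier hidden units, inverted
# dropout, Adam, and softmax / tanh / rectifier output heads. Everything is
# dense matrix algebra so BLAS does the heavy lifting; no external deep
# learning runtime is required (or available offline).

relu <- function(Z) relu_fwd(Z)

softmax_rows <- function(Z) {
  m <- Z[, 1]
  for (j in seq_len(ncol(Z))[-1]) m <- pmax(m, Z[, j])
  E <- exp(Z - m)
  E / rowSums(E)
}

#' Create a multilayer perceptron
#'
#' Weights use a scaled-uniform fan-in initialization
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`), biases start at zero.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param out_activation `"softmax"`, `"tanh"`, `"relu"` or `"linear"`.
#' @param seed integer seed for the weight draw.
#' @return object of class `mlp`.
#' @export
mlp_new <- function(sizes, out_activation = c("softmax", "tanh", "relu", "linear"),
                    seed = 1L) {
  out_activation <- match.arg(out_activation)
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, out = out_activation),
            class = "mlp")
}

# Forward pass. dropout > 0 samples inverted-dropout masks on hidden
# activations from the current RNG stream (caller seeds it).
mlp_forward <- function(net, X, dropout = 0) {
  L <- length(net$W)
  A <- vector("list", L + 1L); Z <- vector("list", L); M <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% net$W[[l]]
    Z[[l]] <- Z[[l]] + rep(net$b[[l]], each = nrow(Z[[l]]))
    if (l < L) {
      H <- relu(Z[[l]])
      if (dropout > 0) {
        M[[l]] <- matrix((stats::runif(length(H)) >= dropout) / (1 - dropout),
                         nrow(H))
        H <- H * M[[l]]
      }
      A[[l + 1L]] <- H
    } else {
      A[[l + 1L]] <- switch(net$out,
        softmax = softmax_rows(Z[[l]]),
        tanh = tanh(Z[[l]]),
        relu = relu(Z[[l]]),
        linear = Z[[l]])
    }
  }
  list(A = A, Z = Z, M = M, out = A[[L + 1L]])
}

# Backward pass from the gradient w.r.t. the output PRE-activation of the
# last layer (for softmax + cross-entropy supply P - Y directly; for other
# heads convert before calling). Returns parameter grads and dX.
mlp_backward <- function(net, fw, dZ_out) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- dZ_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- tcrossprod(dZ, net$W[[l]])
      if (!is.null(fw$M[[l - 1L]])) dA <- dA * fw$M[[l - 1L]]
      dZ <- relu_bwd(dA, fw$Z[[l - 1L]])
    } else {
      dZ <- tcrossprod(dZ, net$W[[1L]])
    }
  }
  list(W = gW, b = gb, dX = dZ)
}

adam_new <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  # fold the bias corrections into a single step size
  a <- lr * sqrt(1 - beta2^opt$t) / (1 - beta1^opt$t)
  for (l in seq_along(net$W)) {
    u <- adam_fused(net$W[[l]], opt$mW[[l]], opt$vW[[l]], grads$W[[l]],
                    a, beta1, beta2, eps)
    net$W[[l]] <- u[[1]]; opt$mW[[l]] <- u[[2]]; opt$vW[[l]] <- u[[3]]
    u <- adam_fused(net$b[[l]], opt$mb[[l]], opt$vb[[l]], grads$b[[l]],
                    a, beta1, beta2, eps)
    net$b[[l]] <- u[[1]]; opt$mb[[l]] <- u[[2]]; opt$vb[[l]] <- u[[3]]
  }
  list(net = net, opt = opt)
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 5e-5, batch size
#' 100, dropout 0.5, early stopping with patience 20 epochs.
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs hard epoch cap (early stopping usually fires first).
#' @param patience consecutive non-improving validation epochs before stop.
#' @param dropout hidden-unit dropout rate during training.
#' @param val_fraction validation fraction when no explicit split is given.
#' @param seed integer seed controlling shuffling, dropout and initialization.
#' @param pretrain_epochs,fusion_epochs,finetune_epochs optional per-phase
#'   epoch caps for the two-stage schedule (default: `max_epochs` for every
#'   phase); used to budget compute in scaled-down experiments.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 5e-5, batch_size = 100L, max_epochs = 500L,
                         patience = 20L, dropout = 0.5, val_fraction = 0.1,
                         seed = 1L, pretrain_epochs = max_epochs,
                         fusion_epochs = max_epochs,
                         finetune_epochs = max_epochs) {
  stopifnot(lr > 0, patience >= 1, batch_size >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), dropout = dropout,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 fusion_epochs = as.integer(fusion_epochs),
                 finetune_epochs = as.integer(finetune_epochs)),
            class = "train_config")
}

#' Early-stopping controller
#'
#' Given the per-epoch validation losses, finds the epoch at which training
#' stops (the first epoch lying `patience` epochs after the running minimum
#' without improvement) and the best epoch whose parameters are restored.
#'
#' @param val_losses numeric vector, one loss per epoch (epoch 1 first).
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with `best_epoch` and `stop_epoch` (`stop_epoch` is
#'   `length(val_losses)` when the horizon ends before the rule fires).
#' @export
early_stopping_controller <- function(val_losses, patience = 20L) {
  stopifnot(patience >= 1)
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) best <- e
    if (e - best >= patience)
      return(list(best_epoch = best, stop_epoch = e))
  }
  list(best_epoch = best, stop_epoch = length(val_losses))
}

#' Inverse-frequency class weights
#'
#' `W_j = N_total / N_j` for classes present in the labels; classes absent
#' from the training labels get weight 0.
#'
#' @param labels integer labels in `1..K`.
#' @param K number of classes.
#' @return numeric weight vector of length `K`.
#' @export
class_weights <- function(labels, K) {
  if (length(labels) == 0) stop("empty label list")
  counts <- tabulate(labels, nbins = K)
  ifelse(counts > 0, length(labels) / counts, 0)
}

#' Weighted cross-entropy loss
#'
#' `-(1/N) * sum_i W[y_i] * log(p[i, y_i])` with probabilities clipped to
#' `[1e-12, 1]`; with unit weights this reduces to the ordinary
#' cross-entropy.
#'
#' @param probs N x K matrix of class probabilities (rows sum to 1).
#' @param labels integer labels in `1..K`.
#' @param W length-K class weight vector.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, W) {
  stopifnot(nrow(probs) == length(labels), ncol(probs) == length(W))
  p <- pmin(pmax(probs[cbind(seq_along(labels), labels)], 1e-12), 1)
  -mean(W[labels] * log(p))
}

one_hot <- function(labels, K) {
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

# Generic supervised training loop for a softmax mlp with weighted CE,
# minibatch Adam, seeded shuffling and early stopping with best-epoch
# parameter restore. Returns net, history and stop info.
train_softmax_mlp <- function(net, X, y, W, Xval, yval, cfg) {
  K <- ncol(net$W[[length(net$W)]])
  opt <- adam_new(net)
  n <- nrow(X)
  set.seed(cfg$seed)
  best <- list(net = net, loss = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  val_losses <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      fw <- mlp_forward(net, X[idx, , drop = FALSE], dropout = cfg$dropout)
      yi <- y[idx]
      dZ <- (fw$out - one_hot(yi, K)) * (W[yi] / length(yi))
      g <- mlp_backward(net, fw, dZ)
      st <- adam_step(net, g, opt, cfg$lr)
      net <- st$net; opt <- st$opt
      tr_loss <- tr_loss + weighted_cross_entropy(fw$out, yi, W); nb <- nb + 1
    }
    vp <- mlp_forward(net, Xval)$out
    vl <- weighted_cross_entropy(vp, yval, W)
    val_losses <- c(val_losses, vl)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss / nb,
                                         val_loss = vl))
    if (vl < best$loss) best <- list(net = net, loss = vl, epoch = epoch)
    if (!is.finite(vl) || !is.finite(tr_loss))
      stop("non-finite loss during training; aborting")
    es <- early_stopping_controller(val_losses, cfg$patience)
    if (epoch - es$best_epoch >= cfg$patience) break
  }
  list(net = best$net, history = history, best_epoch = best$epoch)
}
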