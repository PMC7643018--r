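# Generative augmentation of 1-D feature vectors. The generator maps 100-d
# Gaussian noise through a 512-unit rectified hidden layer to a tanh output
# with the feature dimension, so synthetic rows live on the same [-1, 1]
# scale as range-normalized real w-scores. The discriminator is the
# multibranch classifier with a fourth "fake" channel; at test time only the
# three real-class channels are used.

#' Construct a feature generator
#'
#' @param out_dim output feature dimension (3449 in the default layout).
#' @param noise_dim dimension of the Gaussian noise input (default 100).
#' @param hidden hidden-layer width (default 512, rectifier activation).
#' @param seed integer seed for initialization.
#' @return object of class `feature_generator` (an `mlp` with a tanh head).
#' @export
generator_new <- function(out_dim, noise_dim = 100L, hidden = 512L, seed = 1L) {
  net <- mlp_new(c(noise_dim, hidden, out_dim), out_activation = "tanh",
                 seed = seed)
  net$noise_dim <- as.integer(noise_dim)
  class(net) <- c("feature_generator", "mlp")
  net
}

#' Sample synthetic feature rows from the generator
#'
#' @param gen a [generator_new()] generator (trained or not).
#' @param n number of rows.
#' @param seed integer seed for the noise draw.
#' @return n x out_dim matrix with entries strictly inside (-1, 1).
#' @export
gan_generate <- function(gen, n, seed = 1L) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * gen$noise_dim), n, gen$noise_dim)
  out <- mlp_forward(gen, Z)$out
  # tanh rounds to +/-1 in floating point once saturated; keep the open
  # interval contract of the sampling op
  pmin(pmax(out, -1 + 1e-12), 1 - 1e-12)
}

#' Per-feature range normalizer
#'
#' Fits per-feature min/max on the training split and maps linearly to
#' [-1, 1] (the generator's tanh range); out-of-range values are clipped
#' before mapping. Degenerate features (min = max) map to 0 with a warning.
#'
#' @param X training-split feature matrix.
#' @return object of class `range_normalizer`.
#' @export
fit_range_normalizer <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  if (any(hi == lo)) warning("degenerate feature range(s); mapping to 0")
  structure(list(lo = lo, hi = hi), class = "range_normalizer")
}

#' @rdname fit_range_normalizer
#' @param rn a fitted `range_normalizer`.
#' @export
range_normalize <- function(X, rn) {
  X <- pmin(pmax(X, rep(rn$lo, each = nrow(X))), rep(rn$hi, each = nrow(X)))
  span <- rn$hi - rn$lo
  out <- sweep(sweep(X, 2, rn$lo), 2, ifelse(span > 0, span, 1), `/`) * 2 - 1
  out[, span == 0] <- 0
  out
}

#' @rdname fit_range_normalizer
#' @export
range_denormalize <- function(X, rn) {
  span <- rn$hi - rn$lo
  out <- sweep(sweep((X + 1) / 2, 2, span, `*`), 2, rn$lo, `+`)
  out[, span == 0] <- rep(rn$lo[span == 0], each = nrow(X))
  out
}

#' Discriminator loss on a mixed real/fake batch
#'
#' Weighted cross-entropy over the concatenation of real rows (labels 1..3)
#' and generated rows (label 4), with class weights recomputed per batch by
#' the inverse-proportion rule (including the fake class).
#'
#' @param probs_real,probs_fake N x 4 probability matrices from the
#'   discriminator.
#' @param labels_real integer labels in 1..3 for the real rows.
#' @return scalar loss.
#' @export
discriminator_loss <- function(probs_real, labels_real, probs_fake) {
  if (nrow(probs_real) + nrow(probs_fake) == 0) stop("empty batch")
  probs <- rbind(probs_real, probs_fake)
  labels <- c(labels_real, rep(4L, nrow(probs_fake)))
  weighted_cross_entropy(probs, labels, class_weights(labels, 4L))
}

#' Generator loss (non-saturating form)
#'
#' `-mean(log(1 - p_fake))` over the generated batch, clipped at 1e-12: the
#' generator is rewarded whenever the discriminator assigns its rows to any
#' of the three real classes. This replaces the saturating
#' `log(1 - D(G(z)))` term to keep gradients alive early in training.
#'
#' @param p_fake probabilities of the fake channel on generated rows.
#' @return scalar loss (0 when the discriminator is fully fooled).
#' @export
generator_loss <- function(p_fake) {
  -mean(log(pmax(1 - p_fake, 1e-12)))
}

#' GAN training configuration
#'
#' @param noise_dim,hidden generator topology.
#' @param d_steps,g_steps discriminator/generator updates per iteration.
#' @param fake_ratio generated rows per real row in a discriminator batch.
#' @return list of class `gan_config`.
#' @export
gan_config <- function(noise_dim = 100L, hidden = 512L, d_steps = 1L,
                       g_steps = 1L, fake_ratio = 1) {
  structure(list(noise_dim = as.integer(noise_dim), hidden = as.integer(hidden),
                 d_steps = as.integer(d_steps), g_steps = as.integer(g_steps),
                 fake_ratio = fake_ratio), class = "gan_config")
}

#' Train the adversarial pair and return the discriminator as classifier
#'
#' The discriminator is a multibranch model with K = 4 channels, warm-started
#' by the usual two-stage training on the real (range-normalized) rows. It is
#' then optimized alternately with the generator: during a discriminator step
#' the generator is frozen and a mixed real/fake batch minimizes the weighted
#' cross-entropy over 4 classes; during a generator step the discriminator is
#' frozen and gradients of the non-saturating loss flow through it into the
#' generator. Early stopping monitors the validation loss of the three real
#' channels.
#'
#' @param X,y training rows (already range-normalized) and labels in 1..3.
#' @param blocks feature block table.
#' @param cfg a [train_config()].
#' @param gcfg a [gan_config()].
#' @param Xval,yval validation split (range-normalized).
#' @param warm_start optionally a pretrained K=4 `multibranch_model` to skip
#'   the supervised warm-up.
#' @return list with `generator`, `discriminator` (multibranch, K = 4) and
#'   `history` (per-epoch discriminator/generator/validation losses).
#' @export
train_gan <- function(X, y, blocks, cfg = train_config(), gcfg = gan_config(),
                      Xval, yval, warm_start = NULL) {
  slices <- block_slices(blocks)
  D <- if (is.null(warm_start))
    fit_multibranch(X, y, blocks, K = 4L, cfg = cfg, Xval = Xval, yval = yval)
  else warm_start
  stopifnot(D$K == 4L)
  gen <- generator_new(ncol(X), noise_dim = gcfg$noise_dim,
                       hidden = gcfg$hidden, seed = cfg$seed + 991L)
  opt_g <- adam_new(gen)
  opts_b <- lapply(D$branches, adam_new)
  opt_f <- adam_new(D$fusion)
  n <- nrow(X)
  set.seed(cfg$seed + 471L)
  # validation monitors the renormalized first-three-channel loss (the
  # quantity that matters at test time), not the 4-channel loss, so a
  # discriminator collapsing onto the fake channel cannot look good
  Wv <- class_weights(yval, 3L)
  val3_loss <- function(Dm) {
    p <- mb_forward(Dm, Xval, slices)$out
    p3 <- p[, 1:3, drop = FALSE]
    weighted_cross_entropy(p3 / pmax(rowSums(p3), 1e-12), yval, Wv)
  }
  # warm-started discriminator is the epoch-0 baseline: if adversarial
  # updates only hurt the real-class validation loss, it is restored
  vl0 <- val3_loss(D)
  best <- list(D = D, gen = gen, loss = vl0, epoch = 0L)
  val_losses <- vl0
  history <- data.frame(epoch = integer(0), d_loss = numeric(0),
                        g_loss = numeric(0), val_loss = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    d_tot <- 0; g_tot <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      n_fake <- max(1L, round(length(idx) * gcfg$fake_ratio))
      for (s in seq_len(gcfg$d_steps)) {
        Zf <- matrix(stats::rnorm(n_fake * gen$noise_dim), n_fake)
        Xf <- mlp_forward(gen, Zf)$out
        Xb <- rbind(X[idx, , drop = FALSE], Xf)
        yb <- c(y[idx], rep(4L, n_fake))
        Wb <- class_weights(yb, 4L)
        fw <- mb_forward(D, Xb, slices, dropout = cfg$dropout)
        dZ <- (fw$out - one_hot(yb, 4L)) * (Wb[yb] / length(yb))
        gf <- mlp_backward(D$fusion, fw$fusion_fw, dZ)
        st <- adam_step(D$fusion, gf, opt_f, cfg$lr)
        D$fusion <- st$net; opt_f <- st$opt
        for (b in seq_along(D$branches)) {
          cols <- (b - 1L) * 50L + 1:50
          bf <- fw$branch_fws[[b]]
          dZb <- relu_bwd(gf$dX[, cols, drop = FALSE], bf$Z[[length(bf$Z)]])
          gb <- mlp_backward(D$branches[[b]], bf, dZb)
          stb <- adam_step(D$branches[[b]], gb, opts_b[[b]], cfg$lr)
          D$branches[[b]] <- stb$net; opts_b[[b]] <- stb$opt
        }
        d_tot <- d_tot + weighted_cross_entropy(fw$out, yb, Wb)
      }
      for (s in seq_len(gcfg$g_steps)) {
        Zg <- matrix(stats::rnorm(length(idx) * gen$noise_dim), length(idx))
        gfw <- mlp_forward(gen, Zg)
        # discriminator frozen, no dropout: clean gradient for the generator
        dfw <- mb_forward(D, gfw$out, slices)
        P <- dfw$out
        m <- nrow(P)
        g_tot <- g_tot + generator_loss(P[, 4L])
        # dL/dz_k = dL/dp4 * p4 * (delta_4k - p_k), softmax jacobian of
        # -mean log(1 - p4)
        dP4 <- 1 / pmax(1 - P[, 4L], 1e-12) / m
        dZd <- (dP4 * P[, 4L]) * (one_hot(rep(4L, m), 4L) - P)
        gdisc_f <- mlp_backward(D$fusion, dfw$fusion_fw, dZd)
        dX_gen <- matrix(0, m, ncol(X))
        for (b in seq_along(D$branches)) {
          cols <- (b - 1L) * 50L + 1:50
          bf <- dfw$branch_fws[[b]]
          dZb <- relu_bwd(gdisc_f$dX[, cols, drop = FALSE], bf$Z[[length(bf$Z)]])
          dX_gen[, slices[[b]]] <- mlp_backward(D$branches[[b]], bf, dZb)$dX
        }
        dZg <- dX_gen * (1 - gfw$out^2)      # through the tanh head
        gg <- mlp_backward(gen, gfw, dZg)
        stg <- adam_step(gen, gg, opt_g, cfg$lr)
        gen$W <- stg$net$W; gen$b <- stg$net$b; opt_g <- stg$opt
      }
      nb <- nb + 1
    }
    vl <- val3_loss(D)
    if (!is.finite(vl)) stop("non-finite GAN loss; aborting at last checkpoint")
    val_losses <- c(val_losses, vl)
    history <- rbind(history, data.frame(epoch = epoch, d_loss = d_tot / nb,
                                         g_loss = g_tot / nb, val_loss = vl))
    if (vl < best$loss) best <- list(D = D, gen = gen, loss = vl, epoch = epoch)
    es <- early_stopping_controller(val_losses, cfg$patience)
    if ((epoch + 1L) - es$best_epoch >= cfg$patience) break  # epoch 0 = index 1
  }
  list(generator = best$gen, discriminator = best$D, history = history)
}

#' Three-class prediction from a four-channel discriminator
#'
#' Only the three real-class channels are used at test time; their
#' probabilities are renormalized (softmax over the three real logits, which
#' equals dividing by their sum).
#'
#' @param D a K = 4 `multibranch_model`.
#' @param X feature matrix on the discriminator's input scale.
#' @param blocks block table.
#' @return list with `probs` (N x 3) and `labels`.
#' @export
discriminator_predict3 <- function(D, X, blocks = NULL) {
  if (inherits(X, "feature_table")) { blocks <- X$blocks; X <- X$X }
  if (is.null(blocks)) {
    dims <- D$block_dims
    blocks <- data.frame(start = cumsum(c(1L, dims[-length(dims)])),
                         end = cumsum(dims))
  }
  fw <- mb_forward(D, X, block_slices(blocks))
  z <- fw$fusion_fw$Z[[length(fw$fusion_fw$Z)]]
  # softmax over the three real-class logits: identical to renormalizing
  # the probabilities but immune to underflow when the fake channel wins
  p3 <- softmax_rows(z[, 1:3, drop = FALSE])
  list(probs = p3, labels = max.col(p3, ties.method = "first"))
}
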