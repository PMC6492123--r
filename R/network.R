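# 3D (2D + time) residual U-Net for deep artifact suppression, with its own
# conv3d/maxpool/transposed-conv kernels (src/conv3d.cpp) and backpropagation.
# All kernels are isotropic 3x3x3 (no spatial/temporal direction favoured),
# every convolution is followed by a ReLU except the final residual-producing
# layer, and the network output is ReLU(input + residual) so results are
# non-negative by construction.

#' Network and training configuration
#'
#' @param n_scales Number of multilevel decompositions (>= 1).
#' @param base_channels Channels at the finest scale.
#' @param channel_growth Channel multiplier per scale.
#' @param loss `"l2"` (mean squared error) or `"l1"` (mean absolute error).
#' @param lr Initial ADAM step size.
#' @param batch Samples per optimization step.
#' @param epochs Training passes over the data. The full-scale regime is 350
#'   epochs with batches of 8; the desk-scale benchmark profile
#'   ([desk_profile()]) uses far fewer.
#' @param beta1,beta2,eps ADAM moment parameters.
#' @param final_zero_init Zero-initialize the last (residual) layer so the
#'   untrained network is the identity on non-negative inputs.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(n_scales = 3L, base_channels = 32L, channel_growth = 2L,
                       loss = c("l2", "l1"), lr = 1e-3, batch = 8L,
                       epochs = 350L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       final_zero_init = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  n_scales <- as.integer(n_scales)
  stopifnot(n_scales >= 1L, base_channels >= 1, channel_growth >= 1,
            lr > 0, batch >= 1, epochs >= 1)
  structure(list(n_scales = n_scales, base_channels = as.integer(base_channels),
                 channel_growth = channel_growth, loss = loss, lr = lr,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 final_zero_init = isTRUE(final_zero_init),
                 seed = as.integer(seed)),
            class = "net_config")
}

net_channels <- function(cfg) {
  as.integer(round(cfg$base_channels * cfg$channel_growth^(seq_len(cfg$n_scales) - 1)))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build a residual U-Net
#'
#' Encoder: per scale, two 3x3x3 convolutions with ReLU, then 2x2x2 max
#' pooling down to the next scale. Decoder: 2x2x2 transposed convolution up,
#' concatenation with the same-scale encoder output (skip connection), then
#' two 3x3x3 convolutions with ReLU. A final 1-channel convolution produces
#' the residual; the model output is `ReLU(input + residual)`. Weights use He
#' initialization; the final layer starts at zero by default (identity
#' mapping on non-negative inputs).
#'
#' @param cfg A [net_config()].
#' @return An object of class `resunet` (weights plus config).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(cfg$seed)
  ch <- net_channels(cfg)
  S <- cfg$n_scales
  p <- list()
  for (s in seq_len(S)) {
    cin <- if (s == 1) 1L else ch[s - 1]
    p[[sprintf("enc%d.conv1.W", s)]] <- he_init(c(3, 3, 3, cin, ch[s]), 27 * cin)
    p[[sprintf("enc%d.conv1.b", s)]] <- numeric(ch[s])
    p[[sprintf("enc%d.conv2.W", s)]] <- he_init(c(3, 3, 3, ch[s], ch[s]), 27 * ch[s])
    p[[sprintf("enc%d.conv2.b", s)]] <- numeric(ch[s])
  }
  if (S > 1) for (s in seq_len(S - 1)) {
    p[[sprintf("dec%d.up.W", s)]] <- he_init(c(2, 2, 2, ch[s + 1], ch[s]), 8 * ch[s + 1])
    p[[sprintf("dec%d.up.b", s)]] <- numeric(ch[s])
    p[[sprintf("dec%d.conv1.W", s)]] <- he_init(c(3, 3, 3, 2 * ch[s], ch[s]), 27 * 2 * ch[s])
    p[[sprintf("dec%d.conv1.b", s)]] <- numeric(ch[s])
    p[[sprintf("dec%d.conv2.W", s)]] <- he_init(c(3, 3, 3, ch[s], ch[s]), 27 * ch[s])
    p[[sprintf("dec%d.conv2.b", s)]] <- numeric(ch[s])
  }
  p[["final.W"]] <- if (cfg$final_zero_init) array(0, c(3, 3, 3, ch[1], 1)) else
    he_init(c(3, 3, 3, ch[1], 1), 27 * ch[1])
  p[["final.b"]] <- numeric(1)
  structure(list(cfg = cfg, params = p), class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("Residual U-Net: %d scales, channels %s, %d parameters (loss %s)\n",
              x$cfg$n_scales, paste(net_channels(x$cfg), collapse = "/"),
              np, x$cfg$loss))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

check_net_dims <- function(d, S) {
  div <- 2^(S - 1)
  if (any(d[1:3] %% div != 0))
    stop(sprintf("input dims (%s) must be divisible by 2^(n_scales-1) = %d",
                 paste(d[1:3], collapse = ", "), div))
}

dims3 <- function(a) as.integer(dim(a)[1:3])
nchan <- function(a) as.integer(dim(a)[4])

conv_relu <- function(a, p, nm) {
  W <- p[[paste0(nm, ".W")]]
  pre <- conv3d_fw(a, W, p[[paste0(nm, ".b")]], dims3(a), dim(W)[4], dim(W)[5])
  list(pre = pre, act = relu(pre))
}

# forward pass; keep_cache = TRUE retains activations for backprop
net_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg; S <- cfg$n_scales; p <- model$params
  d <- dim(x)
  stopifnot(length(d) == 3)
  check_net_dims(d, S)
  x4 <- array(x, c(d, 1L))
  cache <- list(x4 = x4, enc = vector("list", S), pool = vector("list", S),
                dec = vector("list", max(S - 1, 0)))
  a <- x4
  for (s in seq_len(S)) {
    c1 <- conv_relu(a, p, sprintf("enc%d.conv1", s))
    c2 <- conv_relu(c1$act, p, sprintf("enc%d.conv2", s))
    cache$enc[[s]] <- list(input = a, pre1 = c1$pre, h1 = c1$act,
                           pre2 = c2$pre, h2 = c2$act)
    if (s < S) {
      pl <- maxpool3d_fw(c2$act, dims3(c2$act), nchan(c2$act))
      cache$pool[[s]] <- pl$arg
      a <- pl$y
    }
  }
  dcur <- cache$enc[[S]]$h2
  if (S > 1) for (s in (S - 1):1) {
    Wu <- p[[sprintf("dec%d.up.W", s)]]
    u <- upconv3d_fw(dcur, Wu, p[[sprintf("dec%d.up.b", s)]],
                     dims3(dcur), dim(Wu)[4], dim(Wu)[5])
    skip <- cache$enc[[s]]$h2
    cat4 <- array(c(u, skip), c(dims3(u), nchan(u) + nchan(skip)))
    c1 <- conv_relu(cat4, p, sprintf("dec%d.conv1", s))
    c2 <- conv_relu(c1$act, p, sprintf("dec%d.conv2", s))
    cache$dec[[s]] <- list(up_in = dcur, u = u, cat = cat4, pre1 = c1$pre,
                           h1 = c1$act, pre2 = c2$pre, h2 = c2$act)
    dcur <- c2$act
  }
  Wf <- p[["final.W"]]
  res <- conv3d_fw(dcur, Wf, p[["final.b"]], dims3(dcur), dim(Wf)[4], 1L)
  pre_out <- x4 + res
  out <- relu(pre_out)
  cache$head_in <- dcur
  cache$pre_out <- pre_out
  r <- array(out, d)
  if (keep_cache) list(out = r, cache = cache) else list(out = r)
}

conv_bw <- function(input, p, nm, g) {
  W <- p[[paste0(nm, ".W")]]
  conv3d_bw(input, W, g, dims3(input), dim(W)[4], dim(W)[5])
}

# backprop of dL/d(out) through the network; returns named gradient list
net_backward <- function(model, cache, gout) {
  cfg <- model$cfg; S <- cfg$n_scales; p <- model$params
  gr <- list()
  g <- array(gout, dim(cache$pre_out)) * (cache$pre_out > 0)
  bwf <- conv_bw(cache$head_in, p, "final", g)
  gr[["final.W"]] <- bwf$gw; gr[["final.b"]] <- bwf$gb
  gcur <- bwf$gx
  gskip <- vector("list", S)
  if (S > 1) for (s in seq_len(S - 1)) {   # decoders, finest first
    dc <- cache$dec[[s]]
    g2 <- gcur * (dc$pre2 > 0)
    bw2 <- conv_bw(dc$h1, p, sprintf("dec%d.conv2", s), g2)
    gr[[sprintf("dec%d.conv2.W", s)]] <- bw2$gw
    gr[[sprintf("dec%d.conv2.b", s)]] <- bw2$gb
    g1 <- bw2$gx * (dc$pre1 > 0)
    bw1 <- conv_bw(dc$cat, p, sprintf("dec%d.conv1", s), g1)
    gr[[sprintf("dec%d.conv1.W", s)]] <- bw1$gw
    gr[[sprintf("dec%d.conv1.b", s)]] <- bw1$gb
    cu <- nchan(dc$u)
    gcat <- bw1$gx
    gu <- gcat[, , , seq_len(cu), drop = FALSE]
    gskip[[s]] <- gcat[, , , cu + seq_len(dim(gcat)[4] - cu), drop = FALSE]
    Wu <- p[[sprintf("dec%d.up.W", s)]]
    bwu <- upconv3d_bw(dc$up_in, Wu, gu, dims3(dc$up_in), dim(Wu)[4], dim(Wu)[5])
    gr[[sprintf("dec%d.up.W", s)]] <- bwu$gw
    gr[[sprintf("dec%d.up.b", s)]] <- bwu$gb
    gcur <- bwu$gx
  }
  # encoders, deepest first; gcur currently holds grad at enc S output
  gh2 <- gcur
  for (s in S:1) {
    if (s < S) gh2 <- gh2 + gskip[[s]]
    en <- cache$enc[[s]]
    g2 <- gh2 * (en$pre2 > 0)
    bw2 <- conv_bw(en$h1, p, sprintf("enc%d.conv2", s), g2)
    gr[[sprintf("enc%d.conv2.W", s)]] <- bw2$gw
    gr[[sprintf("enc%d.conv2.b", s)]] <- bw2$gb
    g1 <- bw2$gx * (en$pre1 > 0)
    bw1 <- conv_bw(en$input, p, sprintf("enc%d.conv1", s), g1)
    gr[[sprintf("enc%d.conv1.W", s)]] <- bw1$gw
    gr[[sprintf("enc%d.conv1.b", s)]] <- bw1$gb
    if (s > 1) {
      en_prev <- cache$enc[[s - 1]]
      gh2 <- maxpool3d_bw(bw1$gx, cache$pool[[s - 1]],
                          dims3(en_prev$h2), nchan(en_prev$h2))
    }
  }
  gr
}

loss_and_grad <- function(out, truth, loss) {
  n <- length(out)
  diffv <- out - truth
  if (loss == "l2") {
    list(loss = mean(diffv^2), g = 2 * diffv / n)
  } else {
    list(loss = mean(abs(diffv)), g = sign(diffv) / n)
  }
}

as_pair_arrays <- function(pair) {
  g <- function(x) if (inherits(x, "cine_volume")) x$data else x
  list(aliased = g(pair$aliased), truth = g(pair$truth))
}

#' Train a residual U-Net on paired (aliased, truth) volumes
#'
#' Minimizes the l2 loss (or l1 when configured) between the network output
#' and the ground truth with ADAM. Deterministic given the config seed (single
#' threaded; batch order reshuffled per epoch from the same stream).
#'
#' @param model A [build_network()] model.
#' @param pairs List of pairs; each element has `aliased` and `truth`
#'   components ([cine_volume] or plain arrays of identical shape, intensities
#'   in [0, 1]). `make_dataset()$pairs` works directly.
#' @param cfg Optional [net_config()] overriding the model's training
#'   hyperparameters (loss, lr, batch, epochs, seed).
#' @param verbose Print per-epoch loss.
#' @return An object of class `trained_model`: the fitted weights, a per-epoch
#'   loss history and a manifest (data checksum, seed, epochs) identifying the
#'   run.
#' @export
train <- function(model, pairs, cfg = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "resunet"))
  if (is.null(cfg)) cfg <- model$cfg
  if (length(pairs) == 0) stop("empty training set")
  arrs <- lapply(pairs, as_pair_arrays)
  d0 <- dim(arrs[[1]]$aliased)
  for (a in arrs) {
    if (!identical(dim(a$aliased), d0) || !identical(dim(a$truth), d0))
      stop("all pairs must share one shape")
  }
  check_net_dims(d0, cfg$n_scales)
  p <- model$params
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  step <- 0
  history <- numeric(cfg$epochs)
  set.seed(cfg$seed)
  n <- length(arrs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    bstarts <- seq(1, n, by = cfg$batch)
    for (b0 in bstarts) {
      bidx <- ord[b0:min(b0 + cfg$batch - 1, n)]
      gacc <- NULL
      for (i in bidx) {
        fw <- net_forward(model, arrs[[i]]$aliased, keep_cache = TRUE)
        lg <- loss_and_grad(fw$out, arrs[[i]]$truth, cfg$loss)
        ep_loss <- ep_loss + lg$loss
        gr <- net_backward(model, fw$cache, lg$g)
        gacc <- if (is.null(gacc)) gr else
          stats::setNames(lapply(names(gr), function(nm) gacc[[nm]] + gr[[nm]]),
                          names(gr))
      }
      nb <- length(bidx)
      step <- step + 1
      for (nm in names(p)) {
        g <- gacc[[nm]] / nb
        m[[nm]] <- cfg$beta1 * m[[nm]] + (1 - cfg$beta1) * g
        v[[nm]] <- cfg$beta2 * v[[nm]] + (1 - cfg$beta2) * g^2
        mhat <- m[[nm]] / (1 - cfg$beta1^step)
        vhat <- v[[nm]] / (1 - cfg$beta2^step)
        p[[nm]] <- p[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
      }
      model$params <- p
    }
    history[ep] <- ep_loss / n
    if (verbose)
      message(sprintf("epoch %3d/%d  %s loss %.6f", ep, cfg$epochs, cfg$loss,
                      history[ep]))
  }
  checksum <- sum(vapply(arrs, function(a) sum(a$aliased) + sum(a$truth), 0))
  structure(list(model = model, cfg = cfg,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      loss = history),
                 manifest = list(n_pairs = n, shape = d0,
                                 data_checksum = signif(checksum, 12),
                                 seed = cfg$seed, epochs = cfg$epochs,
                                 loss = cfg$loss,
                                 final_loss = history[cfg$epochs])),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("Trained residual U-Net: %d pairs, %d epochs, final %s loss %.5f\n",
              x$manifest$n_pairs, x$manifest$epochs, x$manifest$loss,
              x$manifest$final_loss))
  invisible(x)
}

#' Suppress aliasing artifacts with a trained network
#'
#' Single deterministic forward pass; output is the same shape as the input
#' and non-negative by construction.
#'
#' @param trained A [train()] result (or a bare `resunet`).
#' @param aliased Prepared aliased volume ([cine_volume] or array), normalized
#'   to [0, 1] with dims divisible by `2^(n_scales - 1)`.
#' @return Same type as `aliased`.
#' @export
suppress <- function(trained, aliased) {
  model <- if (inherits(trained, "trained_model")) trained$model else trained
  stopifnot(inherits(model, "resunet"))
  is_cine <- inherits(aliased, "cine_volume")
  x <- if (is_cine) aliased$data else aliased
  if (length(dim(x)) != 3)
    stop("input must be a 3D (rows, cols, frames) volume")
  out <- net_forward(model, x)$out
  if (is_cine) { aliased$data <- out; aliased } else out
}
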