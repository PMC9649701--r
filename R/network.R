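# A small pure-R convolutional network with hand-written backpropagation:
# a 4-layer toy backbone plus the two heads (classification and block-index
# prediction). Tensors are H x W x C arrays; convolutions are "same" with
# zero padding, computed as sums of shifted-slice matrix products.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L])
  x
}

as_tensor <- function(m, H, W) {
  array(m, dim = c(H, W, ncol(m)))
}

# "Same" convolution with edge-replicate padding (constant inputs stay
# exactly constant, so zero-sum analyses and flat images behave cleanly).
pad_idx <- function(n, p) c(rep(1L, p), seq_len(n), rep(n, p))

conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; Cout <- dim(W)[4L]
  p <- (k - 1L) %/% 2L
  xp <- x[pad_idx(H, p), pad_idx(Wd, p), , drop = FALSE]
  ym <- matrix(rep(b, each = H * Wd), H * Wd, Cout)
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      xs <- xp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), , drop = FALSE]
      wk <- matrix(W[dr, dc, , ], Cin, Cout)
      ym <- ym + as_mat(xs) %*% wk
    }
  }
  list(y = as_tensor(ym, H, Wd), xp = xp)
}

conv_backward <- function(dy, xp, W) {
  k <- dim(W)[1L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  d <- dim(dy); H <- d[1L]; Wd <- d[2L]
  p <- (k - 1L) %/% 2L
  dym <- as_mat(dy)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(xp))
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      xs <- as_mat(xp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), , drop = FALSE])
      dW[dr, dc, , ] <- crossprod(xs, dym)
      wk <- matrix(W[dr, dc, , ], Cin, Cout)
      dxs <- as_tensor(tcrossprod(dym, wk), H, Wd)
      dxp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), ] <-
        dxp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), , drop = FALSE] + dxs
    }
  }
  # fold padded-border gradients back onto the replicated edge pixels
  ir <- pad_idx(H, p); ic <- pad_idx(Wd, p)
  Cin_d <- dim(xp)[3L]
  tmp <- array(0, dim = c(H, Wd + 2L * p, Cin_d))
  for (i in seq_along(ir)) {
    tmp[ir[i], , ] <- tmp[ir[i], , , drop = FALSE] + dxp[i, , , drop = FALSE]
  }
  dx <- array(0, dim = c(H, Wd, Cin_d))
  for (j in seq_along(ic)) {
    dx[, ic[j], ] <- dx[, ic[j], , drop = FALSE] + tmp[, j, , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = colSums(dym))
}

avgpool2_forward <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H - 1L, by = 2L)
  co <- seq(1L, W - 1L, by = 2L)
  (x[ro, co, , drop = FALSE] + x[ro + 1L, co, , drop = FALSE] +
     x[ro, co + 1L, , drop = FALSE] + x[ro + 1L, co + 1L, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dy) {
  d <- dim(dy)
  dx <- array(0, dim = c(2L * d[1L], 2L * d[2L], d[3L]))
  ro <- seq(1L, 2L * d[1L] - 1L, by = 2L)
  co <- seq(1L, 2L * d[2L] - 1L, by = 2L)
  q <- dy / 4
  dx[ro, co, ] <- q; dx[ro + 1L, co, ] <- q
  dx[ro, co + 1L, ] <- q; dx[ro + 1L, co + 1L, ] <- q
  dx
}

# Adaptive average pooling onto an N x N grid with floor/ceil cell
# boundaries, as used by the index head.
adaptive_cells <- function(H, N) {
  bounds <- floor(H * (0:N) / N)
  lapply(seq_len(N), function(i) (bounds[i] + 1L):bounds[i + 1L])
}

adaptive_pool_forward <- function(x, N) {
  d <- dim(x)
  rows <- adaptive_cells(d[1L], N)
  cols <- adaptive_cells(d[2L], N)
  out <- array(0, dim = c(N, N, d[3L]))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      cell <- x[rows[[a]], cols[[b]], , drop = FALSE]
      out[a, b, ] <- apply(cell, 3L, mean)
    }
  }
  out
}

adaptive_pool_backward <- function(dy, H, W) {
  N <- dim(dy)[1L]
  rows <- adaptive_cells(H, N)
  cols <- adaptive_cells(W, N)
  dx <- array(0, dim = c(H, W, dim(dy)[3L]))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      nr <- length(rows[[a]]); nc <- length(cols[[b]])
      g <- dy[a, b, ] / (nr * nc)
      dx[rows[[a]], cols[[b]], ] <- dx[rows[[a]], cols[[b]], ] +
        rep(g, each = nr * nc)
    }
  }
  dx
}

# Per-channel spatial standardisation (instance normalisation without a
# learned affine): stabilises activation scale so the pooled features of
# different images stay comparable and gradients are well conditioned.
inorm_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  n <- d[1L] * d[2L]
  xm <- as_mat(x)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colSums(xc^2) / n
  isd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, isd, "*")
  list(y = as_tensor(xhat, d[1L], d[2L]), xhat = xhat, isd = isd)
}

inorm_backward <- function(dy, cache) {
  d <- dim(dy)
  dym <- as_mat(dy)
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * cache$xhat)
  dx <- sweep(dym, 2L, m1) - sweep(cache$xhat, 2L, m2, "*")
  dx <- sweep(dx, 2L, cache$isd, "*")
  as_tensor(dx, d[1L], d[2L])
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

init_conv <- function(k, cin, cout) {
  W <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(W = W, b = numeric(cout))
}

#' Initialise the toy LSI model
#'
#' A 4-layer toy convolutional backbone (3x3 convolutions, per-channel
#' spatial standardisation, ReLU; the first three stages halve resolution by
#' 2x2 average pooling) whose output is a hypercolumn — the pooled stage-2,
#' stage-3, and stage-4 activations concatenated on the final grid — plus the
#' two
#' heads: a classification head (global average pooling, affine map, softmax)
#' and an index head (per-cell linear projection to 2 channels, tanh,
#' adaptive average pooling onto the N x N block grid). Any backbone exposing
#' the same image-to-feature-grid contract can replace the toy one.
#'
#' @param n_classes Number of classes C.
#' @param N Blocks per side served by the index head.
#' @param in_channels Input channels (1 for gray images).
#' @param widths Channel widths of the four backbone stages.
#' @param seed RNG seed for the initial weights.
#' @return An object of class `"lsi_model"` holding the parameter list.
#' @export
init_lsi_model <- function(n_classes, N, in_channels = 1L,
                           widths = c(8L, 16L, 32L, 64L), seed = 1L) {
  par <- with_local_seed(seed, {
    F <- feature_channels(widths)
    list(
      conv1 = init_conv(3L, in_channels, widths[1L]),
      conv2 = init_conv(3L, widths[1L], widths[2L]),
      conv3 = init_conv(3L, widths[2L], widths[3L]),
      conv4 = init_conv(3L, widths[3L], widths[4L]),
      cls = list(W = matrix(stats::rnorm(F * n_classes, sd = sqrt(1 / F)),
                            F, n_classes),
                 b = numeric(n_classes)),
      idx = list(W = matrix(stats::rnorm(F * 2L, sd = sqrt(1 / F)), F, 2L),
                 b = numeric(2L))
    )
  })
  structure(list(par = par, n_classes = as.integer(n_classes),
                 N = as.integer(N), in_channels = as.integer(in_channels),
                 widths = as.integer(widths), seed = as.integer(seed)),
            class = "lsi_model")
}

#' @export
print.lsi_model <- function(x, ...) {
  cat(sprintf(
    "Toy LSI model: 4-layer backbone (widths %s), %d classes, index grid %d x %d\n",
    paste(x$widths, collapse = "-"), x$n_classes, x$N, x$N))
  invisible(x)
}

#' Backbone forward pass
#'
#' @param model An [init_lsi_model()] model.
#' @param image Numeric matrix (or H x W x C array matching `in_channels`).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return List with `feat` (H/8 x W/8 x F feature grid) and, when requested,
#'   `cache`.
#' @export
backbone_forward <- function(model, image, keep_cache = FALSE) {
  x <- if (is.matrix(image)) array(image, dim = c(dim(image), 1L)) else image
  par <- model$par
  cache <- list()
  pooled <- vector("list", 4L)
  for (i in 1:4) {
    cv <- conv_forward(x, par[[i]]$W, par[[i]]$b)
    # stages 1-3 are standardised for conditioning; the last stage is left
    # raw so globally pooled features keep their between-image statistics
    no <- if (i < 4L) inorm_forward(cv$y) else NULL
    pre <- if (i < 4L) no$y else cv$y
    act <- pmax(pre, 0)
    pooled[[i]] <- if (i < 4L) avgpool2_forward(act) else act
    if (keep_cache) {
      cache[[i]] <- list(xp = cv$xp, mask = pre > 0,
                         inorm = if (i < 4L) list(xhat = no$xhat, isd = no$isd))
    }
    x <- pooled[[i]]
  }
  # hypercolumn output: stage-2 (pooled once more), stage-3, and stage-4
  # activations concatenated on the final grid, so the heads see both
  # small-receptive-field content features and deep ones
  skip2 <- avgpool2_forward(pooled[[2L]])
  feat <- array(c(skip2, pooled[[3L]], pooled[[4L]]),
                dim = c(dim(skip2)[1:2],
                        dim(skip2)[3L] + dim(pooled[[3L]])[3L] +
                          dim(pooled[[4L]])[3L]))
  list(feat = feat, cache = if (keep_cache) cache else NULL)
}

backbone_backward <- function(model, dfeat, cache) {
  par <- model$par
  w <- model$widths
  grads <- list()
  c2 <- w[2L]; c3 <- w[3L]; c4 <- w[4L]
  d_skip2 <- dfeat[, , seq_len(c2), drop = FALSE]
  d_a3_direct <- dfeat[, , c2 + seq_len(c3), drop = FALSE]
  dy <- dfeat[, , c2 + c3 + seq_len(c4), drop = FALSE]
  for (i in 4:1) {
    if (i < 4L) dy <- avgpool2_backward(dy)
    dy <- dy * cache[[i]]$mask
    if (i < 4L) dy <- inorm_backward(dy, cache[[i]]$inorm)
    bk <- conv_backward(dy, cache[[i]]$xp, par[[i]]$W)
    grads[[i]] <- list(W = bk$dW, b = bk$db)
    dy <- bk$dx
    if (i == 4L) dy <- dy + d_a3_direct
    if (i == 3L) dy <- dy + avgpool2_backward(d_skip2)
  }
  grads
}

# Number of channels in the hypercolumn feature grid.
feature_channels <- function(widths) sum(widths[2:4])

#' Classification head: feature grid to class distribution
#'
#' Global average pooling followed by an affine map and the normalised
#' exponential, yielding a probability vector over the C classes.
#'
#' @param feature_map H x W x F array.
#' @param W,b Affine parameters (F x C matrix, length-C bias).
#' @return List with `phi` (probabilities) and `cache`.
#' @export
classification_head <- function(feature_map, W, b) {
  gap <- colMeans(as_mat(feature_map))
  logits <- as.numeric(gap %*% W) + b
  list(phi = softmax(logits), cache = list(gap = gap, dim = dim(feature_map)))
}

classification_head_backward <- function(dlogits, cache, W) {
  dW <- outer(cache$gap, dlogits)
  dgap <- as.numeric(W %*% dlogits)
  d <- cache$dim
  dfeat <- array(rep(dgap / (d[1L] * d[2L]), each = d[1L] * d[2L]), dim = d)
  list(dW = dW, db = dlogits, dfeat = dfeat)
}

#' Index prediction head: feature grid to per-block index pairs
#'
#' A learned per-cell linear projection of the feature grid to 2 channels, a
#' tanh saturation into (-1, 1), adaptive average pooling onto the N x N
#' block grid, and axis ordering to per-block (first, second) coordinate
#' pairs. Outputs are on the normalised label scale.
#'
#' @param feature_map H x W x F array with spatial size >= N.
#' @param W,b Projection parameters (F x 2 matrix, length-2 bias).
#' @param N Blocks per side.
#' @return List with `pred` (N x N x 2 array in (-1, 1)) and `cache`.
#' @export
index_head <- function(feature_map, W, b, N) {
  d <- dim(feature_map)
  if (d[1L] < N || d[2L] < N) {
    stop("feature map spatial size must be at least N x N")
  }
  z <- as_mat(feature_map) %*% W
  z <- sweep(z, 2L, b, "+")
  t <- tanh(z)
  tt <- as_tensor(t, d[1L], d[2L])
  pred <- adaptive_pool_forward(tt, N)
  list(pred = pred,
       cache = list(fm = as_mat(feature_map), t = t, dim = d, N = N))
}

index_head_backward <- function(dpred, cache, W) {
  d <- cache$dim
  dt_tensor <- adaptive_pool_backward(dpred, d[1L], d[2L])
  dt <- as_mat(dt_tensor)
  dz <- dt * (1 - cache$t^2)
  dW <- crossprod(cache$fm, dz)
  db <- colSums(dz)
  dfeat <- as_tensor(tcrossprod(dz, W), d[1L], d[2L])
  list(dW = dW, db = db, dfeat = dfeat)
}

# Gradient of the LSFSM loss with respect to the predictions: the unit vector
# toward the label, per block (zero at an exact hit).
lsfsm_grad <- function(pred, label) {
  diff <- pred - label
  dist <- sqrt(diff[, , 1L]^2 + diff[, , 2L]^2)
  scale <- ifelse(dist > 1e-12, 1 / dist, 0)
  diff[, , 1L] <- diff[, , 1L] * scale
  diff[, , 2L] <- diff[, , 2L] * scale
  diff
}

zero_like_grads <- function(par) {
  lapply(par, function(p) lapply(p, function(x) x * 0))
}

add_grads <- function(a, b, scale = 1) {
  for (i in seq_along(a)) {
    for (j in seq_along(a[[i]])) {
      a[[i]][[j]] <- a[[i]][[j]] + scale * b[[i]][[j]]
    }
  }
  a
}

grad_global_norm <- function(grads) {
  s <- 0
  for (g in grads) for (x in g) s <- s + sum(x^2)
  sqrt(s)
}

# Scale all gradients down so their global norm is at most `clip`.
clip_grads <- function(grads, clip) {
  gn <- grad_global_norm(grads)
  if (is.finite(clip) && gn > clip) {
    grads <- lapply(grads, function(g) lapply(g, function(x) x * clip / gn))
  }
  grads
}

# lr may be a single rate or a vector/list of per-group rates (named after
# the parameter groups or positional), as in differential-lr fine-tuning.
sgd_step <- function(par, grads, vel, lr, momentum) {
  for (i in seq_along(par)) {
    rate <- if (length(lr) > 1L) {
      nm <- names(par)[i]
      if (!is.null(nm) && !is.null(names(lr)) && nm %in% names(lr)) {
        lr[[nm]]
      } else {
        lr[[min(i, length(lr))]]
      }
    } else {
      lr
    }
    for (j in seq_along(par[[i]])) {
      vel[[i]][[j]] <- momentum * vel[[i]][[j]] - rate * grads[[i]][[j]]
      par[[i]][[j]] <- par[[i]][[j]] + vel[[i]][[j]]
    }
  }
  list(par = par, vel = vel)
}

# Full forward/backward for one augmented sample. Returns losses and, when
# `backward`, parameter gradients (summed over views). Labels are consumed on
# the normalised scale. `train_backbone = FALSE` freezes the backbone (and
# skips its gradient computation), as in head-only experiments.
sample_pass <- function(model, aset, lambda_sm = 1, backward = TRUE,
                        train_backbone = TRUE) {
  par <- model$par
  N <- aset$N
  Z <- aset$Z
  L_c <- 0; L_sm <- 0
  grads <- if (backward) zero_like_grads(par) else NULL
  for (v in seq_along(aset$images)) {
    bf <- backbone_forward(model, aset$images[[v]],
                           keep_cache = backward && train_backbone)
    feat <- bf$feat
    ch <- classification_head(feat, par$cls$W, par$cls$b)
    ih <- index_head(feat, par$idx$W, par$idx$b, N)
    lab_n <- aset$labels[[v]] / Z
    p_true <- max(ch$phi[aset$class_label], 1e-12)
    L_c <- L_c - log(p_true)
    diff <- ih$pred - lab_n
    L_sm <- L_sm + sum(sqrt(diff[, , 1L]^2 + diff[, , 2L]^2))
    if (backward) {
      dlogits <- ch$phi
      dlogits[aset$class_label] <- dlogits[aset$class_label] - 1
      cb <- classification_head_backward(dlogits, ch$cache, par$cls$W)
      grads$cls$W <- grads$cls$W + cb$dW
      grads$cls$b <- grads$cls$b + cb$db
      ib <- index_head_backward(lambda_sm * lsfsm_grad(ih$pred, lab_n),
                                ih$cache, par$idx$W)
      grads$idx$W <- grads$idx$W + ib$dW
      grads$idx$b <- grads$idx$b + ib$db
      if (train_backbone) {
        bg <- backbone_backward(model, cb$dfeat + ib$dfeat, bf$cache)
        for (i in 1:4) {
          grads[[i]]$W <- grads[[i]]$W + bg[[i]]$W
          grads[[i]]$b <- grads[[i]]$b + bg[[i]]$b
        }
      }
    }
  }
  list(L_c = L_c, L_sm = L_sm,
       total = total_objective(L_c, L_sm, lambda_sm), grads = grads)
}

#' Predict the class of a plain image
#'
#' Inference uses the unrotated, unshuffled image only; the augmentation is a
#' training-time device.
#'
#' @param model An `"lsi_model"`.
#' @param image Numeric matrix.
#' @return List with `class` (argmax) and `phi` (class probabilities).
#' @export
predict_class <- function(model, image) {
  feat <- backbone_forward(model, image)$feat
  phi <- classification_head(feat, model$par$cls$W, model$par$cls$b)$phi
  list(class = which.max(phi), phi = phi)
}
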