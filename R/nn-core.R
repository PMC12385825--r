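# Internal neural-network engine: stride-1 "same" convolutions (C++ kernels),
# 2x2 max pooling, a Squeeze-and-Excitation block after the last convolution,
# fully connected layers, softmax cross-entropy and Adam. Parameters live in
# flat named lists of numeric arrays; gradients mirror that structure.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Kaiming-uniform fan-in initialisation
init_mat <- function(nout, nin) {
  matrix(stats::runif(nout * nin, -sqrt(6 / nin), sqrt(6 / nin)), nout, nin)
}

# A branch = conv stack + SE + flatten + fc stack. `cfg` fields used here:
# conv_channels (list of per-stage channel vectors), kernel (kh, kw), pool
# (ph, pw), se_reduction, in_channels, fc_nodes, fc_final_linear (TRUE when
# the branch's last fc feeds a softmax directly).
branch_init <- function(cfg) {
  kh <- cfg$kernel[1]; kw <- cfg$kernel[2]
  params <- list()
  cin <- cfg$in_channels
  i <- 0L
  for (stage in cfg$conv_channels) {
    for (ch in stage) {
      i <- i + 1L
      params[[paste0("conv", i, ".W")]] <- init_mat(ch, kh * kw * cin)
      params[[paste0("conv", i, ".b")]] <- numeric(ch)
      cin <- ch
    }
  }
  if (isTRUE(cfg$use_se)) {
    cse <- cin
    cred <- max(1L, cse %/% cfg$se_reduction)
    params[["se.W1"]] <- init_mat(cred, cse)
    params[["se.b1"]] <- numeric(cred)
    params[["se.W2"]] <- init_mat(cse, cred)
    params[["se.b2"]] <- numeric(cse)
  }
  flat <- branch_flat_size(cfg)
  nin <- flat
  for (j in seq_along(cfg$fc_nodes)) {
    params[[paste0("fc", j, ".W")]] <- init_mat(cfg$fc_nodes[j], nin)
    params[[paste0("fc", j, ".b")]] <- numeric(cfg$fc_nodes[j])
    nin <- cfg$fc_nodes[j]
  }
  params
}

branch_spatial_dims <- function(cfg) {
  h <- cfg$input_dim[1]; w <- cfg$input_dim[2]
  dims <- list()
  for (s in seq_along(cfg$conv_channels)) {
    h <- h %/% cfg$pool[1]; w <- w %/% cfg$pool[2]
    if (h < 1 || w < 1) stop("input too small for ", s, " pooling stages")
    dims[[s]] <- c(h, w)
  }
  dims
}

branch_flat_size <- function(cfg) {
  d <- branch_spatial_dims(cfg)[[length(cfg$conv_channels)]]
  ch <- utils::tail(cfg$conv_channels[[length(cfg$conv_channels)]], 1)
  d[1] * d[2] * ch
}

# forward through one branch; x is an H x W x C numeric array
branch_forward <- function(params, cfg, x) {
  kh <- cfg$kernel[1]; kw <- cfg$kernel[2]
  cache <- list(x_dim = dim(x))
  features <- list()
  a <- x
  i <- 0L
  for (s in seq_along(cfg$conv_channels)) {
    for (ch in cfg$conv_channels[[s]]) {
      i <- i + 1L
      z <- .conv2d_fwd(a, params[[paste0("conv", i, ".W")]],
                       params[[paste0("conv", i, ".b")]], kh, kw)
      cache[[paste0("conv", i)]] <- list(input = a, mask = z > 0)
      a <- relu(z)
      features[[paste0("conv", i)]] <- a
    }
    pl <- .maxpool_fwd(a, cfg$pool[1], cfg$pool[2])
    cache[[paste0("pool", s)]] <- list(idx = pl$idx, in_dim = dim(a))
    a <- pl$out
  }
  if (isTRUE(cfg$use_se)) {
    # Squeeze-and-Excitation on the pooled final maps
    hw <- dim(a)[1] * dim(a)[2]
    z_gap <- apply(a, 3, mean)
    h1 <- relu(as.numeric(params$se.W1 %*% z_gap + params$se.b1))
    s_w <- sigmoid(as.numeric(params$se.W2 %*% h1 + params$se.b2))
    a_se <- sweep(a, 3, s_w, `*`)
    cache$se <- list(a_in = a, z_gap = z_gap, h1 = h1, s = s_w, hw = hw)
    features$se_weights <- s_w
    features$se_out <- a_se
  } else {
    a_se <- a
  }

  v <- as.numeric(a_se)
  cache$flat_dim <- dim(a_se)
  for (j in seq_along(cfg$fc_nodes)) {
    z <- as.numeric(params[[paste0("fc", j, ".W")]] %*% v +
                    params[[paste0("fc", j, ".b")]])
    last <- j == length(cfg$fc_nodes)
    act <- if (last && isTRUE(cfg$fc_final_linear)) z else relu(z)
    cache[[paste0("fc", j)]] <- list(input = v, z = z)
    v <- act
    features[[paste0("fc", j)]] <- v
  }
  list(out = v, cache = cache, features = features)
}

branch_backward <- function(params, cfg, cache, dout) {
  grads <- list()
  v_grad <- dout
  for (j in rev(seq_along(cfg$fc_nodes))) {
    cc <- cache[[paste0("fc", j)]]
    last <- j == length(cfg$fc_nodes)
    dz <- if (last && isTRUE(cfg$fc_final_linear)) v_grad
          else v_grad * (cc$z > 0)
    grads[[paste0("fc", j, ".W")]] <- outer(dz, cc$input)
    grads[[paste0("fc", j, ".b")]] <- dz
    v_grad <- as.numeric(crossprod(params[[paste0("fc", j, ".W")]], dz))
  }
  da_se <- array(v_grad, dim = cache$flat_dim)

  if (isTRUE(cfg$use_se)) {
    se <- cache$se
    # d/d(a_in): scale path + GAP path
    ds <- apply(da_se * se$a_in, 3, sum)
    dz2 <- ds * se$s * (1 - se$s)
    grads$se.W2 <- outer(dz2, se$h1)
    grads$se.b2 <- dz2
    dh1 <- as.numeric(crossprod(params$se.W2, dz2)) * (se$h1 > 0)
    grads$se.W1 <- outer(dh1, se$z_gap)
    grads$se.b1 <- dh1
    dgap <- as.numeric(crossprod(params$se.W1, dh1))
    da <- sweep(da_se, 3, se$s, `*`) +
      sweep(array(1, dim = dim(se$a_in)), 3, dgap / se$hw, `*`)
  } else {
    da <- da_se
  }

  i <- sum(lengths(cfg$conv_channels))
  for (s in rev(seq_along(cfg$conv_channels))) {
    pc <- cache[[paste0("pool", s)]]
    da <- .maxpool_bwd(da, pc$idx, pc$in_dim[1], pc$in_dim[2])
    for (ch in rev(cfg$conv_channels[[s]])) {
      cc <- cache[[paste0("conv", i)]]
      dz <- da * cc$mask
      bw <- .conv2d_bwd(cc$input, dz, params[[paste0("conv", i, ".W")]],
                        cfg$kernel[1], cfg$kernel[2])
      grads[[paste0("conv", i, ".W")]] <- bw$dW
      grads[[paste0("conv", i, ".b")]] <- as.numeric(bw$db)
      da <- bw$dx
      i <- i - 1L
    }
  }
  grads
}

# ---- Adam over flat named parameter lists ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, f) lapply(g, function(x) x * f)
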