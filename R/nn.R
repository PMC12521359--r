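# Small neural-network engine backing the convolutional variational
# embedder: a layer stack (conv / width-upsample / width-crop) with manual
# backpropagation over whole minibatches, dense layers, and AdamW.
# Convolutions run through the compiled batched im2col kernels; everything
# else is plain R.

nn_conv <- function(wname, bname, cin, cout, sh = 1L, sw = 1L, act = "relu",
                    kh = 3L, kw = 3L) {
  list(type = "conv", W = wname, b = bname, cin = cin, cout = cout,
       kh = kh, kw = kw, sh = sh, sw = sw, act = act)
}
nn_upsample_w <- function() list(type = "upsample_w")
nn_crop_w <- function(target) list(type = "crop_w", target = target)

nn_init_conv <- function(params, layer, rgen) {
  fan_in <- layer$kh * layer$kw * layer$cin
  params[[layer$W]] <- matrix(rgen(layer$cout * fan_in) * sqrt(2 / fan_in),
                              layer$cout, fan_in)
  params[[layer$b]] <- numeric(layer$cout)
  params
}

# xs: list of H x W x C arrays (one per image in the batch).
# Returns list(out = activated outputs, caches).
stack_forward_batch <- function(xs, layers, params) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      out <- conv2d_forward_batch(xs, params[[l$W]], params[[l$b]], l$kh,
                                  l$kw, l$sh, l$sw, l$act == "relu")
      caches[[li]] <- list(x = xs, a = out)
      xs <- out
    } else if (l$type == "upsample_w") {
      w_in <- dim(xs[[1]])[2]
      caches[[li]] <- w_in
      xs <- lapply(xs, function(x) {
        x[, rep(seq_len(w_in), each = 2), , drop = FALSE]
      })
    } else if (l$type == "crop_w") {
      caches[[li]] <- dim(xs[[1]])
      xs <- lapply(xs, function(x) x[, seq_len(l$target), , drop = FALSE])
    }
  }
  list(out = xs, caches = caches)
}

# das: list of gradients w.r.t. the stack outputs. Accumulates weight/bias
# gradients (summed over the batch) into `grads` (an environment keyed like
# params) and returns the gradients w.r.t. the stack inputs.
stack_backward_batch <- function(das, layers, params, caches, grads) {
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    if (l$type == "conv") {
      cc <- caches[[li]]
      if (l$act == "relu") {
        das <- Map(function(d, a) d * (a > 0), das, cc$a)
      }
      res <- conv2d_backward_batch(cc$x, params[[l$W]], das, l$kh, l$kw,
                                   l$sh, l$sw)
      grads[[l$W]] <- grad_get(grads, l$W) + res$dw
      grads[[l$b]] <- grad_get(grads, l$b) + as.numeric(res$db)
      das <- res$dxs
    } else if (l$type == "upsample_w") {
      w_in <- caches[[li]]
      idx <- seq_len(w_in)
      das <- lapply(das, function(d) {
        d[, 2 * idx - 1, , drop = FALSE] + d[, 2 * idx, , drop = FALSE]
      })
    } else if (l$type == "crop_w") {
      dm <- caches[[li]]
      das <- lapply(das, function(d) {
        full <- array(0, dm)
        full[, seq_len(dim(d)[2]), ] <- d
        full
      })
    }
  }
  das
}

# Single-image convenience wrappers (used by low-level checks).
stack_forward <- function(x, layers, params) {
  fw <- stack_forward_batch(list(x), layers, params)
  list(out = fw$out[[1]], caches = fw$caches)
}

stack_backward <- function(da, layers, params, caches, grads) {
  stack_backward_batch(list(da), layers, params, caches, grads)[[1]]
}

grad_get <- function(env, nm) {
  if (exists(nm, envir = env, inherits = FALSE)) env[[nm]] else 0
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

# AdamW update; weight decay applied only to names in `decay_on`.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_on = character()) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
    if (weight_decay > 0 && nm %in% decay_on) {
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    }
  }
  list(params = params, state = state)
}
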