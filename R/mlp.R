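# Small fully connected conditioner networks (tanh activations) with
# hand-written backpropagation, plus an Adam optimizer.  The final
# layer is zero-initialized so every coupling layer starts as the
# identity transform, making the flow's initial density exactly the
# uniform base distribution.

mlp_init <- function(d_in, d_hidden, d_out, seed) {
  set.seed(seed)
  if (d_in == 0L) {
    # unconditional parameterization (1D flows): bias-only output
    return(list(b3 = rep(0, d_out)))
  }
  xav <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), n_in, n_out)
  }
  list(W1 = xav(d_in, d_hidden), b1 = rep(0, d_hidden),
       W2 = xav(d_hidden, d_hidden), b2 = rep(0, d_hidden),
       W3 = matrix(0, d_hidden, d_out), b3 = rep(0, d_out))
}

mlp_forward <- function(net, X) {
  if (is.null(net$W1)) {
    n <- nrow(X)
    return(list(out = matrix(net$b3, n, length(net$b3), byrow = TRUE),
                cache = list(n = n)))
  }
  n <- nrow(X)
  H1 <- tanh(X %*% net$W1 + rep(net$b1, each = n))
  H2 <- tanh(H1 %*% net$W2 + rep(net$b2, each = n))
  out <- H2 %*% net$W3 + rep(net$b3, each = n)
  list(out = out, cache = list(X = X, H1 = H1, H2 = H2))
}

mlp_backward <- function(net, cache, G_out) {
  if (is.null(net$W1)) {
    return(list(grads = list(b3 = colSums(G_out)),
                G_in = matrix(0, nrow(G_out), 0L)))
  }
  gW3 <- crossprod(cache$H2, G_out)
  gb3 <- colSums(G_out)
  G2 <- tcrossprod(G_out, net$W3) * (1 - cache$H2^2)
  gW2 <- crossprod(cache$H1, G2)
  gb2 <- colSums(G2)
  G1 <- tcrossprod(G2, net$W2) * (1 - cache$H1^2)
  gW1 <- crossprod(cache$X, G1)
  gb1 <- colSums(G1)
  G_in <- tcrossprod(G1, net$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       G_in = G_in)
}

# ---- Adam ----------------------------------------------------------

adam_init <- function(param_list) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(param_list), v = zero_like(param_list), t = 0L)
}

#' One Adam update step over a nested parameter list
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (!is.numeric(p)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
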