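# Monotone rational-quadratic splines on an interval [a, b].
#
# Each spline is a strictly increasing C^1 map [a,b] -> [a,b] built
# from B rational-quadratic bins (Gregory & Delbourgo form, as used in
# neural spline flows).  The knot layout is produced from
# unconstrained conditioner outputs: bin widths and heights through a
# row-wise softmax (with a small minimum bin fraction for numerical
# safety), interior knot derivatives through a shifted softplus so
# that zero raw parameters give the identity map.  Endpoint
# derivatives are fixed to 1, which pins the interval endpoints and
# makes the all-zero parameterization exactly the identity.
#
# All routines operate on "flattened" inputs: M scalar spline
# evaluations at once, each with its own knot table (rows of the
# parameter matrices), because a coupling layer conditions the knots
# on other coordinates sample by sample.

# shift making softplus(0 + .RQ_DSHIFT) == 1
.RQ_DSHIFT <- log(exp(1) - 1)

# Analytic value+gradient generators for the in-bin transform and its
# log-derivative, in the 7 local variables (x, xk, wb, yk, hb, dk,
# dk1): evaluation point, left knot, bin width, left y-knot, bin
# height, and the derivatives at the two bounding knots.  base::deriv
# emits vectorized code for the exact partial derivatives used in
# backpropagation.
.rq_y_fun <- deriv(
  ~ yk + hb * ((hb / wb) * ((x - xk) / wb)^2 +
                 dk * ((x - xk) / wb) * (1 - (x - xk) / wb)) /
    ((hb / wb) + (dk1 + dk - 2 * (hb / wb)) *
       ((x - xk) / wb) * (1 - (x - xk) / wb)),
  c("x", "xk", "wb", "yk", "hb", "dk", "dk1"),
  function.arg = c("x", "xk", "wb", "yk", "hb", "dk", "dk1")
)

.rq_ld_fun <- deriv(
  ~ 2 * log(hb / wb) +
    log(dk1 * ((x - xk) / wb)^2 +
          2 * (hb / wb) * ((x - xk) / wb) * (1 - (x - xk) / wb) +
          dk * (1 - (x - xk) / wb)^2) -
    2 * log((hb / wb) + (dk1 + dk - 2 * (hb / wb)) *
              ((x - xk) / wb) * (1 - (x - xk) / wb)),
  c("x", "xk", "wb", "yk", "hb", "dk", "dk1"),
  function.arg = c("x", "xk", "wb", "yk", "hb", "dk", "dk1")
)

#' Build rational-quadratic spline knot tables from raw parameters
#'
#' @param raw numeric matrix, M x (3B - 1): per row, B unconstrained
#'   bin-width logits, B bin-height logits, and B - 1 interior
#'   derivative parameters.
#' @param n_bins number of bins B (>= 2).
#' @param a,b interval endpoints, b > a.
#' @param min_bin minimum bin width/height as a fraction of the
#'   interval (numerical guard; default 1e-3).
#' @return list with knot tables (`cw`, `ch` cumulative x/y knots,
#'   M x (B+1)), bin sizes (`w`, `h`, M x B), derivatives (`d`,
#'   M x (B+1), endpoints fixed at 1) and caches for backprop.
#' @keywords internal
rq_params <- function(raw, n_bins, a, b, min_bin = 1e-3) {
  B <- n_bins
  stopifnot(ncol(raw) == 3L * B - 1L, b > a)
  L <- b - a
  mw <- min_bin * L
  s <- L - B * mw
  pw <- row_softmax(raw[, 1:B, drop = FALSE])
  ph <- row_softmax(raw[, B + 1:B, drop = FALSE])
  w <- mw + s * pw
  h <- mw + s * ph
  td <- raw[, 2L * B + seq_len(B - 1L), drop = FALSE] + .RQ_DSHIFT
  M <- nrow(raw)
  d <- matrix(1, M, B + 1L)
  d[, 2:B] <- softplus(td)
  cw <- matrix(a, M, B + 1L)
  cw[, 2:(B + 1L)] <- a + row_cumsum(w)
  ch <- matrix(a, M, B + 1L)
  ch[, 2:(B + 1L)] <- a + row_cumsum(h)
  cw[, B + 1L] <- b
  ch[, B + 1L] <- b
  list(B = B, a = a, b = b, scale = s,
       w = w, h = h, d = d, cw = cw, ch = ch,
       pw = pw, ph = ph, td = td)
}

# locate the bin of each x against per-row cumulative knots (columns
# 2..B are the interior knots); x must already be clamped to [a, b]
.rq_bin <- function(x, cknots, B) {
  if (B == 1L) return(rep(1L, length(x)))
  1L + rowSums(x > cknots[, 2:B, drop = FALSE])
}

.rq_gather <- function(P, k) {
  M <- length(k)
  i1 <- cbind(seq_len(M), k)
  i2 <- cbind(seq_len(M), k + 1L)
  list(xk = P$cw[i1], wb = P$w[i1], yk = P$ch[i1], hb = P$h[i1],
       dk = P$d[i1], dk1 = P$d[i2])
}

#' Evaluate the spline (value and log-derivative)
#'
#' @param x numeric vector of M points in `[a, b]`.
#' @param P knot tables from [rq_params()].
#' @return list(y, logd, k): transformed values, log spline
#'   derivative, bin index per point.
#' @keywords internal
rq_forward <- function(x, P) {
  if (any(x < P$a - 1e-9 | x > P$b + 1e-9))
    stop("rq_forward: coordinate outside [a, b]")
  x <- pmin(pmax(x, P$a), P$b)
  k <- .rq_bin(x, P$cw, P$B)
  g <- .rq_gather(P, k)
  xi <- (x - g$xk) / g$wb
  sb <- g$hb / g$wb
  q1 <- xi * (1 - xi)
  den <- sb + (g$dk1 + g$dk - 2 * sb) * q1
  y <- g$yk + g$hb * (sb * xi^2 + g$dk * q1) / den
  logd <- 2 * log(sb) + log(g$dk1 * xi^2 + 2 * sb * q1 + g$dk * (1 - xi)^2) -
    2 * log(den)
  y <- pmin(pmax(y, P$a), P$b)
  list(y = y, logd = logd, k = k)
}

#' Invert the spline analytically (per-bin quadratic solve)
#'
#' @param y numeric vector of M points in `[a, b]`.
#' @param P knot tables from [rq_params()].
#' @return list(x, logd): preimages and the log-derivative of the
#'   *inverse* map (the negated forward log-derivative at `x`).
#' @keywords internal
rq_inverse <- function(y, P) {
  if (any(y < P$a - 1e-9 | y > P$b + 1e-9))
    stop("rq_inverse: coordinate outside [a, b]")
  y <- pmin(pmax(y, P$a), P$b)
  k <- .rq_bin(y, P$ch, P$B)
  g <- .rq_gather(P, k)
  sb <- g$hb / g$wb
  dy <- y - g$yk
  term <- dy * (g$dk1 + g$dk - 2 * sb)
  aa <- g$hb * (sb - g$dk) + term
  bb <- g$hb * g$dk - term
  cc <- -sb * dy
  disc <- pmax(bb^2 - 4 * aa * cc, 0)
  xi <- 2 * cc / (-bb - sqrt(disc))
  xi <- pmin(pmax(xi, 0), 1)
  # one Newton step sharpens the quadratic-solve root to ~1e-12
  q1 <- xi * (1 - xi)
  den <- sb + (g$dk1 + g$dk - 2 * sb) * q1
  yhat <- g$yk + g$hb * (sb * xi^2 + g$dk * q1) / den
  dydxi <- g$wb * sb^2 *
    (g$dk1 * xi^2 + 2 * sb * q1 + g$dk * (1 - xi)^2) / den^2
  xi <- pmin(pmax(xi - (yhat - y) / dydxi, 0), 1)
  x <- g$xk + g$wb * xi
  q1 <- xi * (1 - xi)
  den <- sb + (g$dk1 + g$dk - 2 * sb) * q1
  logd_fwd <- 2 * log(sb) +
    log(g$dk1 * xi^2 + 2 * sb * q1 + g$dk * (1 - xi)^2) - 2 * log(den)
  list(x = x, logd = -logd_fwd)
}

#' Forward evaluation with partial derivatives for backpropagation
#'
#' Returns, in addition to the value and log-derivative, the exact
#' gradients of both with respect to the 7 local bin variables.
#'
#' @inheritParams rq_forward
#' @keywords internal
rq_forward_grad <- function(x, P) {
  x <- pmin(pmax(x, P$a), P$b)
  k <- .rq_bin(x, P$cw, P$B)
  g <- .rq_gather(P, k)
  vy <- .rq_y_fun(x, g$xk, g$wb, g$yk, g$hb, g$dk, g$dk1)
  vl <- .rq_ld_fun(x, g$xk, g$wb, g$yk, g$hb, g$dk, g$dk1)
  list(y = pmin(pmax(as.numeric(vy), P$a), P$b),
       logd = as.numeric(vl),
       k = k,
       gy = attr(vy, "gradient"),
       gl = attr(vl, "gradient"))
}

#' Backpropagate through a batch of spline evaluations
#'
#' @param fw output of [rq_forward_grad()].
#' @param P knot tables from [rq_params()].
#' @param grad_y upstream gradient w.r.t. the spline outputs (length M).
#' @param grad_logd upstream gradient w.r.t. the log-derivatives.
#' @return list(g_x, g_raw): gradient w.r.t. the input points and
#'   w.r.t. the raw (unconstrained) parameter matrix, M x (3B - 1).
#' @keywords internal
rq_backward <- function(fw, P, grad_y, grad_logd) {
  B <- P$B
  M <- length(fw$y)
  k <- fw$k
  # combine upstream gradients over the two heads
  ge <- fw$gy * grad_y + fw$gl * grad_logd # M x 7
  g_x <- ge[, 1L]
  jm <- matrix(seq_len(B), M, B, byrow = TRUE)
  # widths: xk depends on w_j for j < k, wb is w_k
  g_w <- (jm < k) * ge[, 2L] + (jm == k) * ge[, 3L]
  g_h <- (jm < k) * ge[, 4L] + (jm == k) * ge[, 5L]
  # through w = mw + s * softmax(tw)
  g_pw <- P$scale * g_w
  g_tw <- P$pw * (g_pw - rowSums(g_pw * P$pw))
  g_ph <- P$scale * g_h
  g_th <- P$ph * (g_ph - rowSums(g_ph * P$ph))
  # derivatives: endpoints fixed, interior via softplus
  g_d <- matrix(0, M, B + 1L)
  i1 <- cbind(seq_len(M), k)
  i2 <- cbind(seq_len(M), k + 1L)
  g_d[i1] <- g_d[i1] + ge[, 6L]
  g_d[i2] <- g_d[i2] + ge[, 7L]
  g_td <- g_d[, 2:B, drop = FALSE] * sigmoid(P$td)
  g_raw <- matrix(0, M, 3L * B - 1L)
  g_raw[, 1:B] <- g_tw
  g_raw[, B + 1:B] <- g_th
  g_raw[, 2L * B + seq_len(B - 1L)] <- g_td
  list(g_x = g_x, g_raw = g_raw)
}
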