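# Minimal reverse-mode engine for the restoration networks.
#
# Activations are H x W x C double arrays. Each forward pass records a tape of
# primitive ops (conv, leaky-relu, tanh, nearest-neighbour upsample, channel
# concat, inverted dropout); tape_backward replays it in reverse, accumulating
# parameter gradients per named conv layer. Convolutions run through the
# RcppArmadillo im2col kernels; everything stays in double precision, which the
# finite-difference gradient checks rely on.

as_act <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

tape_new <- function(params) {
  e <- new.env(parent = emptyenv())
  e$vals <- list()
  e$ops <- list()
  e$params <- params
  e
}

tp_push <- function(tp, val, op) {
  id <- length(tp$vals) + 1L
  tp$vals[[id]] <- val
  tp$ops[[id]] <- op
  id
}

tp_input <- function(tp, x) tp_push(tp, as_act(x), list(type = "input"))

tp_conv <- function(tp, id, lname) {
  ly <- tp$params[[lname]]
  y <- conv2d_forward(tp$vals[[id]], ly$W, ly$b, ly$k, ly$stride, ly$pad)
  tp_push(tp, y, list(type = "conv", in1 = id, lname = lname))
}

tp_lrelu <- function(tp, id, alpha = 0.2) {
  x <- tp$vals[[id]]
  tp_push(tp, x * ((x > 0) + alpha * (x <= 0)),
          list(type = "lrelu", in1 = id, alpha = alpha))
}

tp_tanh <- function(tp, id) {
  tp_push(tp, tanh(tp$vals[[id]]), list(type = "tanh", in1 = id))
}

tp_up2 <- function(tp, id) {
  x <- tp$vals[[id]]
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  tp_push(tp, y, list(type = "up2", in1 = id))
}

tp_concat <- function(tp, id1, id2) {
  a <- tp$vals[[id1]]; b <- tp$vals[[id2]]
  d <- dim(a)
  y <- array(c(a, b), dim = c(d[1], d[2], d[3] + dim(b)[3]))
  tp_push(tp, y, list(type = "concat", in1 = id1, in2 = id2, c1 = d[3]))
}

tp_dropout <- function(tp, id, p) {
  x <- tp$vals[[id]]
  mask <- array((runif(length(x)) >= p) / (1 - p), dim = dim(x))
  tp_push(tp, x * mask, list(type = "dropout", in1 = id, mask = mask))
}

acc_grad <- function(cur, g) if (is.null(cur)) g else cur + g

tape_backward <- function(tp, out_id, gout) {
  grads <- vector("list", length(tp$vals))
  grads[[out_id]] <- as_act(gout)
  pg <- list()
  for (id in seq.int(out_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    op <- tp$ops[[id]]
    if (op$type == "input") next
    if (op$type == "conv") {
      ly <- tp$params[[op$lname]]
      bk <- conv2d_backward(tp$vals[[op$in1]], ly$W, g, ly$k, ly$stride, ly$pad)
      if (is.null(pg[[op$lname]])) {
        pg[[op$lname]] <- list(W = bk$dW, b = as.numeric(bk$db))
      } else {
        pg[[op$lname]]$W <- pg[[op$lname]]$W + bk$dW
        pg[[op$lname]]$b <- pg[[op$lname]]$b + as.numeric(bk$db)
      }
      grads[[op$in1]] <- acc_grad(grads[[op$in1]], bk$dx)
    } else if (op$type == "lrelu") {
      x <- tp$vals[[op$in1]]
      grads[[op$in1]] <- acc_grad(grads[[op$in1]],
                                  g * ((x > 0) + op$alpha * (x <= 0)))
    } else if (op$type == "tanh") {
      y <- tp$vals[[id]]
      grads[[op$in1]] <- acc_grad(grads[[op$in1]], g * (1 - y^2))
    } else if (op$type == "up2") {
      d <- dim(g)
      h <- d[1] / 2; w <- d[2] / 2
      gin <- g[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
             g[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
             g[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
             g[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
      grads[[op$in1]] <- acc_grad(grads[[op$in1]], gin)
    } else if (op$type == "concat") {
      grads[[op$in1]] <- acc_grad(grads[[op$in1]],
                                  g[, , seq_len(op$c1), drop = FALSE])
      grads[[op$in2]] <- acc_grad(grads[[op$in2]],
                                  g[, , -seq_len(op$c1), drop = FALSE])
    } else if (op$type == "dropout") {
      grads[[op$in1]] <- acc_grad(grads[[op$in1]], g * op$mask)
    } else {
      stop("unknown tape op: ", op$type)
    }
  }
  list(pgrads = pg, grads = grads)
}

# ---- layer construction -----------------------------------------------------

conv_layer <- function(cin, cout, k, stride, pad, init_sd = 0.02) {
  list(W = matrix(rnorm(cout * cin * k * k, 0, init_sd), cout, cin * k * k),
       b = numeric(cout), k = k, stride = stride, pad = pad,
       cin = cin, cout = cout)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
    st$v[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
  }
  st
}

adam_step <- function(params, pg, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(pg)) {
    for (slot in c("W", "b")) {
      g <- pg[[nm]][[slot]]
      st$m[[nm]][[slot]] <- beta1 * st$m[[nm]][[slot]] + (1 - beta1) * g
      st$v[[nm]][[slot]] <- beta2 * st$v[[nm]][[slot]] + (1 - beta2) * g^2
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (st$m[[nm]][[slot]] / bc1) /
        (sqrt(st$v[[nm]][[slot]] / bc2) + eps)
    }
  }
  list(params = params, state = st)
}

# Numerically stable softplus; log(1 + exp(z)).
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

sigmoid <- function(z) 1 / (1 + exp(-z))
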