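# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is a node on a "tape": an environment holding
# the forward value, references to parent nodes, and a pullback closure that
# maps the incoming gradient to per-parent gradients.  Nodes are recorded in
# creation order, which is already a topological order, so the backward sweep
# is a single reverse pass.  Sparse aggregation operators (Matrix::dgCMatrix)
# enter only as constants; their transposes are precomputed by the caller.
#
# The engine is deliberately small: it supports exactly the operations the
# heterogeneous message-passing model and its prediction heads need.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), pullback = NULL,
                    needs_grad = NULL, param_name = NULL) {
  if (is.null(needs_grad)) {
    needs_grad <- !is.null(param_name) ||
      any(vapply(parents, function(p) p$needs_grad, logical(1)))
  }
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$pullback <- pullback
  nd$needs_grad <- needs_grad
  nd$param_name <- param_name
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) {
  ad_node(tape, as.matrix(value), needs_grad = FALSE)
}

ad_param <- function(tape, value, name) {
  ad_node(tape, value, param_name = name, needs_grad = TRUE)
}

ad_value <- function(x) x$value

.acc_grad <- function(nd, g) {
  if (!nd$needs_grad) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar loss node; returns named list of parameter
# gradients (names are the param_name given at ad_param time).
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[tape$n - i + 1L]]
    if (is.null(nd$grad) || !nd$needs_grad) next
    if (!is.null(nd$param_name)) {
      nm <- nd$param_name
      grads[[nm]] <- if (is.null(grads[[nm]])) nd$grad else grads[[nm]] + nd$grad
    }
    if (!is.null(nd$pullback)) {
      pg <- nd$pullback(nd$grad)
      for (k in seq_along(nd$parents)) {
        if (!is.null(pg[[k]])) .acc_grad(nd$parents[[k]], pg[[k]])
      }
    }
  }
  grads
}

## ---- primitive operations ------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, parents = list(a, b), pullback = function(g) {
    list(if (a$needs_grad) g %*% t(bv) else NULL,
         if (b$needs_grad) crossprod(av, g) else NULL)
  })
}

# Fixed sparse operator S (with precomputed transpose tS) times node h.
# tS must be forced here: it is first touched inside the pullback closure,
# and an unforced promise would evaluate in the caller's (mutated) loop
# environment.
ad_spmm <- function(tape, S, tS, h) {
  force(tS)
  ad_node(tape, as.matrix(S %*% h$value), parents = list(h),
          pullback = function(g) list(as.matrix(tS %*% g)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, parents = list(a, b),
          pullback = function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, parents = list(a, b),
          pullback = function(g) list(g, -g))
}

# Add a 1 x d bias row to every row of h.
ad_add_bias <- function(tape, h, b) {
  ad_node(tape, sweep(h$value, 2L, as.numeric(b$value), "+"),
          parents = list(h, b),
          pullback = function(g) list(g, matrix(colSums(g), 1L)))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, parents = list(a),
          pullback = function(g) list(g * s))
}

# Elementwise product with a constant mask (dropout).
ad_mask <- function(tape, a, mask) {
  ad_node(tape, a$value * mask, parents = list(a),
          pullback = function(g) list(g * mask))
}

ad_cbind <- function(tape, ...) {
  ps <- list(...)
  widths <- vapply(ps, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(ps, ad_value)), parents = ps,
          pullback = function(g) {
            lapply(seq_along(ps), function(k) {
              if (ps[[k]]$needs_grad) g[, starts[k]:ends[k], drop = FALSE] else NULL
            })
          })
}

# Row gather h[idx, ]; pullback scatter-adds into the source rows.
ad_rows <- function(tape, h, idx) {
  idx <- as.integer(idx)
  nr <- nrow(h$value)
  ad_node(tape, h$value[idx, , drop = FALSE], parents = list(h),
          pullback = function(g) {
            out <- matrix(0, nr, ncol(g))
            rs <- rowsum(g, group = idx)
            out[as.integer(rownames(rs)), ] <- rs
            list(out)
          })
}

ad_sigmoid <- function(tape, a) {
  s <- stats::plogis(a$value)
  ad_node(tape, s, parents = list(a),
          pullback = function(g) list(g * s * (1 - s)))
}

ad_relu <- function(tape, a) {
  v <- a$value
  ad_node(tape, pmax(v, 0), parents = list(a),
          pullback = function(g) list(g * (v > 0)))
}

ad_tanh <- function(tape, a) {
  tv <- tanh(a$value)
  ad_node(tape, tv, parents = list(a),
          pullback = function(g) list(g * (1 - tv^2)))
}

ad_activate <- function(tape, a, activation) {
  switch(activation,
         identity = a,
         relu = ad_relu(tape, a),
         tanh = ad_tanh(tape, a),
         sigmoid = ad_sigmoid(tape, a),
         stop("unknown activation: ", activation))
}

# Numerically stabilized mean binary cross-entropy with logits.
ad_bce_logits <- function(tape, logits, labels) {
  x <- as.numeric(logits$value)
  y <- as.numeric(labels)
  if (length(x) == 0L) stop("bce loss on an empty batch")
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  li <- pmax(x, 0) - x * y + log1p(exp(-abs(x)))
  n <- length(x)
  ad_node(tape, matrix(mean(li), 1L), parents = list(logits),
          pullback = function(g) {
            list(matrix((stats::plogis(x) - y) / n * as.numeric(g), ncol = 1L))
          })
}

ad_mse <- function(tape, pred, obs) {
  p <- as.numeric(pred$value)
  y <- as.numeric(obs)
  stopifnot(length(p) == length(y), length(p) > 0L)
  n <- length(p)
  ad_node(tape, matrix(mean((p - y)^2), 1L), parents = list(pred),
          pullback = function(g) {
            list(matrix(2 * (p - y) / n * as.numeric(g), ncol = 1L))
          })
}

# Weighted sum of scalar loss nodes.
ad_weighted_sum <- function(tape, nodes, weights) {
  stopifnot(length(nodes) == length(weights))
  v <- sum(vapply(nodes, function(nd) as.numeric(nd$value), numeric(1)) * weights)
  ad_node(tape, matrix(v, 1L), parents = nodes,
          pullback = function(g) {
            lapply(seq_along(nodes), function(k) matrix(weights[k] * as.numeric(g), 1L))
          })
}

## ---- optimizer -----------------------------------------------------------

# Adam with L2 weight decay folded into the gradient (the convention of the
# reference deep-learning stacks when "weight decay" is passed to Adam).
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 1e-6) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
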