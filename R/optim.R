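# Adam optimizer over nested lists ("trees") of numeric arrays, used to train
# every parameter group of the pipeline (CNN kernel, nerve time constants,
# layer weights and neuron parameters, readout head).

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
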