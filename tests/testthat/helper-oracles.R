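# Independent reference implementations used to cross-check the package.

# Binary entropy in bits.
h2 <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  out
}

# Closed-form capacity of a binary-input channel with invertible 2x2
# conditional matrix W (rows sum to 1). At the interior optimum the
# divergences D_s are all equal to C; writing L_r = log2(1/q_r) for the
# optimal output law gives W L = C 1 + h (h = row entropies), and since
# W^{-1} 1 = 1, the normalisation sum(2^-L) = 1 yields
#   C = log2( sum_r 2^{-(W^{-1} h)_r} ).
binary_capacity_closed_form <- function(W) {
  h <- apply(W, 1, function(r) h2(r[1]))
  v <- solve(W, h)
  log2(sum(2^(-v)))
}

# Plain-R Blahut-Arimoto keeping the whole lower-bound trajectory, as an
# independent reference for the compiled solver (and its monotonicity).
ba_reference <- function(W, tol = 1e-12, max_iter = 50000L) {
  ns <- nrow(W)
  p <- rep(1 / ns, ns)
  lower_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    q <- colSums(p * W)
    D <- vapply(seq_len(ns), function(s) {
      w <- W[s, ]
      nz <- w > 0
      sum(w[nz] * log(w[nz] / q[nz]))
    }, numeric(1))
    lower <- sum(p * D)
    upper <- max(D)
    lower_trace <- c(lower_trace, lower / log(2))
    if ((upper - lower) / log(2) < tol) break
    p <- p * exp(D - upper)
    p <- p / sum(p)
  }
  list(capacity_bits = lower / log(2), p = p, lower_trace = lower_trace)
}

# Direct-summation joint MI of a flattened table p(x, y): used to verify
# the chain rule against the package's conditional MI.
mi_direct <- function(joint) {
  pr <- rowSums(joint)
  ps <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0) {
      s <- s + joint[i, j] * log2(joint[i, j] / (pr[i] * ps[j]))
    }
  }
  s
}

# Random conditional probability matrix (rows sum to 1).
random_channel <- function(ns, nr) {
  W <- matrix(rexp(ns * nr), ns, nr)
  W / rowSums(W)
}

# Random 3-way probability array.
random_joint3 <- function(d1, d2, d3) {
  a <- array(rexp(d1 * d2 * d3), dim = c(d1, d2, d3))
  a / sum(a)
}

# Tiny two-condition trace set built in code.
make_traces <- function(n_cells = 3, conditions = c("0", "1"),
                        channels = "YFP", plateau = c(100, 400),
                        n_frames = 64) {
  rows <- list()
  for (ci in seq_along(conditions)) {
    for (cell in seq_len(n_cells)) {
      for (ch in channels) {
        v <- plateau[ci] * (1 - exp(-(1:n_frames) / 8))
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell_id = paste0("c", cell), condition = conditions[ci],
          channel = ch, frame = 1:n_frames, value = v)
      }
    }
  }
  dplyr::bind_rows(rows)
}
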