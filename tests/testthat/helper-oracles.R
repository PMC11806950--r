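# Independent oracles used across the suite.
#
# Information quantities are recomputed here through joint-entropy sums
# (H(a) + H(b) - H(ab) etc.) over table() counts -- a different code path
# from the package's plug-in ratio sums -- and the widest-path search is
# checked against exhaustive enumeration of admissible pair sequences.

# joint entropy of any number of aligned vectors, via pasted cells
o_ent <- function(...) {
  cell <- do.call(paste, c(list(...), sep = "\r"))
  p <- as.numeric(table(cell)) / length(cell)
  -sum(p * log(p))
}

o_mi <- function(x, y) o_ent(x) + o_ent(y) - o_ent(x, y)

o_cmi <- function(x, y, z) o_ent(x, z) + o_ent(y, z) - o_ent(x, y, z) - o_ent(z)

# distribution-space formulas (for exact-count fixtures): p is a full joint
# probability array/vector with matching index helpers
p_mi <- function(p2) {
  # p2: matrix over (a, b)
  pa <- rowSums(p2); pb <- colSums(p2)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (p2[i, j] > 0) s <- s + p2[i, j] * log(p2[i, j] / (pa[i] * pb[j]))
  s
}

p_cmi <- function(p3) {
  # p3: array over (a, b, c); sum_c p(c) I(a;b | c)
  s <- 0
  for (k in seq_len(dim(p3)[3])) {
    m <- p3[, , k]
    pc <- sum(m)
    if (pc == 0) next
    s <- s + pc * p_mi(m / pc)
  }
  s
}

# expand a joint-count specification into aligned observation vectors
counts_to_sample <- function(levels_df, counts) {
  idx <- rep(seq_len(nrow(levels_df)), counts)
  levels_df[idx, , drop = FALSE]
}

# Exact 8-cell fixture: uniform binary a, symmetric flip chain a -> b -> c
# with flip probability eps; n must make every cell count integral.
noisy_chain3 <- function(eps, n) {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  pr <- 0.5 * ifelse(g$a == g$b, 1 - eps, eps) * ifelse(g$b == g$c, 1 - eps, eps)
  cnt <- pr * n
  stopifnot(all(abs(cnt - round(cnt)) < 1e-9))
  list(sample = counts_to_sample(g, round(cnt)),
       p3 = array(pr, c(2, 2, 2)))
}

# Exact 16-cell fixture: y -> a -> b -> c chain of symmetric flips.
noisy_chain4 <- function(eps, n) {
  g <- expand.grid(y = 0:1, a = 0:1, b = 0:1, c = 0:1)
  pr <- 0.5 * ifelse(g$y == g$a, 1 - eps, eps) *
    ifelse(g$a == g$b, 1 - eps, eps) * ifelse(g$b == g$c, 1 - eps, eps)
  cnt <- pr * n
  stopifnot(all(abs(cnt - round(cnt)) < 1e-9))
  list(sample = counts_to_sample(g, round(cnt)), probs = pr, grid = g)
}

# Random anchored tree-shaped table: each feature's parent is the anchor or
# an earlier feature, with a per-edge flip probability.
gen_random_table <- function(m, n, seed, eps_range = c(0.05, 0.45)) {
  set.seed(seed)
  y <- rbinom(n, 1L, 0.5)
  cols <- list(Y = y)
  for (i in seq_len(m)) {
    parent <- cols[[sample.int(length(cols), 1L)]]
    eps <- runif(1, eps_range[1], eps_range[2])
    cols[[sprintf("X%d", i)]] <- (parent + rbinom(n, 1L, eps)) %% 2L
  }
  influence_table(as.data.frame(cols), anchor = "Y")
}

# Exhaustive maxi-min oracle over the ordered-pair graph. Enumerates every
# pair sequence with positive bottleneck (pair repetition excluded, feature
# repetition deliberately allowed -- the DPI gates must rule it out on
# their own) and records, per terminal pair, the best bottleneck score.
oracle_pair_scores <- function(tab, bins = 10) {
  enc <- infotrail:::encode_table(tab, "mle", bins = bins)
  cols <- lapply(enc$codes, identity)
  p <- length(cols)
  y <- enc$anchor
  na <- setdiff(seq_len(p), y)
  m <- length(na)

  MI <- matrix(NA_real_, p, p)
  mi <- function(i, j) {
    if (is.na(MI[i, j])) MI[i, j] <<- MI[j, i] <<- o_mi(cols[[i]], cols[[j]])
    MI[i, j]
  }
  CMI <- new.env(parent = emptyenv())
  cmi <- function(i, j, k) {
    key <- paste(min(i, j), max(i, j), k)
    v <- CMI[[key]]
    if (is.null(v)) {
      v <- o_cmi(cols[[i]], cols[[j]], cols[[k]])
      CMI[[key]] <- v
    }
    v
  }
  iota <- function(a, b, c) {
    if (!(mi(a, b) > mi(a, c))) return(0)
    if (!(mi(y, b) > mi(y, c))) return(0)
    max(mi(a, b) - cmi(a, b, c), 0)
  }

  O <- matrix(0, m, m)
  recurse <- function(a, b, bott, used) {
    for (ci in seq_len(m)) {
      if (ci == a || ci == b) next
      key <- b * (m + 1L) + ci
      if (key %in% used) next
      nb <- min(bott, iota(na[a], na[b], na[ci]))
      if (nb > O[b, ci]) O[b, ci] <<- nb
      if (nb > 0) recurse(b, ci, nb, c(used, key))
    }
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    w0 <- iota(y, na[i], na[j])
    if (w0 > O[i, j]) O[i, j] <- w0
    if (w0 > 0) recurse(i, j, w0, i * (m + 1L) + j)
  }
  dimnames(O) <- list(enc$names[na], enc$names[na])
  O
}

# convenience: searched state on a table
searched_state <- function(tab, estimator = "mle", seed = 1L, ...) {
  st <- init_scores(tab, estimator, ...)
  run_search(st, search_options(seed = seed))
}
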