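# Edge scoring and the bottleneck (maxi-min) Dijkstra search over the graph
# of ordered feature pairs.
#
# A path stub ...(Xa, Xb) extends to (Xb, Xc) over an edge weighted
#   w = max{I(Xa;Xb;Xc), 0} * [I(Xa;Xb) > I(Xa;Xc)] * [I(Y;Xb) > I(Y;Xc)],
# the truncated interaction information gated by two strict data-processing
# inequality conditions (local, and global with respect to the anchor Y).
# Initial pairs use a = Y, where both gates coincide. The search keeps, per
# ordered pair, the best bottleneck score seen so far and the predecessor
# feature, and repeatedly expands the unvisited pair of maximal score --
# Dijkstra's algorithm on the (max, min) semiring.

# local RNG scope: run `expr` under a given seed, restoring the caller's
# generator state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# I(a;b|c) with caching; symmetric in (a,b). Indices into enc columns.
cmi_cached <- function(state, a, b, c) {
  key <- paste(min(a, b), max(a, b), c, sep = ".")
  v <- state$cmi[[key]]
  if (is.null(v)) {
    enc <- state$enc
    v <- cmi_codes(enc$codes[[a]], enc$nlev[[a]],
                   enc$codes[[b]], enc$nlev[[b]],
                   enc$codes[[c]], enc$nlev[[c]])
    state$cmi[[key]] <- v
  }
  v
}

# Edge weight for (Xa,Xb) -> (Xb,Xc), enc-column indices. The interaction
# information is only computed when both strict gates hold (it is multiplied
# by zero otherwise).
edge_weight_idx <- function(state, a, b, c) {
  state$counter$n <- state$counter$n + 1L
  M <- state$M
  y <- state$enc$anchor
  if (!(M[a, b] > M[a, c]) || !(M[y, b] > M[y, c])) return(0)
  max(M[a, b] - cmi_cached(state, a, b, c), 0)
}

#' Edge score of a candidate path extension
#'
#' The weight assigned to extending a path ending \code{(a, b)} by the
#' feature \code{c}, with respect to the anchor \code{y}:
#' \code{max(I(a;b;c), 0)} if both strict DPI gates
#' \code{I(a;b) > I(a;c)} and \code{I(y;b) > I(y;c)} hold, else 0. Ties in
#' mutual information fail the strict inequalities and zero the edge, which
#' conservatively prunes (noiseless deterministic copies score 0).
#'
#' @param y,a,b,c Equal-length features; \code{y} is the anchor. For the
#'   initial step out of the anchor pass \code{a = y}. The three features
#'   \code{a}, \code{b}, \code{c} are meant to be distinct columns of one
#'   table (the table-level entry points enforce that); columns with
#'   identical values are legal and score 0 through the strict gates.
#' @param estimator \code{"mle"} or \code{"kt"}; inputs are prepared as in
#'   \code{\link{estimate_mi}}.
#' @param bins Discretization bins for \code{"mle"} on numeric inputs.
#' @return The edge weight in nats (non-negative).
#' @export
edge_score <- function(y, a, b, c, estimator = c("mle", "kt"), bins = 10L) {
  estimator <- match.arg(estimator)
  feats <- list(y = y, a = a, b = b, c = c)
  prep <- function(x) {
    if (estimator == "kt") kendall_transform(x)
    else if (is.numeric(x) && length(unique(x)) > 2L) discretize(x, bins)
    else x
  }
  feats <- lapply(feats, prep)
  i_ab <- mutual_info(feats$a, feats$b)
  if (!(i_ab > mutual_info(feats$a, feats$c))) return(0)
  if (!(mutual_info(feats$y, feats$b) > mutual_info(feats$y, feats$c))) return(0)
  max(i_ab - cond_mutual_info(feats$a, feats$b, feats$c), 0)
}

#' Search options
#'
#' @param min_score Early-stop threshold in nats: the main loop stops once
#'   the best queued pair scores below it. The default 0 disables it.
#' @param targets Optional character vector of feature names; the search
#'   stops as soon as every target has a visited pair ending at it.
#' @param seed Integer seed used to break score ties at queue extraction;
#'   part of the run configuration, so identical data + seed reproduce the
#'   result exactly.
#' @return A \code{search_options} list.
#' @export
search_options <- function(min_score = 0, targets = NULL, seed = 1L) {
  if (min_score < 0) stop("'min_score' must be non-negative")
  structure(list(min_score = min_score, targets = targets,
                 seed = as.integer(seed)),
            class = "search_options")
}

#' Initialize pair scores from the anchor
#'
#' Scores every ordered pair \code{(Xi, Xj)} of distinct non-anchor features
#' with \code{edge_score(Y, Y, Xi, Xj)}, the weight of the path
#' \code{(Y, Xi, Xj)}. Pairs with positive score are queued with the anchor
#' as predecessor; the rest start unreachable. The \eqn{m^2} evaluations are
#' mutually independent. Pairwise mutual information between all features
#' (anchor included) is precomputed here and reused by the search; the
#' conditional terms needed during relaxation are computed lazily.
#'
#' @param tab An \code{\link{influence_table}}.
#' @param estimator \code{"mle"} or \code{"kt"}.
#' @param bins MLE discretization bins for ordinal columns.
#' @param auto_split Under \code{"kt"}, expand unordered multi-category
#'   features into per-category indicators instead of failing.
#' @return A \code{pair_state} object holding the score matrix \code{S},
#'   predecessor matrix \code{P} (0 = anchor, NA = unreachable), visit
#'   flags and estimation caches.
#' @export
init_scores <- function(tab, estimator = c("mle", "kt"), bins = 10L,
                        auto_split = FALSE) {
  enc <- encode_table(tab, estimator, bins = bins, auto_split = auto_split)
  p <- length(enc$codes)
  y <- enc$anchor
  if (p - 1L < 2L)
    stop("need at least two non-anchor features to search for paths")

  # pairwise MI between all features, anchor included
  M <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    M[i, j] <- M[j, i] <- mi_codes(enc$codes[[i]], enc$nlev[[i]],
                                   enc$codes[[j]], enc$nlev[[j]])
  }

  map <- setdiff(seq_len(p), y)
  m <- length(map)
  state <- list(enc = enc, M = M, map = map,
                features = enc$names[map], anchor = enc$names[y],
                cmi = new.env(parent = emptyenv()),
                counter = new.env(parent = emptyenv()),
                S = matrix(0, m, m), P = matrix(NA_integer_, m, m),
                visited = matrix(FALSE, m, m), queued = matrix(FALSE, m, m),
                pop_trace = numeric(0), searched = FALSE)
  state$counter$n <- 0L
  class(state) <- "pair_state"

  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    w <- edge_weight_idx(state, y, map[i], map[j])
    if (w > 0) {
      state$S[i, j] <- w
      state$P[i, j] <- 0L
      state$queued[i, j] <- TRUE
    }
  }
  state
}

#' @export
print.pair_state <- function(x, ...) {
  cat(sprintf("pair search state: %d features (anchor: %s), %s\n",
              length(x$features), x$anchor,
              if (x$searched) "search complete" else "initialized"))
  cat(sprintf("  %d/%d pairs scored > 0, %d visited, %d edge evaluations\n",
              sum(x$S > 0), length(x$S) - nrow(x$S), sum(x$visited),
              x$counter$n))
  invisible(x)
}

#' Run the bottleneck widest-path search
#'
#' Dijkstra's algorithm on the ordered-pair graph under the (max, min)
#' semiring: repeatedly extract the unvisited queued pair \code{(a, b)} of
#' maximal score (ties broken at random under the option seed), mark it
#' visited, and for every feature \code{c} outside \code{\{a, b\}} with
#' \code{(b, c)} unvisited relax
#' \code{S[b,c] <- max(S[b,c], min(w(a,b,c), S[a,b]))}, recording the
#' predecessor and (re)queuing on improvement. Terminates when the queue
#' empties, when the best queued score drops below \code{min_score}, or when
#' every requested target has a visited pair ending at it. The final
#' \code{S[, j]} maxima are the maxi-min path scores per terminal feature.
#'
#' @param state A \code{pair_state} from \code{\link{init_scores}}.
#' @param opts A \code{\link{search_options}} object.
#' @return The completed \code{pair_state}.
#' @export
run_search <- function(state, opts = search_options()) {
  stopifnot(inherits(state, "pair_state"))
  if (!inherits(opts, "search_options")) stop("'opts' must come from search_options()")
  m <- nrow(state$S)
  tidx <- NULL
  if (!is.null(opts$targets)) {
    tidx <- match(opts$targets, state$features)
    if (anyNA(tidx))
      stop("unknown target feature(s): ",
           paste(opts$targets[is.na(tidx)], collapse = ", "))
  }
  with_seed(opts$seed, {
    repeat {
      open <- which(state$queued & !state$visited)
      if (!length(open)) break
      sc <- state$S[open]
      mx <- max(sc)
      if (mx < opts$min_score) break
      best <- open[sc == mx]
      pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
      a <- (pick - 1L) %% m + 1L
      b <- (pick - 1L) %/% m + 1L
      state$queued[pick] <- FALSE
      state$visited[pick] <- TRUE
      state$pop_trace <- c(state$pop_trace, mx)
      if (!is.null(tidx) &&
          all(vapply(tidx, function(t) any(state$visited[, t]), logical(1))))
        break
      sab <- state$S[pick]
      for (cc in seq_len(m)) {
        if (cc == a || cc == b || state$visited[b, cc]) next
        w <- edge_weight_idx(state, state$map[a], state$map[b], state$map[cc])
        s <- min(w, sab)
        if (s > state$S[b, cc]) {
          state$S[b, cc] <- s
          state$P[b, cc] <- a
          state$queued[b, cc] <- TRUE
        }
      }
    }
  })
  state$searched <- TRUE
  state
}
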