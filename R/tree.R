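# Path reconstruction from the predecessor map, merging into an
# anchor-rooted tree, leaf/relay role assignment, score pruning, and an
# independent audit of the path criteria.

#' Reconstruct the influence path to a terminal feature
#'
#' Picks the ordered pair ending at \code{terminal} with maximal final
#' score and follows the predecessor map back to the anchor. If no pair
#' ending at the terminal has positive score the feature is not influenced
#' and \code{NULL} is returned. Ties between equally scored terminal pairs
#' are broken at random under the current RNG state (seed it, or go through
#' \code{\link{build_tree}} which does).
#'
#' @param state A searched \code{pair_state}.
#' @param terminal Feature name (not the anchor).
#' @return An \code{influence_path} -- list with \code{features} (anchor
#'   first), \code{score} (nats) and \code{terminal} -- or \code{NULL}.
#' @export
reconstruct_path <- function(state, terminal) {
  stopifnot(inherits(state, "pair_state"))
  if (terminal == state$anchor)
    stop("the anchor is the path root; it cannot be a terminal")
  t <- match(terminal, state$features)
  if (is.na(t)) stop("unknown feature: ", terminal)
  col <- state$S[, t]
  col[t] <- -Inf
  mx <- max(col)
  if (!(mx > 0)) return(NULL)
  best <- which(col == mx)
  a <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best

  m <- nrow(state$S)
  rev_feats <- c(t, a)
  cur <- c(a, t)
  repeat {
    prev <- state$P[cur[1], cur[2]]
    if (is.na(prev))
      stop("internal error: predecessor chain broken at (",
           state$features[cur[1]], ", ", state$features[cur[2]], ")")
    if (prev == 0L) break
    rev_feats <- c(rev_feats, prev)
    cur <- c(prev, cur[1])
    if (length(rev_feats) > m)
      stop("internal error: predecessor chain longer than the feature count")
  }
  structure(list(features = c(state$anchor, state$features[rev(rev_feats)]),
                 score = mx, terminal = terminal),
            class = "influence_path")
}

#' @export
print.influence_path <- function(x, ...) {
  cat(sprintf("%s  [%.6g nat]\n", paste(x$features, collapse = " -> "),
              x$score))
  invisible(x)
}

# Assemble the pair-node table from a list of paths. Nodes are identified by
# ordered pairs (and a depth-1 node per first feature), never collapsed by
# feature, so one feature may appear as several nodes (multi-modality).
assemble_nodes <- function(paths, anchor) {
  cols <- c("id", "parent", "depth", "prev_feature", "feature", "score", "role")
  nodes <- list()
  for (p in paths) {
    f <- p$features # anchor first
    L <- length(f)
    sc <- p$score
    id1 <- paste(anchor, f[2], sep = ">")
    if (is.null(nodes[[id1]])) {
      nodes[[id1]] <- list(id = id1, parent = "", depth = 1L,
                           prev_feature = anchor, feature = f[2],
                           score = sc, role = "relay")
    } else {
      nodes[[id1]]$score <- max(nodes[[id1]]$score, sc)
    }
    par <- id1
    for (k in 2:(L - 1)) {
      id <- paste(f[k], f[k + 1], sep = ">")
      is_term <- k == L - 1L
      if (is.null(nodes[[id]])) {
        nodes[[id]] <- list(id = id, parent = par, depth = k,
                            prev_feature = f[k], feature = f[k + 1],
                            score = sc, role = if (is_term) "leaf" else "relay")
      } else {
        # shared prefix of a deeper path: keep the larger bottleneck score
        nodes[[id]]$score <- max(nodes[[id]]$score, sc)
        if (is_term) nodes[[id]]$role <- "leaf"
      }
      par <- id
    }
  }
  if (!length(nodes))
    return(as.data.frame(stats::setNames(
      list(character(0), character(0), integer(0), character(0),
           character(0), numeric(0), character(0)), cols)))
  df <- do.call(rbind, lapply(nodes, function(n)
    data.frame(n, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[order(df$depth, df$id), cols]
}

#' Build the influence tree
#'
#' Reconstructs the best path to every reachable terminal (or to the given
#' targets only), merges shared pair prefixes into one anchor-rooted tree,
#' and classifies features: a feature is a \emph{leaf} if it terminates its
#' own path, a \emph{relay} if it lies in the interior of any path,
#' \emph{both} if both, and \emph{absent} if it is not influenced. A feature
#' may appear as several distinct pair-nodes (one per incoming context),
#' which represents multi-modality and is deliberately not collapsed.
#'
#' @param state A searched \code{pair_state}.
#' @param targets Optional character vector of terminals to reconstruct.
#' @param seed Seed for the tie-break used when several pairs ending at a
#'   terminal share the maximal score.
#' @return An \code{influence_tree}: list with \code{nodes} (data frame:
#'   id, parent, depth, prev_feature, feature, score, role), \code{paths}
#'   (named by terminal), \code{roles} (named over all non-anchor features)
#'   and \code{anchor}.
#' @export
build_tree <- function(state, targets = NULL, seed = 1L) {
  stopifnot(inherits(state, "pair_state"))
  terms <- if (is.null(targets)) state$features else {
    if (!all(targets %in% state$features))
      stop("unknown target feature(s): ",
           paste(setdiff(targets, state$features), collapse = ", "))
    targets
  }
  paths <- with_seed(seed, {
    out <- lapply(terms, function(t) reconstruct_path(state, t))
    names(out) <- terms
    out[!vapply(out, is.null, logical(1))]
  })
  new_tree(paths, state$features, state$anchor)
}

new_tree <- function(paths, features, anchor) {
  roles <- stats::setNames(rep("absent", length(features)), features)
  for (p in paths) {
    inner <- p$features[-c(1, length(p$features))]
    roles[inner] <- ifelse(roles[inner] %in% c("leaf", "both"), "both", "relay")
    t <- p$terminal
    roles[t] <- if (roles[t] %in% c("relay", "both")) "both" else "leaf"
  }
  structure(list(nodes = assemble_nodes(paths, anchor), paths = paths,
                 roles = roles, anchor = anchor),
            class = "influence_tree")
}

#' @export
print.influence_tree <- function(x, ...) {
  cat(sprintf("influence tree (anchor: %s): %d paths, %d pair-nodes\n",
              x$anchor, length(x$paths), nrow(x$nodes)))
  for (p in x$paths) print(p)
  invisible(x)
}

#' Prune an influence tree by path score
#'
#' Drops every path whose maxi-min score falls below \code{min_score}
#' (inclusive rule: a path scoring exactly the threshold is kept) and
#' rebuilds the tree, so relays survive only if they still lie on a kept
#' path. Idempotent, and monotone in the threshold.
#'
#' @param tree An \code{influence_tree}.
#' @param min_score Threshold in nats (non-negative).
#' @return The pruned \code{influence_tree}.
#' @export
prune_tree <- function(tree, min_score) {
  stopifnot(inherits(tree, "influence_tree"))
  if (min_score < 0) stop("'min_score' must be non-negative")
  keep <- vapply(tree$paths, function(p) p$score >= min_score, logical(1))
  new_tree(tree$paths[keep], names(tree$roles), tree$anchor)
}

#' Audit emitted paths against the influence-path criteria
#'
#' Recomputes, independently of the search state, the quantities behind the
#' three defining criteria for every path in a tree: (1) mutual information
#' with the anchor strictly decreases along the path; (2) each local segment
#' satisfies \code{I(P[i-1]; P[i]) > I(P[i-1]; P[i+1])}; (3) the minimal
#' tri-variate interaction information along the path is positive. Also
#' checks that the stored path score equals the recomputed minimum edge
#' score to within \code{1e-12}.
#'
#' @param tree An \code{influence_tree}.
#' @param tab The \code{influence_table} the tree was built from.
#' @param estimator,bins,auto_split Estimation settings, as in
#'   \code{\link{init_scores}}.
#' @return A data frame with one row per path and logical columns
#'   \code{dpi_anchor}, \code{dpi_local}, \code{min_ii_positive},
#'   \code{score_consistent}.
#' @export
audit_paths <- function(tree, tab, estimator = c("mle", "kt"), bins = 10L,
                        auto_split = FALSE) {
  stopifnot(inherits(tree, "influence_tree"))
  enc <- encode_table(tab, estimator, bins = bins, auto_split = auto_split)
  mi2 <- function(i, j) mi_codes(enc$codes[[i]], enc$nlev[[i]],
                                 enc$codes[[j]], enc$nlev[[j]])
  cmi3 <- function(i, j, k) cmi_codes(enc$codes[[i]], enc$nlev[[i]],
                                      enc$codes[[j]], enc$nlev[[j]],
                                      enc$codes[[k]], enc$nlev[[k]])
  rows <- lapply(tree$paths, function(p) {
    idx <- match(p$features, enc$names)
    L <- length(idx)
    miY <- vapply(idx[-1], function(i) mi2(idx[1], i), numeric(1))
    dpi_anchor <- all(diff(miY) < 0)
    dpi_local <- TRUE
    edges <- numeric(0)
    for (k in seq_len(L - 2)) {
      a <- idx[k]; b <- idx[k + 1]; c <- idx[k + 2]
      if (!(mi2(a, b) > mi2(a, c))) dpi_local <- FALSE
      edges <- c(edges, mi2(a, b) - cmi3(a, b, c))
    }
    data.frame(terminal = p$terminal, length = L - 1L, score = p$score,
               dpi_anchor = dpi_anchor, dpi_local = dpi_local,
               min_ii_positive = min(edges) > 0,
               score_consistent = abs(min(edges) - p$score) <= 1e-12,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(terminal = character(0), length = integer(0),
                      score = numeric(0), dpi_anchor = logical(0),
                      dpi_local = logical(0), min_ii_positive = logical(0),
                      score_consistent = logical(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full influence-path analysis of a table
#'
#' Convenience wrapper: initializes pair scores, runs the widest-path
#' search, builds the influence tree and prunes it at \code{min_score}.
#'
#' @param tab An \code{\link{influence_table}}.
#' @param estimator,bins,auto_split As in \code{\link{init_scores}}.
#' @param min_score Score threshold (nats) used both as the search early
#'   stop and the pruning cutoff.
#' @param targets Optional terminals of interest (early-stops the search).
#' @param seed Seed for all tie-breaking.
#' @return An \code{influence_tree}; the completed search state is attached
#'   as attribute \code{state}.
#' @export
trace_influence <- function(tab, estimator = c("mle", "kt"), bins = 10L,
                            min_score = 0, targets = NULL, seed = 1L,
                            auto_split = FALSE) {
  st <- init_scores(tab, estimator, bins = bins, auto_split = auto_split)
  st <- run_search(st, search_options(min_score = min_score,
                                      targets = targets, seed = seed))
  tr <- build_tree(st, targets = targets, seed = seed)
  tr <- prune_tree(tr, min_score)
  attr(tr, "state") <- st
  tr
}
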