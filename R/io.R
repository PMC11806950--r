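# Serialization of influence trees (TSV, JSON, DOT) and the end-to-end
# file-in / files-out pipeline. All numeric scores are serialized at 6
# significant digits so artifacts are byte-stable and diffable.

fmt_score <- function(x) formatC(x, digits = 6, format = "g")

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

tree_to_dot <- function(tree) {
  lines <- c("digraph influence {",
             "  rankdir=LR;",
             sprintf("  %s [label=%s, shape=egg];",
                     dot_quote("@anchor"), dot_quote(tree$anchor)))
  nd <- tree$nodes
  for (i in seq_len(nrow(nd))) {
    shape <- if (nd$role[i] == "leaf") "box" else "ellipse"
    lines <- c(lines, sprintf("  %s [label=%s, shape=%s];",
                              dot_quote(nd$id[i]),
                              dot_quote(nd$feature[i]), shape))
  }
  for (i in seq_len(nrow(nd))) {
    from <- if (identical(nd$parent[i], "")) dot_quote("@anchor")
            else dot_quote(nd$parent[i])
    lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                              from, dot_quote(nd$id[i]),
                              dot_quote(fmt_score(nd$score[i]))))
  }
  c(lines, "}")
}

#' Serialize an influence tree
#'
#' Writes a tree in one of three formats. \code{tsv}: one row per pair-node
#' with columns \code{depth}, \code{prev_feature}, \code{feature},
#' \code{score_nats}, \code{role}. \code{json}: a nested document with the
#' anchor, the node table and the path list. \code{dot}: a Graphviz digraph
#' in which the anchor is egg-shaped, leaves are boxes and relays ellipses;
#' node identifiers are the ordered pairs, so a feature appearing in several
#' contexts keeps one vertex per context. Scores are printed at 6
#' significant digits in every format.
#'
#' @param tree An \code{influence_tree}.
#' @param path Output file path.
#' @param format \code{"tsv"}, \code{"json"} or \code{"dot"}.
#' @return The path, invisibly.
#' @export
write_tree <- function(tree, path, format = c("tsv", "json", "dot")) {
  stopifnot(inherits(tree, "influence_tree"))
  format <- match.arg(format)
  nd <- tree$nodes
  if (format == "tsv") {
    out <- data.frame(depth = nd$depth, prev_feature = nd$prev_feature,
                      feature = nd$feature, score_nats = fmt_score(nd$score),
                      role = nd$role, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    doc <- list(
      anchor = tree$anchor,
      nodes = lapply(seq_len(nrow(nd)), function(i) list(
        id = nd$id[i], parent = nd$parent[i], depth = nd$depth[i],
        prev_feature = nd$prev_feature[i], feature = nd$feature[i],
        score_nats = as.numeric(fmt_score(nd$score[i])), role = nd$role[i])),
      paths = lapply(unname(tree$paths), function(p) list(
        features = p$features, terminal = p$terminal,
        score_nats = as.numeric(fmt_score(p$score)))),
      roles = as.list(tree$roles))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(tree_to_dot(tree), path)
  }
  invisible(path)
}

#' Run the full influence-path pipeline on a file or table
#'
#' Reads the input (unless already an \code{influence_table}), traces the
#' influence tree, prunes it, optionally builds the permutation null, and
#' writes: one tree file per requested format
#' (\code{<out_prefix>_tree.<format>}), a per-length null summary TSV
#' (\code{<out_prefix>_null.tsv}, when \code{permutations > 0}) and a JSON
#' run log (\code{<out_prefix>_log.json}) recording the configuration and
#' runtime counters, including the number of edge-score evaluations.
#' Artifacts contain no timestamps, so identical configuration and seed
#' reproduce them byte-for-byte.
#'
#' @param input Path to a delimited table, or an \code{influence_table}.
#' @param anchor Anchor feature name (ignored if \code{input} is already an
#'   \code{influence_table}).
#' @param estimator,bins,auto_split Estimation settings.
#' @param min_score Score threshold (nats): search early stop and pruning.
#' @param targets Optional terminals of interest.
#' @param permutations Number of permutation-null replicates (0 = skip).
#' @param seed Integer seed for all randomness.
#' @param out_prefix Path prefix for artifacts.
#' @param format Character vector of tree formats to write.
#' @param delim Optional input delimiter override.
#' @param kinds Optional kind overrides for input columns.
#' @return Invisibly, a list with the pruned \code{tree}, the
#'   \code{null_distribution} (or NULL) and the vector of written
#'   \code{files}.
#' @export
run_pipeline <- function(input, anchor = NULL, estimator = c("mle", "kt"),
                         bins = 10L, min_score = 0, targets = NULL,
                         permutations = 0L, seed = 1L, out_prefix,
                         format = "tsv", delim = NULL, kinds = NULL,
                         auto_split = FALSE) {
  estimator <- match.arg(estimator)
  tab <- if (inherits(input, "influence_table")) input
         else read_influence_table(input, anchor, kinds = kinds, delim = delim)
  tr <- trace_influence(tab, estimator, bins = bins, min_score = min_score,
                        targets = targets, seed = seed,
                        auto_split = auto_split)
  st <- attr(tr, "state")
  files <- character(0)
  format <- match.arg(format, c("tsv", "json", "dot"), several.ok = TRUE)
  for (f in format) {
    fp <- paste0(out_prefix, "_tree.", f)
    write_tree(tr, fp, f)
    files <- c(files, fp)
  }
  nd <- NULL
  if (permutations > 0L) {
    nd <- null_distribution(tab, estimator, replicates = permutations,
                            seed = seed, bins = bins, min_score = min_score,
                            auto_split = auto_split)
    np <- paste0(out_prefix, "_null.tsv")
    sm <- summary(nd)
    sm$p50 <- fmt_score(sm$p50); sm$p95 <- fmt_score(sm$p95)
    sm$p99 <- fmt_score(sm$p99); sm$max <- fmt_score(sm$max)
    utils::write.table(sm, np, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, np)
  }
  log <- list(
    input = if (is.character(input)) basename(input) else "<in-memory table>",
    anchor = attr(tab, "anchor"), estimator = estimator, bins = bins,
    min_score = min_score,
    targets = if (is.null(targets)) character(0) else targets,
    permutations = permutations, seed = seed,
    n_observations = nrow(tab), n_features = ncol(tab),
    n_edge_evaluations = st$counter$n,
    n_pairs_visited = sum(st$visited),
    n_paths = length(tr$paths))
  lp <- paste0(out_prefix, "_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, lp)
  invisible(list(tree = tr, null = nd, files = files))
}
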