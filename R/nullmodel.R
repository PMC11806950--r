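# Permutation null model: destroy all dependencies by independently
# shuffling every column (anchor included), re-run the full search, and
# collect the scores of any spurious paths, stratified by path length.

#' Independently permute every feature of a table
#'
#' Shuffles the values of each column -- including the anchor -- with an
#' independent draw from a seeded stream, exactly preserving every marginal
#' while destroying all joint structure.
#'
#' @param tab An \code{\link{influence_table}}.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A permuted \code{influence_table} with the same attributes.
#' @export
permute_table <- function(tab, seed = 1L) {
  stopifnot(inherits(tab, "influence_table"))
  n <- nrow(tab)
  out <- tab
  with_seed(seed, {
    for (nm in names(out)) out[[nm]] <- out[[nm]][sample.int(n)]
  })
  out
}

#' Permutation null distribution of path scores
#'
#' Runs the full pipeline (permute, score, search, reconstruct) on
#' \code{replicates} anchor-destroyed copies of the data and records the
#' score and length of every path detected on them. Replicate seeds are
#' drawn up-front from the master seed (counter style), so the result is
#' identical for a given master seed regardless of evaluation order, and
#' the replicates are independent and safe to parallelize.
#'
#' @param tab An \code{\link{influence_table}}.
#' @param estimator,bins,auto_split As in \code{\link{init_scores}}.
#' @param replicates Number of permuted copies (at least 1).
#' @param seed Master seed.
#' @param min_score Early-stop/pruning threshold applied within each
#'   replicate, as in \code{\link{trace_influence}}.
#' @return A \code{null_distribution}: list with \code{samples} (data frame
#'   of \code{replicate}, \code{length}, \code{score}), \code{yields}
#'   (paths detected per replicate), \code{replicates} and \code{seed}.
#' @export
null_distribution <- function(tab, estimator = c("mle", "kt"),
                              replicates = 100L, seed = 1L, bins = 10L,
                              min_score = 0, auto_split = FALSE) {
  estimator <- match.arg(estimator)
  if (replicates < 1L) stop("'replicates' must be at least 1")
  rep_seeds <- with_seed(seed, sample.int(2147483646L, replicates))
  samples <- vector("list", replicates)
  yields <- integer(replicates)
  for (r in seq_len(replicates)) {
    pt <- permute_table(tab, seed = rep_seeds[r])
    tr <- trace_influence(pt, estimator, bins = bins, min_score = min_score,
                          seed = rep_seeds[r], auto_split = auto_split)
    yields[r] <- length(tr$paths)
    if (length(tr$paths))
      samples[[r]] <- data.frame(
        replicate = r,
        length = vapply(tr$paths, function(p) length(p$features) - 1L, 1L),
        score = vapply(tr$paths, function(p) p$score, 1))
  }
  samples <- samples[!vapply(samples, is.null, logical(1))]
  samples <- if (length(samples))
    do.call(rbind, c(samples, list(make.row.names = FALSE)))
  else
    data.frame(replicate = integer(0), length = integer(0),
               score = numeric(0))
  structure(list(samples = samples, yields = yields,
                 replicates = replicates, seed = seed),
            class = "null_distribution")
}

#' Empirical null percentile
#'
#' Inclusive empirical percentile (type-1 / inverted-CDF quantile) of the
#' null path scores, either within one path-length stratum or pooled over
#' all lengths. \code{q = 100} returns the maximum observed score.
#'
#' @param nd A \code{\link{null_distribution}}.
#' @param q Percentile in \code{[0, 100]}.
#' @param path_length Optional stratum (number of non-anchor features on the
#'   path); \code{NULL} pools all lengths.
#' @return The percentile in nats, or \code{NA} if the stratum is empty.
#' @export
null_percentile <- function(nd, q, path_length = NULL) {
  stopifnot(inherits(nd, "null_distribution"))
  if (q < 0 || q > 100) stop("'q' must be in [0, 100]")
  v <- if (is.null(path_length)) nd$samples$score
       else nd$samples$score[nd$samples$length == path_length]
  if (!length(v)) return(NA_real_)
  stats::quantile(v, q / 100, type = 1, names = FALSE)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("permutation null: %d replicates, %d spurious paths (%.2f per replicate)\n",
              x$replicates, nrow(x$samples), mean(x$yields)))
  invisible(x)
}

#' Per-length summary of a null distribution
#'
#' @param object A \code{\link{null_distribution}}.
#' @param ... Unused.
#' @return A data frame with one row per observed path length plus a pooled
#'   row (\code{path_length = "all"}): sample count, median, 95th, 99th
#'   percentile and maximum score.
#' @export
summary.null_distribution <- function(object, ...) {
  s <- object$samples
  strata <- sort(unique(s$length))
  row <- function(len, v) data.frame(
    path_length = len, n = length(v),
    p50 = stats::quantile(v, 0.50, type = 1, names = FALSE),
    p95 = stats::quantile(v, 0.95, type = 1, names = FALSE),
    p99 = stats::quantile(v, 0.99, type = 1, names = FALSE),
    max = max(v), stringsAsFactors = FALSE)
  rows <- lapply(strata, function(l) row(as.character(l), s$score[s$length == l]))
  if (nrow(s)) rows <- c(rows, list(row("all", s$score)))
  if (!length(rows))
    return(data.frame(path_length = character(0), n = integer(0),
                      p50 = numeric(0), p95 = numeric(0), p99 = numeric(0),
                      max = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
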