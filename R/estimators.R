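# Plug-in information estimators on categorical data, plus the Kendall
# transformation for ordinal inputs. All quantities are in nats.

# Integer-code a vector: factors keep their level order, everything else is
# coded by sorted unique value. Codes are 1..k with no gaps in the domain
# (cells may still be empty).
as_codes <- function(x) {
  if (is.factor(x)) {
    list(codes = as.integer(x), k = nlevels(x))
  } else {
    u <- sort(unique(x))
    list(codes = match(x, u), k = length(u))
  }
}

check_feature <- function(x, arg = "x") {
  if (length(x) == 0L)
    stop(sprintf("'%s' is empty; information estimates need at least one observation", arg))
  if (anyNA(x))
    stop(sprintf("'%s' contains missing values; impute or drop them before estimation", arg))
  invisible(x)
}

check_lengths <- function(...) {
  ns <- vapply(list(...), length, 1L)
  if (length(unique(ns)) != 1L)
    stop("features must have identical length (got ", paste(ns, collapse = ", "), ")")
  invisible(NULL)
}

# --- code-level kernels (no validation, used by the search hot path) ---

ent_codes <- function(c1, k1) {
  p <- tabulate(c1, k1) / length(c1)
  p <- p[p > 0]
  -sum(p * log(p))
}

mi_codes <- function(c1, k1, c2, k2) {
  n <- length(c1)
  pj <- tabulate(c1 + k1 * (c2 - 1L), k1 * k2) / n
  px <- tabulate(c1, k1) / n
  py <- tabulate(c2, k2) / n
  pp <- rep.int(px, k2) * rep(py, each = k1)
  keep <- pj > 0
  max(sum(pj[keep] * log(pj[keep] / pp[keep])), 0)
}

cmi_codes <- function(c1, k1, c2, k2, c3, k3) {
  n <- length(c1)
  j3 <- tabulate(c1 + k1 * ((c2 - 1L) + k2 * (c3 - 1L)), k1 * k2 * k3) / n
  v <- 0
  for (z in seq_len(k3)) {
    m <- matrix(j3[(z - 1L) * k1 * k2 + seq_len(k1 * k2)], k1, k2)
    pz <- sum(m)
    if (pz == 0) next
    px <- rowSums(m)
    py <- colSums(m)
    pp <- outer(px, py) / pz
    keep <- m > 0
    v <- v + sum(m[keep] * log(m[keep] / pp[keep]))
  }
  max(v, 0)
}

# --- user-facing operations ---

#' Plug-in entropy
#'
#' Maximum-likelihood (plug-in) Shannon entropy of a categorical feature,
#' \eqn{-\sum_k \hat p_k \ln \hat p_k} over the observed category
#' frequencies.
#'
#' @param x A vector; factors are used as-is, other vectors are treated as
#'   categorical by distinct value.
#' @return Entropy in nats, between 0 and \code{log} of the number of
#'   distinct observed values.
#' @examples
#' entropy(rep(c("a", "b"), 5)) # log(2)
#' @export
entropy <- function(x) {
  check_feature(x)
  cx <- as_codes(x)
  ent_codes(cx$codes, cx$k)
}

#' Plug-in mutual information
#'
#' Maximum-likelihood mutual information \eqn{I(X;Y)} from the joint
#' contingency table of two equal-length categorical features. Symmetric and
#' non-negative.
#'
#' @param x,y Equal-length vectors, treated as categorical. Ordinal data must
#'   be discretized (see \code{\link{discretize}}) or Kendall-transformed
#'   first; \code{\link{estimate_mi}} automates both.
#' @return Mutual information in nats.
#' @export
mutual_info <- function(x, y) {
  check_feature(x, "x"); check_feature(y, "y")
  check_lengths(x, y)
  cx <- as_codes(x); cy <- as_codes(y)
  mi_codes(cx$codes, cx$k, cy$codes, cy$k)
}

#' Plug-in conditional mutual information
#'
#' Maximum-likelihood \eqn{I(X;Y|Z)} from the three-way contingency table.
#'
#' @param x,y,z Equal-length vectors, treated as categorical.
#' @return Conditional mutual information in nats (non-negative).
#' @export
cond_mutual_info <- function(x, y, z) {
  check_feature(x, "x"); check_feature(y, "y"); check_feature(z, "z")
  check_lengths(x, y, z)
  cx <- as_codes(x); cy <- as_codes(y); cz <- as_codes(z)
  cmi_codes(cx$codes, cx$k, cy$codes, cy$k, cz$codes, cz$k)
}

#' Interaction information of three features
#'
#' Computes \eqn{I(X;Y;Z) = I(X;Y) - I(X;Y|Z)}, the tri-variate
#' generalization of mutual information. Positive values indicate
#' redundancy (typical of chains \eqn{X \to Z \to Y}); negative values
#' indicate synergy (the XOR pattern). The value is invariant under any
#' permutation of the three arguments, although the two reported components
#' are not.
#'
#' @param a,b,c Equal-length vectors, treated as categorical.
#' @return A list with elements \code{i_ab} (\eqn{I(a;b)}),
#'   \code{i_ab_given_c} (\eqn{I(a;b|c)}) and their difference \code{ii}.
#' @export
interaction_info <- function(a, b, c) {
  check_feature(a, "a"); check_feature(b, "b"); check_feature(c, "c")
  check_lengths(a, b, c)
  ca <- as_codes(a); cb <- as_codes(b); cc <- as_codes(c)
  i_ab <- mi_codes(ca$codes, ca$k, cb$codes, cb$k)
  i_ab_c <- cmi_codes(ca$codes, ca$k, cb$codes, cb$k, cc$codes, cc$k)
  list(i_ab = i_ab, i_ab_given_c = i_ab_c, ii = i_ab - i_ab_c)
}

#' Kendall transformation
#'
#' Maps an ordinal (or binary) feature of length \eqn{n} to a categorical
#' feature of length \eqn{n(n-1)}: one token per ordered observation pair
#' \eqn{(i, j)}, \eqn{i \neq j}, equal to \code{UP} if \eqn{x_j > x_i},
#' \code{DOWN} if \eqn{x_j < x_i} and \code{TIE} otherwise. Pairs are
#' enumerated in a fixed lexicographic order over \eqn{(i, j)} (outer index
#' \eqn{i}, inner index \eqn{j}), so features transformed from the same table
#' stay row-aligned and their transforms can be fed directly to
#' \code{\link{mutual_info}}. The transform is invariant under strictly
#' monotone maps of \code{x} and its size grows with the square of the
#' number of observations.
#'
#' @param x A numeric vector, ordered factor, or a factor with at most two
#'   levels (ordered by level code). Unordered factors with more than two
#'   categories have no total order; split them with
#'   \code{\link{split_categorical}} first.
#' @return A factor of length \code{n*(n-1)} with levels
#'   \code{DOWN}, \code{TIE}, \code{UP}.
#' @export
kendall_transform <- function(x) {
  check_feature(x)
  n <- length(x)
  if (n < 2L) stop("the Kendall transformation needs at least two observations")
  if (is.character(x)) x <- factor(x)
  if (is.factor(x) && !is.ordered(x) && nlevels(x) > 2L)
    stop("unordered feature with more than two categories has no Kendall ",
         "transformation; split it into per-category indicators with ",
         "split_categorical() first")
  v <- if (is.factor(x)) as.integer(x) else as.numeric(x)
  i <- rep(seq_len(n), each = n)
  j <- rep.int(seq_len(n), n)
  keep <- i != j
  d <- sign(v[j[keep]] - v[i[keep]])
  factor(c("DOWN", "TIE", "UP")[d + 2L], levels = c("DOWN", "TIE", "UP"))
}

#' Equal-frequency discretization
#'
#' Bins an ordinal/continuous feature into at most \code{bins} categories of
#' (approximately) equal frequency. Bin boundaries are empirical quantiles of
#' type 1 (inverted CDF), so boundaries are observed values and tied
#' observations are assigned deterministically by value. Features with no
#' more distinct values than \code{bins} are used as-is, one category per
#' value.
#'
#' @param x Numeric vector.
#' @param bins Maximum number of categories, at least 2.
#' @return A factor with at most \code{bins} levels.
#' @export
discretize <- function(x, bins = 10L) {
  check_feature(x)
  if (!is.numeric(x)) stop("'x' must be numeric to be discretized")
  if (bins < 2L) stop("'bins' must be at least 2")
  u <- sort(unique(x))
  if (length(u) <= bins)
    return(factor(match(x, u), levels = seq_along(u)))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 1, names = FALSE)
  br <- unique(qs)
  factor(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

#' Split a multi-category feature into binary indicators
#'
#' One-hot expansion of an unordered categorical feature with more than two
#' categories, the standard remedy for estimators (such as the Kendall
#' transformation) that cannot handle unordered multi-category inputs.
#'
#' @param x A factor (or vector coerced to one) with more than two
#'   categories.
#' @param name Base name used for the indicator names.
#' @return A named list of binary factors (levels \code{"0"}, \code{"1"}),
#'   one per category, named \code{<name>=<category>}.
#' @export
split_categorical <- function(x, name = deparse(substitute(x))) {
  check_feature(x)
  x <- as.factor(x)
  if (nlevels(x) <= 2L)
    stop("feature has at most two categories; splitting is only needed for ",
         "unordered features with more than two")
  out <- lapply(levels(x), function(l)
    factor(as.integer(x == l), levels = 0:1))
  names(out) <- paste0(name, "=", levels(x))
  out
}

#' Mutual information with estimator dispatch
#'
#' Front-end over \code{\link{mutual_info}} that prepares the inputs for the
#' chosen estimator: \code{"mle"} discretizes numeric inputs into
#' \code{bins} equal-frequency categories and uses the plug-in estimate;
#' \code{"kt"} Kendall-transforms both inputs (with the shared pair
#' enumeration, so they stay aligned) and computes the plug-in estimate on
#' the token pairs.
#'
#' @param x,y Equal-length features.
#' @param method \code{"mle"} or \code{"kt"}.
#' @param bins Bin count for MLE discretization of numeric inputs.
#' @return Mutual information in nats.
#' @export
estimate_mi <- function(x, y, method = c("mle", "kt"), bins = 10L) {
  method <- match.arg(method)
  check_lengths(x, y)
  if (method == "mle") {
    if (is.numeric(x) && length(unique(x)) > 2L) x <- discretize(x, bins)
    if (is.numeric(y) && length(unique(y)) > 2L) y <- discretize(y, bins)
    mutual_info(x, y)
  } else {
    mutual_info(kendall_transform(x), kendall_transform(y))
  }
}
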