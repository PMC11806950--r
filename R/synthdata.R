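# Synthetic benchmark generators: the two-chain junction network and
# parameterized anchored chain layouts. All channels are binary symmetric
# (bit-flip with probability eps on each link), with a uniform binary root.
#
# The default noise level eps = 0.2 is a structural requirement, not a
# tuning knob: the pipeline's anchor-DPI gate needs I(Y;A2) > I(Y;J) in the
# junction network, and for symmetric channels with per-link correlation
# rho = 1 - 2*eps this holds only when rho^2 < 1/2, i.e.
# eps > (1 - 1/sqrt(2))/2 ~ 0.146 (see the methods vignette for the
# derivation). 0.2 leaves a comfortable margin while keeping the chain
# signal strong.

flip_channel <- function(parent, eps) {
  (parent + stats::rbinom(length(parent), 1L, eps)) %% 2L
}

#' Generate the junction benchmark
#'
#' Samples from a Bayesian network of two binary chains sharing the anchor:
#' \code{Y -> A1 -> A2 -> JA -> A3} and \code{Y -> B1 -> B2 -> JB -> B3},
#' each link a symmetric bit-flip channel with probability \code{eps}. The
#' hidden mid-chain features \code{JA} and \code{JB} are withheld from the
#' output; in their place a single four-category junction feature
#' \code{J} = (\code{JA}, \code{JB}) (Cartesian pairing, so it retains the
#' information of both) is emitted. The observable table is
#' \code{Y, A1, A2, A3, B1, B2, B3, J} with anchor \code{Y}. Recovering the
#' two chains, with \code{J} as a bi-modal relay on both, is the benchmark
#' topology.
#'
#' The sample is \emph{balanced between the chains}: \code{n/2} rows are
#' drawn from the network and their A/B mirror images are appended. The two
#' chains are exchangeable in the network, so mirrored rows follow the same
#' distribution, but the empirical distribution becomes exactly symmetric
#' under swapping the chains. This matters because features at equal depth
#' carry exactly equal anchor information in the population
#' (\eqn{I(Y;A1) = I(Y;B1)}), and the strict DPI gates reject cross-chain
#' edges only on such exact ties; a plain iid sample breaks the tie by
#' noise and manufactures one spurious cross-chain path. Balancing restores
#' the population tie in the sample, which is the regime in which the
#' benchmark topology is identifiable.
#'
#' @param n Number of observations; must be even (see above).
#' @param eps Flip probability per link, in \code{[0, 0.5]}; at 0 the chains
#'   are deterministic copies (and the strict DPI gates reject everything),
#'   at 0.5 all features are independent of the anchor.
#' @param seed Integer seed; identical configuration reproduces the table.
#' @return An \code{\link{influence_table}}.
#' @export
gen_junction <- function(n = 5000L, eps = 0.2, seed = 1L) {
  if (n < 2L || n %% 2L != 0L)
    stop("'n' must be even and at least 2 (the sample is chain-balanced)")
  if (eps < 0 || eps > 0.5) stop("'eps' must be in [0, 0.5]")
  h <- n %/% 2L
  with_seed(seed, {
    y <- stats::rbinom(h, 1L, 0.5)
    a1 <- flip_channel(y, eps); a2 <- flip_channel(a1, eps)
    ja <- flip_channel(a2, eps); a3 <- flip_channel(ja, eps)
    b1 <- flip_channel(y, eps); b2 <- flip_channel(b1, eps)
    jb <- flip_channel(b2, eps); b3 <- flip_channel(jb, eps)
    # category labels carry a prefix so delimited-text round trips keep
    # them categorical (bare "01" would re-read as the number 1)
    j <- factor(c(paste0("j", ja, jb), paste0("j", jb, ja)),
                levels = c("j00", "j01", "j10", "j11"))
    influence_table(
      data.frame(Y = c(y, y),
                 A1 = c(a1, b1), A2 = c(a2, b2), A3 = c(a3, b3),
                 B1 = c(b1, a1), B2 = c(b2, a2), B3 = c(b3, a3),
                 J = j),
      anchor = "Y")
  })
}

#' Generate anchored noisy chains
#'
#' An anchor plus \code{branching} independent chains of \code{depth}
#' binary features each, every link a symmetric bit-flip channel with
#' probability \code{eps}. Columns are named \code{C<branch>_<depth>}. The
#' ground-truth edge list is attached as attribute \code{"edges"} for
#' recovery scoring.
#'
#' @param depth Chain length (features per branch), at least 1.
#' @param branching Number of chains, at least 1.
#' @param n Number of observations.
#' @param eps Flip probability per link.
#' @param seed Integer seed.
#' @return An \code{\link{influence_table}} with a ground-truth
#'   \code{"edges"} attribute (data frame \code{from}, \code{to}).
#' @export
gen_chain <- function(depth = 3L, branching = 2L, n = 1000L, eps = 0.2,
                      seed = 1L) {
  if (depth < 1L || branching < 1L) stop("'depth' and 'branching' must be at least 1")
  if (eps < 0 || eps > 0.5) stop("'eps' must be in [0, 0.5]")
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    cols <- list(Y = y)
    edges <- list()
    for (b in seq_len(branching)) {
      parent <- y
      pname <- "Y"
      for (d in seq_len(depth)) {
        nm <- sprintf("C%d_%d", b, d)
        parent <- flip_channel(parent, eps)
        cols[[nm]] <- parent
        edges[[length(edges) + 1L]] <- data.frame(from = pname, to = nm,
                                                  stringsAsFactors = FALSE)
        pname <- nm
      }
    }
    tab <- influence_table(as.data.frame(cols), anchor = "Y")
    attr(tab, "edges") <- do.call(rbind, edges)
    tab
  })
}

#' Generate a table of mutually independent binary features
#'
#' A negative control: the anchor and every other feature are independent
#' fair coin flips, so no influence path exists in the population.
#'
#' @param m Number of non-anchor features.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return An \code{\link{influence_table}} with anchor \code{Y}.
#' @export
gen_independent <- function(m = 6L, n = 1000L, seed = 1L) {
  if (m < 2L) stop("'m' must be at least 2")
  with_seed(seed, {
    cols <- c(list(Y = stats::rbinom(n, 1L, 0.5)),
              stats::setNames(lapply(seq_len(m), function(i)
                stats::rbinom(n, 1L, 0.5)), sprintf("X%d", seq_len(m))))
    influence_table(as.data.frame(cols), anchor = "Y")
  })
}
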