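# The tabular container: n observations x m features with per-feature kind
# (binary / categorical / ordinal) and a designated anchor.

infer_kind <- function(col) {
  nu <- length(unique(col))
  if (nu <= 2L) "binary"
  else if (is.numeric(col)) "ordinal"
  else "categorical"
}

#' Build an influence table
#'
#' Wraps a data frame as the input container of the influence-path search:
#' every column is a feature with a kind (\code{binary}, \code{categorical}
#' or \code{ordinal}) and one column is designated the anchor -- the
#' perturbation or intervention feature from which all paths originate.
#' Kinds are inferred unless given: columns with at most two distinct values
#' are binary, other numeric columns ordinal, the rest categorical.
#' Missing values are rejected (impute upstream if needed).
#'
#' @param data A data frame with named columns and at least one row.
#' @param anchor Name of the anchor column.
#' @param kinds Optional named character vector overriding inferred kinds
#'   for some or all columns.
#' @return A data frame of class \code{influence_table} with binary and
#'   categorical columns stored as factors, plus \code{anchor} and
#'   \code{kinds} attributes.
#' @examples
#' tab <- gen_junction(n = 200, seed = 1)
#' anchor(tab)
#' @export
influence_table <- function(data, anchor, kinds = NULL) {
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  if (nrow(data) < 1L) stop("'data' has no observations")
  if (is.null(names(data)) || any(!nzchar(names(data))))
    stop("all columns must be named")
  if (length(anchor) != 1L || !anchor %in% names(data))
    stop(sprintf("anchor feature '%s' is not a column of the table",
                 as.character(anchor)[1]))
  bad <- names(data)[vapply(data, anyNA, logical(1))]
  if (length(bad))
    stop("missing values in column(s): ", paste(bad, collapse = ", "),
         "; impute or drop them before analysis")

  k <- vapply(data, infer_kind, character(1))
  if (!is.null(kinds)) {
    unknown <- setdiff(names(kinds), names(data))
    if (length(unknown))
      stop("kinds given for unknown column(s): ", paste(unknown, collapse = ", "))
    if (!all(kinds %in% c("binary", "categorical", "ordinal")))
      stop("kinds must be 'binary', 'categorical' or 'ordinal'")
    k[names(kinds)] <- kinds
  }
  for (nm in names(data)) {
    if (k[[nm]] == "binary") {
      if (length(unique(data[[nm]])) > 2L)
        stop(sprintf("column '%s' declared binary but has more than two distinct values", nm))
      data[[nm]] <- as.factor(data[[nm]])
    } else if (k[[nm]] == "categorical") {
      data[[nm]] <- as.factor(data[[nm]])
    } else if (!is.numeric(data[[nm]])) {
      stop(sprintf("column '%s' declared ordinal but is not numeric", nm))
    }
  }
  structure(data, anchor = anchor, kinds = k,
            class = c("influence_table", "data.frame"))
}

#' @export
print.influence_table <- function(x, ...) {
  k <- attr(x, "kinds")
  cat(sprintf("influence table: %d observations x %d features (anchor: %s)\n",
              nrow(x), ncol(x), attr(x, "anchor")))
  cat(sprintf("  kinds: %d binary, %d categorical, %d ordinal\n",
              sum(k == "binary"), sum(k == "categorical"), sum(k == "ordinal")))
  invisible(x)
}

#' Anchor and kinds accessors
#'
#' @param tab An \code{influence_table}.
#' @return \code{anchor()} the anchor column name; \code{feature_kinds()} the
#'   named kind vector.
#' @export
anchor <- function(tab) attr(tab, "anchor")

#' @rdname anchor
#' @export
feature_kinds <- function(tab) attr(tab, "kinds")

guess_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited table as an influence table
#'
#' Reads a CSV/TSV file with a header row and wraps it with
#' \code{\link{influence_table}}; empty cells and \code{NA} are treated as
#' missing and rejected with the offending columns named.
#'
#' @param path File path; the delimiter defaults to \code{","} for
#'   \code{.csv} and tab otherwise.
#' @param anchor Anchor column name.
#' @param kinds Optional kind overrides, as in \code{\link{influence_table}}.
#' @param delim Optional explicit field delimiter.
#' @return An \code{influence_table}.
#' @export
read_influence_table <- function(path, anchor, kinds = NULL, delim = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = guess_delim(path, delim),
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("input table is empty: ", path)
  influence_table(df, anchor, kinds)
}

#' Write an influence table to delimited text
#'
#' @param tab An \code{influence_table} (or plain data frame).
#' @param path Output path; delimiter chosen as in
#'   \code{\link{read_influence_table}}.
#' @param delim Optional explicit delimiter.
#' @return The path, invisibly.
#' @export
write_influence_table <- function(tab, path, delim = NULL) {
  utils::write.table(as.data.frame(tab), path, sep = guess_delim(path, delim),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Encode a table for a given estimator into aligned integer-code columns.
# mle: ordinal columns are discretized, factors keep their codes.
# kt:  every column is Kendall-transformed with the shared (i,j) pair
#      enumeration; unordered >2-category columns are either rejected or
#      (auto_split) expanded into per-category indicators. Returns a list
#      with codes/nlev/names/anchor index.
encode_table <- function(tab, estimator = c("mle", "kt"), bins = 10L,
                         auto_split = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(tab, "influence_table"))
  anc <- attr(tab, "anchor")
  kinds <- attr(tab, "kinds")
  cols <- as.list(as.data.frame(tab))

  if (estimator == "mle") {
    enc <- lapply(names(cols), function(nm) {
      x <- cols[[nm]]
      if (kinds[[nm]] == "ordinal") x <- discretize(x, bins)
      as_codes(x)
    })
    names(enc) <- names(cols)
  } else {
    wide <- kinds == "categorical" &
      vapply(cols, function(x) length(unique(x)) > 2L, logical(1))
    if (wide[[anc]])
      stop("the anchor has more than two unordered categories; the Kendall ",
           "transformation cannot order it")
    if (any(wide) && !auto_split)
      stop("unordered feature(s) with more than two categories cannot be ",
           "Kendall-transformed: ", paste(names(cols)[wide], collapse = ", "),
           "; split them into per-category indicators (split_categorical(), ",
           "or auto_split = TRUE / --auto-split)")
    out <- list()
    for (nm in names(cols)) {
      if (wide[[nm]]) {
        out <- c(out, split_categorical(cols[[nm]], name = nm))
      } else {
        out[[nm]] <- cols[[nm]]
      }
    }
    enc <- lapply(out, function(x) as_codes(kendall_transform(x)))
  }

  list(codes = lapply(enc, `[[`, "codes"),
       nlev = vapply(enc, `[[`, 1L, "k"),
       names = names(enc),
       anchor = match(anc, names(enc)),
       n = nrow(tab),
       estimator = estimator)
}
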