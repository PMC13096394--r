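#' @include AllClasses.R AllGenerics.R
NULL

#' Information portrait of a class
#'
#' The ranked list of descriptive gradations by their knowledge-matrix
#' value for one class: which feature values promote (\eqn{I_{ij} > 0}) and
#' which hinder (\eqn{I_{ij} < 0}) membership.  Entries are sorted by
#' descending \eqn{I_{ij}}, ties kept in gradation order.
#'
#' @param model a [KnowledgeModel-class].
#' @param class a class gradation of the model.
#' @param topK keep only the top entries (optional).
#' @return data.frame: \code{scale}, \code{gradation}, \code{id},
#'   \code{value}, \code{sign} (\code{"contributing"}, \code{"hindering"}
#'   or \code{"neutral"}).
#' @export
informationPortrait <- function(model, class, topK = NULL) {
  stopifnot(is(model, "KnowledgeModel"))
  if (!class %in% colnames(model@values))
    .stopf("unknown class gradation: %s", class)
  grad <- gradationInfo(model)
  v <- model@values[, class]
  df <- data.frame(scale = grad$scale, gradation = grad$label, id = grad$id,
                   value = unname(v),
                   sign = ifelse(v > 0, "contributing",
                                 ifelse(v < 0, "hindering", "neutral")),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$value, seq_len(nrow(df))), ]
  rownames(df) <- NULL
  if (!is.null(topK)) df <- utils::head(df, topK)
  df
}

#' Significance of gradations and scales
#'
#' Per-gradation significance is the population standard deviation of
#' \eqn{I_{ij}} across classes: a gradation whose knowledge values differ
#' strongly between classes is informative; one with identical values in
#' every class carries nothing.  Scales aggregate their gradations by mean.
#' Both tables are sorted descending and carry the cumulative normalized
#' Pareto curve in percent of total significance.
#'
#' @param model a [KnowledgeModel-class] with at least two classes.
#' @return a [SignificanceTable-class].
#' @export
significanceTable <- function(model) {
  stopifnot(is(model, "KnowledgeModel"))
  if (ncol(model@values) < 2L)
    .stopf("significance requires at least two class gradations")
  grad <- gradationInfo(model)
  sigma <- .rowPopSd(model@values)
  gdf <- data.frame(id = grad$id, scale = grad$scale, index = grad$index,
                    label = grad$label, sigma = unname(sigma),
                    stringsAsFactors = FALSE)
  gdf <- gdf[order(-gdf$sigma, seq_len(nrow(gdf))), ]
  gdf$cumPercent <- .cumSharePercent(gdf$sigma)
  rownames(gdf) <- NULL
  agg <- tapply(sigma, grad$scale, mean)
  sdf <- data.frame(scale = names(agg), sigma = as.numeric(agg),
                    stringsAsFactors = FALSE)
  sdf <- sdf[order(-sdf$sigma, sdf$scale), ]
  sdf$cumPercent <- .cumSharePercent(sdf$sigma)
  rownames(sdf) <- NULL
  new("SignificanceTable", gradations = gdf, scales = sdf,
      criterion = model@criterion)
}

.cumSharePercent <- function(v) {
  tot <- sum(v)
  if (tot == 0) return(seq_along(v) / length(v) * 100)  # degenerate: uniform
  100 * cumsum(v) / tot
}

#' Pareto coverage at a feature fraction
#'
#' The share of total significance carried by the top-ranked fraction of
#' features, with linear interpolation between ranks.
#'
#' @param table a [SignificanceTable-class].
#' @param featureFraction fraction of features in \eqn{(0, 1]}.
#' @param level \code{"scale"} (default; the classical Pareto curve over
#'   descriptive scales) or \code{"gradation"}.
#' @return percent of total significance in \eqn{[0, 100]}.
#' @export
paretoCoverage <- function(table, featureFraction,
                           level = c("scale", "gradation")) {
  stopifnot(is(table, "SignificanceTable"))
  level <- match.arg(level)
  if (featureFraction <= 0 || featureFraction > 1)
    .stopf("featureFraction must lie in (0, 1]")
  df <- if (level == "scale") table@scales else table@gradations
  if (nrow(df) == 0L) .stopf("empty significance table")
  curve <- c(0, df$cumPercent)            # C[k] at k = 0 .. n features
  p <- featureFraction * nrow(df)
  k <- floor(p)
  t <- p - k
  val <- curve[k + 1L]
  if (t > 0) val <- val + t * (curve[k + 2L] - curve[k + 1L])
  val
}

#' Signed gradation-to-class contribution graph
#'
#' The bipartite graph underlying the knowledge matrix: one edge per
#' (gradation, class) pair, weighted by \eqn{I_{ij}} and signed.  Edges are
#' ranked by \eqn{|I_{ij}|} (ties broken deterministically by scale,
#' gradation and class order) and filtered to the top \code{topK} edges or
#' the top \code{topPercent} percent of edges.  Zero-weight edges are never
#' emitted.
#'
#' @param model a [KnowledgeModel-class].
#' @param topK keep this many strongest edges.
#' @param topPercent keep this percent of the strongest edges (exactly one
#'   of \code{topK}/\code{topPercent} must be given).
#' @return data.frame of edges: \code{scale}, \code{gradation}, \code{id},
#'   \code{class}, \code{weight}, \code{sign}; the applied filter is
#'   attached as attribute \code{"filter"}.
#' @export
contributionGraph <- function(model, topK = NULL, topPercent = NULL) {
  stopifnot(is(model, "KnowledgeModel"))
  if (is.null(topK) == is.null(topPercent))
    .stopf("give exactly one of topK or topPercent")
  grad <- gradationInfo(model)
  I <- model@values
  edges <- data.frame(
    scale = rep(grad$scale, times = ncol(I)),
    gradation = rep(grad$label, times = ncol(I)),
    id = rep(grad$id, times = ncol(I)),
    class = rep(colnames(I), each = nrow(I)),
    weight = as.vector(I),
    gradOrd = rep(seq_len(nrow(I)), times = ncol(I)),
    classOrd = rep(seq_len(ncol(I)), each = nrow(I)),
    stringsAsFactors = FALSE)
  edges <- edges[edges$weight != 0, ]
  edges <- edges[order(-abs(edges$weight), edges$gradOrd, edges$classOrd), ]
  k <- if (!is.null(topK)) topK
       else floor(nrow(edges) * topPercent / 100 + 1e-9)
  k <- min(k, nrow(edges))
  if (k <= 0L) .warnf("filter selects no edges; returning an empty graph")
  edges <- utils::head(edges, max(k, 0L))
  edges$sign <- ifelse(edges$weight > 0, "+", "-")
  edges$gradOrd <- edges$classOrd <- NULL
  rownames(edges) <- NULL
  attr(edges, "filter") <- if (!is.null(topK))
    list(type = "top_k", value = topK)
  else list(type = "top_percent", value = topPercent)
  edges
}

#' Export a contribution graph as Graphviz DOT
#'
#' Edges carry \code{weight}, a red/blue color for positive/negative sign,
#' and a pen width proportional to \eqn{|I_{ij}|}, reproducing the content
#' of the classical feature-contribution diagrams as a data export.
#'
#' @param edges output of [contributionGraph()].
#' @param path output DOT path.
#' @return \code{path}, invisibly.
#' @export
writeGraphDOT <- function(edges, path) {
  maxw <- if (nrow(edges)) max(abs(edges$weight)) else 1
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  body <- if (nrow(edges)) sprintf(
    '  %s -- %s [weight=%g, color=%s, penwidth=%.2f];',
    q(edges$id), q(edges$class), edges$weight,
    ifelse(edges$weight > 0, "red", "blue"),
    0.5 + 3.5 * abs(edges$weight) / maxw) else character()
  writeLines(c("graph contributions {", body, "}"), path)
  invisible(path)
}

#' Imbalance baseline of a screening set
#'
#' The prevalence of the active class and the accuracy of the trivial
#' classifier that predicts every object inactive — the yardstick any
#' accuracy figure on a highly imbalanced screening set must be read
#' against.
#'
#' @param nTotal total number of objects (> 0).
#' @param nActive number of active objects, \eqn{0 \le} \code{nActive}
#'   \eqn{\le} \code{nTotal}.
#' @return named list: \code{prevalencePercent},
#'   \code{trivialAccuracyPercent}, \code{trivialCorrect}.  The first two
#'   sum to 100 exactly.
#' @examples
#' baselineStats(3523, 48)
#' @export
baselineStats <- function(nTotal, nActive) {
  if (length(nTotal) != 1L || nTotal <= 0) .stopf("nTotal must be positive")
  if (nActive < 0 || nActive > nTotal)
    .stopf("nActive must lie in [0, nTotal]")
  prev <- 100 * nActive / nTotal
  list(prevalencePercent = prev,
       trivialAccuracyPercent = 100 - prev,
       trivialCorrect = nTotal - nActive)
}

#' Export an information portrait or significance table as TSV
#'
#' @param x a data.frame (portrait, contribution graph) or
#'   [SignificanceTable-class].
#' @param path output TSV path.
#' @param level for significance tables, \code{"scale"} or
#'   \code{"gradation"}.
#' @return \code{path}, invisibly.
#' @export
writeAnalysisTSV <- function(x, path, level = c("scale", "gradation")) {
  if (is(x, "SignificanceTable")) {
    level <- match.arg(level)
    x <- if (level == "scale") x@scales else x@gradations
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
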