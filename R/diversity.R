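#' Prey species richness
#'
#' Number of taxa with at least one occurrence. For a matrix (e.g. fish by
#' taxon) the taxa are pooled over rows first, so the result equals the
#' richness of the pooled count vector.
#'
#' @param x non-negative numeric vector, or matrix with taxa as columns.
#' @return integer count of occurring taxa.
#' @export
richness <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) x <- colSums(as.matrix(x))
  if (any(x < 0)) stop("entries must be non-negative")
  sum(x > 0)
}

#' Shannon-Wiener diversity index
#'
#' H' = -sum p_i log p_i over the nonzero proportions, in natural-log units
#' (nats). Zero counts contribute nothing, so the index is invariant to
#' zero-padding and to taxon order.
#'
#' @param x non-negative count (or proportion) vector with positive total.
#' @return H' in nats; 0 for a single-taxon sample. H' <= log(richness).
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all-zero count vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Whittaker beta-diversity between two diets
#'
#' Presence/absence dissimilarity of two prey lists,
#' \deqn{\beta_w = \frac{a+b+c}{(2a+b+c)/2} - 1,}
#' where \eqn{a} is the number of taxa shared by the two diets and \eqn{b},
#' \eqn{c} the numbers exclusive to each. 0 means identical prey lists
#' (niche fully shared), 1 means disjoint lists.
#'
#' @param x,y prey presence, either as character vectors of taxon names or as
#'   logical/numeric presence vectors over a common taxon ordering.
#' @return object of class \code{beta_diversity}: list with components
#'   \code{a}, \code{b}, \code{c}, \code{beta_w}.
#' @examples
#' beta_whittaker(c("cal", "euph"), c("cal", "dec"))
#' @export
beta_whittaker <- function(x, y) {
  as_set <- function(v) {
    if (is.character(v)) return(unique(v))
    if (is.null(names(v))) names(v) <- seq_along(v)
    names(v)[as.logical(v > 0)]
  }
  sx <- as_set(x); sy <- as_set(y)
  if (length(sx) == 0L && length(sy) == 0L)
    stop("both presence sets are empty")
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  bw <- (a + b + cc) / ((2 * a + b + cc) / 2) - 1
  structure(list(a = a, b = b, c = cc, beta_w = bw),
            class = "beta_diversity")
}

#' @export
print.beta_diversity <- function(x, ...) {
  cat(sprintf("Whittaker beta-diversity: %.4f  (a=%d shared, b=%d, c=%d)\n",
              x$beta_w, x$a, x$b, x$c))
  invisible(x)
}
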