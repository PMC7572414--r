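#' Pianka's niche-overlap index
#'
#' \deqn{O_{jk} = \frac{\sum_i p_{ij} p_{ik}}
#'   {\sqrt{\sum_i p_{ij}^2 \sum_i p_{ik}^2}},}
#' the cosine similarity of two resource-utilization vectors: 0 means no
#' overlap (disjoint prey use), 1 complete overlap. The index is symmetric and
#' invariant to positive rescaling of either vector, so raw \%FO or \%N
#' vectors can be supplied without normalizing to proportions.
#'
#' @param p,q non-negative utilization vectors over the same ordered prey
#'   groups; each must have at least one positive entry.
#' @return overlap index in [0, 1].
#' @examples
#' pianka(c(0.5, 0.5, 0), c(0.5, 0, 0.5))  # 0.5
#' @export
pianka <- function(p, q) {
  if (length(p) != length(q)) stop("vectors must have the same length")
  if (any(p < 0) || any(q < 0)) stop("utilization values must be non-negative")
  if (sum(p) == 0 || sum(q) == 0) stop("zero utilization vector")
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' RA2 randomization test for niche overlap
#'
#' Tests an observed Pianka overlap against the RA2 null model: in each
#' iteration every nonzero entry of both vectors is replaced by an independent
#' Uniform(0, 1) draw while zero entries (prey groups absent from the
#' observed diet) stay zero -- zero states retained, niche breadth relaxed.
#' Groups absent from both diets are dropped beforehand; retained zeros in
#' both vectors contribute nothing to the index. The p-value uses the add-one
#' estimator \eqn{(1 + \#\{O_{null} \ge O_{obs}\})/(1 + iterations)}, so it is
#' never exactly zero.
#'
#' @param p,q observed utilization vectors (see \code{\link{pianka}}).
#' @param iterations number of null draws (default 1000).
#' @param seed optional seed; identical seed gives an identical result.
#' @param tail \code{"greater"} (null overlap >= observed; the standard
#'   "more overlap than chance" question) or \code{"two.sided"}.
#' @param randomize \code{"both"} (default; both vectors randomized each
#'   iteration) or \code{"first"} (randomize \code{p}, keep \code{q} fixed).
#' @return object of class \code{overlap_result}: observed index, null
#'   sample, p-value, iterations, algorithm tag, seed, tail.
#' @export
ra2_null_test <- function(p, q, iterations = 1000, seed = NULL,
                          tail = c("greater", "two.sided"),
                          randomize = c("both", "first")) {
  tail <- match.arg(tail)
  randomize <- match.arg(randomize)
  if (iterations < 1) stop("iterations must be >= 1")
  obs <- pianka(p, q)
  keep <- p > 0 | q > 0
  p <- p[keep]; q <- q[keep]
  nzp <- which(p > 0); nzq <- which(q > 0)
  null <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    pp <- p; qq <- q
    pp[nzp] <- runif(length(nzp))
    if (randomize == "both") qq[nzq] <- runif(length(nzq))
    pianka(pp, qq)
  }, numeric(1L)))
  p_up <- (1 + sum(null >= obs)) / (1 + iterations)
  p_lo <- (1 + sum(null <= obs)) / (1 + iterations)
  pv <- switch(tail, greater = p_up, two.sided = min(1, 2 * min(p_up, p_lo)))
  structure(list(observed = obs, null = null, p_value = pv,
                 iterations = iterations, algorithm = "RA2",
                 seed = seed, tail = tail, randomize = randomize),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Pianka overlap O = %.4f  (%s null, %d iterations, tail = %s)\n  p-value = %.4g   null mean = %.4f\n",
    x$observed, x$algorithm, x$iterations, x$tail, x$p_value, mean(x$null)))
  invisible(x)
}

#' Pairwise Pianka overlap matrix with RA2 significance
#'
#' Computes Pianka overlap (and RA2 p-values) over requested pairs of diet
#' vectors keyed by species and area: species pairs within each area,
#' same-species pairs between areas, or all pairs. The pair list is traversed
#' in a fixed order under one shared seed stream, so results are reproducible
#' as a set.
#'
#' @param diets numeric matrix, strata as rows (one utilization vector per
#'   row), prey groups as columns.
#' @param strata data.frame with one row per row of \code{diets}, columns
#'   \code{species} and \code{area}.
#' @param mode \code{"species_within_area"}, \code{"areas_within_species"},
#'   or \code{"all"}.
#' @param iterations,seed,tail passed to \code{\link{ra2_null_test}}.
#' @return object of class \code{overlap_matrix}: list with symmetric
#'   matrices \code{O} (unit diagonal) and \code{p} (NA where a pair was not
#'   requested), plus a long data.frame \code{pairs}.
#' @export
pairwise_overlap_matrix <- function(diets, strata,
                                    mode = c("all", "species_within_area",
                                             "areas_within_species"),
                                    iterations = 1000, seed = NULL,
                                    tail = "greater") {
  mode <- match.arg(mode)
  diets <- as.matrix(diets)
  if (nrow(diets) < 2L) stop("need at least two diet vectors")
  stopifnot(nrow(strata) == nrow(diets))
  labs <- paste(strata$species, strata$area, sep = "|")
  rownames(diets) <- labs
  n <- nrow(diets)
  O <- diag(1, n); dimnames(O) <- list(labs, labs)
  P <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  wanted <- function(i, j) switch(
    mode,
    all = TRUE,
    species_within_area = strata$area[i] == strata$area[j] &&
      strata$species[i] != strata$species[j],
    areas_within_species = strata$species[i] == strata$species[j] &&
      strata$area[i] != strata$area[j])
  pairs <- list()
  seeds <- child_seeds(seed %||% sample.int(.Machine$integer.max, 1L),
                       n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    k <- k + 1L
    if (!wanted(i, j)) { O[i, j] <- O[j, i] <- pianka(diets[i, ], diets[j, ]); next }
    r <- ra2_null_test(diets[i, ], diets[j, ], iterations = iterations,
                       seed = seeds[k], tail = tail)
    O[i, j] <- O[j, i] <- r$observed
    P[i, j] <- P[j, i] <- r$p_value
    pairs[[length(pairs) + 1L]] <- data.frame(
      stratum_1 = labs[i], stratum_2 = labs[j],
      O = r$observed, p_value = r$p_value, iterations = iterations,
      stringsAsFactors = FALSE)
  }
  structure(list(O = O, p = P,
                 pairs = if (length(pairs)) do.call(rbind, pairs)
                         else data.frame(),
                 mode = mode, iterations = iterations, seed = seed),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Pianka overlap (", x$mode, " pairs tested, ",
      x$iterations, " RA2 iterations)\n", sep = "")
  print(round(x$O, digits))
  invisible(x)
}
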