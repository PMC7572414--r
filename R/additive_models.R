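# Penalized-spline additive modelling protocol: collinearity screening,
# distribution-driven family choice, thin plate regression splines with a
# small basis (k = 4) to avoid over-fitting, and AIC-based stepwise term
# selection. mgcv does the penalized fitting; the screening, family decision
# and selection logic live here.

#' Collinearity diagnostics for a set of model predictors
#'
#' Pairwise Pearson correlations among numeric predictors and generalized
#' variance-inflation factors (GVIF) per term, computed from determinant
#' ratios of the correlation matrix of the dummy-coded design. Terms are
#' flagged when |r| >= \code{r_threshold} with another predictor or
#' GVIF >= \code{gvif_threshold}, the screening rule used before fitting.
#'
#' @param data data.frame holding the predictors.
#' @param terms character vector of predictor names (numeric or factor).
#' @param r_threshold correlation flag threshold (default 0.70).
#' @param gvif_threshold GVIF flag threshold (default 3).
#' @return object of class \code{collinearity_report}: \code{correlations}
#'   (matrix), \code{gvif} (data.frame term, df, gvif, flagged),
#'   \code{flagged_pairs}, \code{ok} (TRUE when nothing is flagged).
#' @export
collinearity_diagnostics <- function(data, terms,
                                     r_threshold = 0.70,
                                     gvif_threshold = 3) {
  stopifnot(length(terms) >= 1L, all(terms %in% names(data)))
  df <- data[terms]
  if (nrow(df) < 3L) stop("need at least 3 rows")
  for (v in terms) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    vals <- if (is.factor(df[[v]])) as.integer(df[[v]]) else df[[v]]
    if (length(unique(vals)) < 2L) stop("constant predictor: ", v)
  }
  num <- terms[vapply(df, is.numeric, logical(1L))]
  cors <- if (length(num) >= 2L) cor(df[num], use = "complete.obs")
          else matrix(1, 0, 0)

  X <- model.matrix(~., df)[, -1L, drop = FALSE]
  assign_idx <- attr(model.matrix(~., df), "assign")[-1L]
  gvif <- rep(1, length(terms))
  if (length(terms) >= 2L && ncol(X) >= 2L) {
    R <- cor(X)
    detR <- det(R)
    for (j in seq_along(terms)) {
      idx <- which(assign_idx == j)
      gvif[j] <- det(R[idx, idx, drop = FALSE]) *
        det(R[-idx, -idx, drop = FALSE]) / detR
    }
  }
  dfree <- vapply(seq_along(terms), function(j) sum(assign_idx == j),
                  integer(1L))
  flagged_pairs <- if (length(num) >= 2L) {
    idx <- which(abs(cors) >= r_threshold & upper.tri(cors), arr.ind = TRUE)
    data.frame(var1 = rownames(cors)[idx[, 1L]],
               var2 = colnames(cors)[idx[, 2L]],
               r = cors[idx], stringsAsFactors = FALSE)
  } else data.frame()
  gtab <- data.frame(term = terms, df = dfree, gvif = gvif,
                     flagged = gvif >= gvif_threshold,
                     stringsAsFactors = FALSE)
  structure(list(correlations = cors, gvif = gtab,
                 flagged_pairs = flagged_pairs,
                 ok = !any(gtab$flagged) && nrow(flagged_pairs) == 0L,
                 r_threshold = r_threshold,
                 gvif_threshold = gvif_threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity screening (flag: |r| >=", x$r_threshold,
      "or GVIF >=", x$gvif_threshold, ")\n")
  print(x$gvif, row.names = FALSE)
  if (nrow(x$flagged_pairs)) {
    cat("Correlated pairs:\n"); print(x$flagged_pairs, row.names = FALSE)
  }
  cat(if (x$ok) "No collinearity flags.\n" else "Collinearity flagged.\n")
  invisible(x)
}

#' Choose a response family by the normality decision path
#'
#' Shapiro-Wilk test on the raw response: if normality is not rejected at
#' \code{alpha}, a Gaussian model with identity link is used. Otherwise the
#' log-transformed response is tested (requires a strictly positive
#' response); if normality is then not rejected, the model is Gaussian on the
#' log scale. If normality fails after transformation, a Gamma distribution
#' with log link is used. The full decision path is returned.
#'
#' @param y numeric response, n >= 3 (Shapiro-Wilk subsamples above 5000).
#' @param alpha significance level for the normality tests (default 0.05).
#' @param seed seed for the (rarely needed) subsampling.
#' @return object of class \code{family_decision}: \code{family} (one of
#'   \code{"gaussian-identity"}, \code{"gaussian-log"}, \code{"gamma-log"})
#'   and \code{path} (data.frame of tests and decisions).
#' @export
choose_family <- function(y, alpha = 0.05, seed = NULL) {
  y <- y[is.finite(y)]
  if (length(y) < 3L) stop("need at least 3 finite response values")
  sw <- function(v) {
    if (length(v) > 5000L) v <- with_seed(seed, sample(v, 5000L))
    shapiro.test(v)
  }
  path <- data.frame(test = character(), W = numeric(), p = numeric(),
                     decision = character(), stringsAsFactors = FALSE)
  t1 <- sw(y)
  path <- rbind(path, data.frame(test = "shapiro_raw", W = unname(t1$statistic),
                                 p = t1$p.value,
                                 decision = ifelse(t1$p.value >= alpha,
                                                   "gaussian-identity",
                                                   "try log"),
                                 stringsAsFactors = FALSE))
  fam <- "gaussian-identity"
  if (t1$p.value < alpha) {
    if (any(y <= 0)) {
      bad <- which(y <= 0)
      stop("log/gamma path needs a strictly positive response; ",
           "non-positive values at rows ",
           paste(head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    }
    t2 <- sw(log(y))
    fam <- if (t2$p.value >= alpha) "gaussian-log" else "gamma-log"
    path <- rbind(path, data.frame(test = "shapiro_log",
                                   W = unname(t2$statistic), p = t2$p.value,
                                   decision = fam, stringsAsFactors = FALSE))
  }
  structure(list(family = fam, path = path, alpha = alpha),
            class = "family_decision")
}

#' @export
print.family_decision <- function(x, ...) {
  cat("Family decision:", x$family, "\n")
  print(x$path, row.names = FALSE)
  invisible(x)
}

term_formula <- function(response, smooth_terms, factor_terms, k) {
  rhs <- c(if (length(smooth_terms))
             sprintf("s(%s, k = %d, bs = \"tp\")", smooth_terms, k),
           factor_terms)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a penalized-spline additive model
#'
#' Fits a generalized additive model with thin plate regression splines for
#' each smooth term, the basis dimension restricted to \code{k} (default 4)
#' to avoid over-fitting, smoothing parameters chosen by GCV (REML available
#' via \code{method}). The \code{"gaussian-log"} family is handled as a
#' Gaussian model of the log-transformed response (a transformation, not a
#' log-link GLM). Predictors are screened for collinearity first; flagged
#' designs are rejected unless \code{override_collinearity = TRUE}.
#'
#' @param data data.frame with the response and predictors.
#' @param response response column name.
#' @param smooth_terms character vector of continuous predictors to smooth.
#' @param factor_terms character vector of categorical predictors entering
#'   parametrically.
#' @param family \code{"auto"} (decide via \code{\link{choose_family}}) or
#'   one of \code{"gaussian-identity"}, \code{"gaussian-log"},
#'   \code{"gamma-log"}.
#' @param k basis dimension per smooth (default 4).
#' @param method smoothing-parameter criterion, \code{"GCV.Cp"} (default) or
#'   \code{"REML"}.
#' @param check_collinearity run the pre-fit screening (default TRUE when
#'   there are >= 2 terms).
#' @param override_collinearity fit anyway when the screening flags terms.
#' @return object of class \code{additive_fit}: the underlying
#'   \code{mgcv::gam} fit plus \code{family_label}, \code{edf} (per smooth),
#'   \code{aic}, \code{deviance_explained} (percent), \code{terms},
#'   \code{response}.
#' @export
fit_additive_model <- function(data, response, smooth_terms = character(),
                               factor_terms = character(),
                               family = "auto", k = 4,
                               method = c("GCV.Cp", "REML"),
                               check_collinearity = TRUE,
                               override_collinearity = FALSE) {
  method <- match.arg(method)
  terms <- c(smooth_terms, factor_terms)
  stopifnot(response %in% names(data), all(terms %in% names(data)))
  data <- data[complete.cases(data[c(response, terms)]), , drop = FALSE]
  n <- nrow(data)
  total_basis <- length(smooth_terms) * k + length(factor_terms) + 1L
  if (n <= total_basis)
    stop("n (", n, ") must exceed the total basis dimension (",
         total_basis, ")")
  for (v in factor_terms)
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])

  screening <- NULL
  if (check_collinearity && length(terms) >= 2L) {
    screening <- collinearity_diagnostics(data, terms)
    if (!screening$ok && !override_collinearity)
      stop("collinearity screening flagged predictors (",
           paste(screening$gvif$term[screening$gvif$flagged],
                 collapse = ", "),
           "); pass override_collinearity = TRUE to fit anyway")
  }

  fd <- NULL
  if (identical(family, "auto")) {
    fd <- choose_family(data[[response]])
    family <- fd$family
  }
  family <- match.arg(family,
                      c("gaussian-identity", "gaussian-log", "gamma-log"))
  yname <- response
  if (family == "gaussian-log") {
    if (any(data[[response]] <= 0))
      stop("gaussian-log requires a strictly positive response")
    yname <- paste0(".log_", response)
    data[[yname]] <- log(data[[response]])
  }
  if (family == "gamma-log" && any(data[[response]] <= 0))
    stop("gamma-log requires a strictly positive response")
  fam_obj <- switch(family,
                    "gaussian-identity" = stats::gaussian(),
                    "gaussian-log" = stats::gaussian(),
                    "gamma-log" = stats::Gamma(link = "log"))
  fml <- term_formula(yname, smooth_terms, factor_terms, k)
  fit <- mgcv::gam(fml, family = fam_obj, data = data, method = method)
  if (!fit$converged)
    stop("penalized IRLS did not converge for response ", response)

  edf <- if (length(smooth_terms)) {
    s_lab <- vapply(fit$smooth, function(s) s$label, character(1L))
    setNames(pen.edf_by_smooth(fit), s_lab)
  } else numeric(0)
  dev_expl <- 100 * (1 - fit$deviance / fit$null.deviance)
  structure(list(gam = fit, family_label = family,
                 family_decision = fd, screening = screening,
                 response = response, smooth_terms = smooth_terms,
                 factor_terms = factor_terms, k = k,
                 edf = edf, aic = AIC(fit),
                 deviance_explained = dev_expl, n = n),
            class = "additive_fit")
}

# per-smooth effective degrees of freedom (sum of per-coefficient edf)
pen.edf_by_smooth <- function(fit) {
  vapply(fit$smooth, function(s)
    sum(fit$edf[s$first.para:s$last.para]), numeric(1L))
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("Additive model: %s [%s], n = %d\n", x$response,
              x$family_label, x$n))
  if (length(x$edf)) {
    cat("  smooth terms (edf):\n")
    for (i in seq_along(x$edf))
      cat(sprintf("    %-28s %.2f\n", names(x$edf)[i], x$edf[i]))
  }
  if (length(x$factor_terms))
    cat("  factor terms:", paste(x$factor_terms, collapse = ", "), "\n")
  cat(sprintf("  AIC = %.2f, deviance explained = %.1f%%\n",
              x$aic, x$deviance_explained))
  invisible(x)
}

#' @export
summary.additive_fit <- function(object, ...) {
  s <- summary(object$gam)
  out <- list(fit = object, gam_summary = s)
  class(out) <- "summary.additive_fit"
  out
}

#' @export
print.summary.additive_fit <- function(x, ...) {
  print(x$fit)
  s <- x$gam_summary
  if (!is.null(s$s.table) && nrow(s$s.table)) {
    cat("\nApproximate smooth-term tests (F on edf/Ref.df; approximate):\n")
    print(round(s$s.table, 4))
  }
  if (!is.null(s$p.table) && nrow(s$p.table)) {
    cat("\nParametric coefficients:\n")
    print(round(s$p.table, 4))
  }
  invisible(x)
}

#' @export
predict.additive_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  p <- if (is.null(newdata)) predict(object$gam, type = "link", ...)
       else predict(object$gam, newdata = newdata, type = "link", ...)
  if (type == "link") return(p)
  switch(object$family_label,
         "gaussian-identity" = p,
         "gaussian-log" = exp(p),   # median back-transform of the log model
         "gamma-log" = exp(p))
}

#' @export
residuals.additive_fit <- function(object, ...) residuals(object$gam, ...)

#' @export
coef.additive_fit <- function(object, ...) coef(object$gam)

#' @export
AIC.additive_fit <- function(object, ..., k = 2) object$aic

#' @export
fitted.additive_fit <- function(object, ...) fitted(object$gam)

#' @export
plot.additive_fit <- function(x, ...) {
  plot(x$gam, pages = 1, ...)
  invisible(x)
}

#' Forward-backward stepwise term selection by AIC
#'
#' Builds the model term by term: a forward pass adds, at each step, the
#' candidate whose inclusion lowers AIC the most, accepting a move only when
#' the improvement exceeds \code{delta} (default 2, the conventional
#' information-criterion margin; ties break toward fewer terms). A backward
#' pass then drops terms whose removal lowers AIC by more than \code{delta}.
#' All models share one family, chosen up front.
#'
#' @param data,response,family,k,method as in
#'   \code{\link{fit_additive_model}}.
#' @param smooth_candidates continuous candidate predictors (entered as
#'   smooths).
#' @param factor_candidates categorical candidate predictors.
#' @param delta minimum AIC improvement to accept a move (default 2).
#' @param check_collinearity screen the full candidate set first
#'   (default TRUE).
#' @return list of class \code{stepwise_selection}: \code{best} (an
#'   \code{additive_fit}), \code{trace} (data.frame of every evaluated
#'   move), \code{family}.
#' @export
stepwise_select <- function(data, response, smooth_candidates = character(),
                            factor_candidates = character(),
                            family = "auto", k = 4, method = "GCV.Cp",
                            delta = 2, check_collinearity = TRUE) {
  cands <- c(setNames(rep("smooth", length(smooth_candidates)),
                      smooth_candidates),
             setNames(rep("factor", length(factor_candidates)),
                      factor_candidates))
  if (!length(cands)) stop("need at least one candidate term")
  if (identical(family, "auto"))
    family <- choose_family(data[[response]][is.finite(data[[response]])])$family
  if (check_collinearity && length(cands) >= 2L)
    collinearity_diagnostics(data, names(cands))  # errors on constant terms

  fit_terms <- function(terms) {
    fit_additive_model(
      data, response,
      smooth_terms = terms[unname(cands[terms]) == "smooth"],
      factor_terms = terms[unname(cands[terms]) == "factor"],
      family = family, k = k, method = method,
      check_collinearity = FALSE)
  }
  null_fit <- fit_terms(character(0))
  current <- character(0)
  current_fit <- null_fit
  trace <- data.frame(step = "start", term = "(intercept)",
                      aic = null_fit$aic, accepted = TRUE,
                      stringsAsFactors = FALSE)

  repeat {  # forward
    remaining <- setdiff(names(cands), current)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(tm)
      tryCatch(fit_terms(c(current, tm))$aic, error = function(e) Inf),
      numeric(1L))
    best <- remaining[which.min(aics)]
    accepted <- min(aics) < current_fit$aic - delta
    trace <- rbind(trace, data.frame(step = "forward", term = best,
                                     aic = min(aics), accepted = accepted,
                                     stringsAsFactors = FALSE))
    if (!accepted) break
    current <- c(current, best)
    current_fit <- fit_terms(current)
  }
  repeat {  # backward
    if (length(current) < 1L) break
    aics <- vapply(current, function(tm)
      tryCatch(fit_terms(setdiff(current, tm))$aic, error = function(e) Inf),
      numeric(1L))
    worst <- current[which.min(aics)]
    accepted <- min(aics) < current_fit$aic - delta
    trace <- rbind(trace, data.frame(step = "backward", term = worst,
                                     aic = min(aics), accepted = accepted,
                                     stringsAsFactors = FALSE))
    if (!accepted) break
    current <- setdiff(current, worst)
    current_fit <- fit_terms(current)
  }
  if (!is.finite(current_fit$aic)) stop("all candidate models failed to fit")
  structure(list(best = current_fit, trace = trace, family = family,
                 selected = current),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat("Stepwise AIC selection [", x$family, "]\n", sep = "")
  cat("  selected terms:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$best)
  invisible(x)
}
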