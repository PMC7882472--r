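# Statistical protocol: [0,1] standardization, Gaussian and binomial fits,
# AICc, all-subsets enumeration under marginality, Delta < 6 candidate sets,
# conditional model averaging, importance counts, VIF.
#
# Term labels: L = % arable land (landscape composition), S = fragment size
# class (small = 0, large = 1), C = log10 connectivity, R = species-richness
# covariate; interactions "L:C", "S:C", "L:S".

#' Standardize a numeric vector to the unit interval
#'
#' Maps the minimum to 0 and the maximum to 1 linearly:
#' \eqn{(x - \min x) / (\max x - \min x)}. Affine transformations of the
#' input leave the output unchanged.
#'
#' @param x numeric vector with \code{max(x) > min(x)}.
#' @return Vector in [0, 1].
#' @export
standardize01 <- function(x) {
  r <- range(x)
  if (!all(is.finite(r)))
    stop("standardize01(): input must be finite", call. = FALSE)
  if (r[1] == r[2])
    stop("standardize01(): constant vector cannot be standardized",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

# design matrix (no intercept column) for a term vector; interactions are
# products of the parent columns
build_design <- function(terms, data) {
  if (!length(terms))
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(data))
    if (length(miss))
      stop("term '", tm, "' refers to missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

new_fit <- function(model, terms, family, n, converged = TRUE) {
  sm <- summary(model)
  co <- coef(sm)
  ll <- logLik(model)
  k <- attr(ll, "df")  # glm: p; lm: p + 1 (residual variance counts)
  # predictors were fitted under safe internal names .t1, .t2, ...;
  # restore the user-facing term labels (which may contain ":")
  lab <- rownames(co)
  for (i in seq_along(terms))
    lab[lab == paste0(".t", i)] <- terms[i]
  structure(list(
    terms = terms,
    family = family,
    coefficients = data.frame(term = lab,
                              estimate = co[, 1], se = co[, 2],
                              row.names = NULL, stringsAsFactors = FALSE),
    loglik = as.numeric(ll),
    k = k,
    n = n,
    # AICc is undefined when n - k - 1 <= 0 (tiny analytic fixtures);
    # such fits are usable on their own but not for model comparison
    aicc = tryCatch(aicc(as.numeric(ll), k, n), error = function(e) NA_real_),
    converged = converged,
    model = model
  ), class = "fw_fit")
}

#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf("%s fit [%s]: k = %d, n = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$family,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$k, x$n, x$loglik, x$aicc,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

check_rank <- function(x) {
  xx <- cbind(`(Intercept)` = 1, x)
  qr_ <- qr(xx)
  if (qr_$rank < ncol(xx)) {
    aliased <- colnames(xx)[qr_$pivot[-seq_len(qr_$rank)]]
    stop("rank-deficient design: aliased column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
}

#' Gaussian linear fit of a response on a design matrix
#'
#' Ordinary least squares with an intercept. The log-likelihood uses the
#' maximum-likelihood residual variance, and the parameter count k includes
#' the intercept, the slopes and the residual variance, so AICc values are
#' comparable with other implementations that count the variance.
#'
#' @param y numeric response.
#' @param x numeric design matrix (predictors only; the intercept is added),
#'   or NULL for the intercept-only model.
#' @param terms optional character labels for the model's terms.
#' @return An \code{fw_fit} object.
#' @export
fit_lm <- function(y, x = NULL, terms = colnames(x)) {
  if (is.null(x)) x <- matrix(numeric(0), length(y), 0)
  x <- as.matrix(x)
  if (length(y) <= ncol(x) + 1)
    stop("too few observations for ", ncol(x), " predictors", call. = FALSE)
  terms <- terms %||% character(0)
  check_rank(x)
  df <- data.frame(.y = y)
  if (ncol(x)) {
    xx <- as.data.frame(x)
    names(xx) <- paste0(".t", seq_len(ncol(x)))
    df <- cbind(df, xx)
  }
  model <- lm(.y ~ ., data = df)
  new_fit(model, terms, "gaussian", length(y))
}

#' Binomial (logit) fit of successes/trials on a design matrix
#'
#' Logistic regression by iteratively reweighted least squares. Fits that do
#' not converge or show symptoms of complete separation (fitted probabilities
#' at the boundary / runaway coefficients) are flagged with a warning and
#' \code{converged = FALSE}, and are excluded from model averaging.
#'
#' @param successes,trials integer vectors, \code{0 <= successes <= trials}.
#' @inheritParams fit_lm
#' @return An \code{fw_fit} object.
#' @export
fit_binom <- function(successes, trials, x = NULL, terms = colnames(x)) {
  stopifnot(all(successes >= 0), all(successes <= trials))
  if (is.null(x)) x <- matrix(numeric(0), length(successes), 0)
  x <- as.matrix(x)
  if (length(successes) < ncol(x) + 1)
    stop("too few observations for ", ncol(x), " predictors", call. = FALSE)
  terms <- terms %||% character(0)
  check_rank(x)
  df <- data.frame(.succ = successes, .fail = trials - successes)
  if (ncol(x)) {
    xx <- as.data.frame(x)
    names(xx) <- paste0(".t", seq_len(ncol(x)))
    df <- cbind(df, xx)
  }
  boundary <- FALSE
  model <- withCallingHandlers(
    glm(cbind(.succ, .fail) ~ . - .succ - .fail, family = binomial(),
        data = df, control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        boundary <<- TRUE
      invokeRestart("muffleWarning")
    })
  ok <- model$converged && !boundary && all(abs(coef(model)) < 15)
  if (!ok)
    warning("binomial fit flagged (separation or non-convergence): ",
            if (length(terms)) paste(terms, collapse = " + ") else "1",
            call. = FALSE)
  new_fit(model, terms %||% character(0), "binomial", length(successes),
          converged = ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\,\ell + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (including intercept and, for
#'   Gaussian models, the residual variance).
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 = ", n - k - 1, " <= 0", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All submodels of a global model, respecting marginality
#'
#' Enumerates every subset of the global model's terms (including the null,
#' intercept-only model) in which each interaction "A:B" appears only
#' together with both of its main effects. Free covariates (no interactions)
#' simply double the count. The default global model — three main effects,
#' their three two-way interactions and a free richness covariate — yields
#' 36 models (18 without the covariate).
#'
#' @param mains character vector of main-effect labels.
#' @param interactions character vector of "A:B" labels over \code{mains}.
#' @param covariates free main-effect terms not involved in interactions.
#' @return List of character vectors of terms, deterministically ordered by
#'   model size then term labels; the first element is the null model
#'   (length 0).
#' @export
enumerate_submodels <- function(mains = c("L", "S", "C"),
                                interactions = c("L:C", "S:C", "L:S"),
                                covariates = "R") {
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% mains))
      stop("interaction '", ia, "' violates marginality: both parents must ",
           "be main effects of the global model", call. = FALSE)
  }
  all_terms <- c(mains, interactions, covariates)
  n <- length(all_terms)
  models <- list()
  for (mask in 0:(2^n - 1)) {
    terms <- all_terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (ia in intersect(interactions, terms)) {
      parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% terms)) { ok <- FALSE; break }
    }
    if (ok) models[[length(models) + 1]] <- terms
  }
  ord <- order(lengths(models),
               vapply(models, function(t) paste(t, collapse = " "),
                      character(1)))
  models[ord]
}

#' Fit every submodel of a global model
#'
#' @param models list of term vectors (see \code{\link{enumerate_submodels}}).
#' @param data data frame holding the term columns and the response.
#' @param response for a Gaussian fit, \code{list(kind = "gaussian",
#'   var = <column>)}; for a binomial fit \code{list(kind = "binomial",
#'   successes = <column>, trials = <column>)}.
#' @return List of \code{fw_fit} objects, same order as \code{models}.
#' @export
fit_submodels <- function(models, data, response) {
  lapply(models, function(terms) {
    x <- build_design(terms, data)
    if (response$kind == "gaussian") {
      fit_lm(data[[response$var]], x, terms)
    } else {
      fit_binom(data[[response$successes]], data[[response$trials]], x, terms)
    }
  })
}

#' Best candidate models within six AICc units of the top model
#'
#' Computes \eqn{\Delta_i = AICc_i - \min AICc}, keeps models with
#' \eqn{\Delta_i < } \code{delta_threshold} (strict), and assigns Akaike
#' weights \eqn{w_i \propto e^{-\Delta_i/2}} renormalised over the kept set.
#' Flagged (non-converged) fits are dropped first with a warning. Ties in
#' AICc are broken by fewer terms, then lexicographic term order.
#'
#' @param fits list of \code{fw_fit} objects.
#' @param delta_threshold AICc gap defining the candidate set (default 6).
#' @return List of class \code{fw_candidates}: \code{fits}, \code{delta},
#'   \code{weight} (summing to 1), ordered by increasing AICc.
#' @export
candidate_set <- function(fits, delta_threshold = 6) {
  drop <- !vapply(fits, `[[`, logical(1), "converged")
  if (any(drop)) {
    warning(sum(drop), " flagged fit(s) excluded from the candidate set",
            call. = FALSE)
    fits <- fits[!drop]
  }
  if (!length(fits)) stop("no usable fits", call. = FALSE)
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  sz <- vapply(fits, function(f) length(f$terms), integer(1))
  lab <- vapply(fits, function(f) paste(f$terms, collapse = " "), character(1))
  ord <- order(a, sz, lab)
  fits <- fits[ord]; a <- a[ord]
  delta <- a - a[1]
  keep <- delta < delta_threshold
  fits <- fits[keep]; delta <- delta[keep]
  w <- exp(-delta / 2)
  structure(list(fits = fits, delta = delta, weight = w / sum(w)),
            class = "fw_candidates")
}

#' @export
print.fw_candidates <- function(x, ...) {
  cat("Candidate set:", length(x$fits), "models (Delta AICc <",
      format(max(x$delta) + 1e-9, digits = 3), ")\n")
  for (i in seq_along(x$fits))
    cat(sprintf("  %-30s Delta=%6.3f w=%.3f\n",
                if (length(x$fits[[i]]$terms))
                  paste(x$fits[[i]]$terms, collapse = " + ") else "(null)",
                x$delta[i], x$weight[i]))
  invisible(x)
}

#' Conditional model-averaged coefficients
#'
#' For each term, the Akaike weights of the candidate models containing that
#' term are renormalised and the coefficient is averaged over those models
#' only (conditional averaging, avoiding shrinkage towards zero). The
#' unconditional standard error combines within-model variance and
#' between-model spread,
#' \eqn{SE = \sum_m \tilde w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2}},
#' the 95\% CI is \eqn{\pm 1.96\, SE}, importance is the count of candidate
#' models containing the term, and significance codes come from a two-sided
#' normal test of \eqn{z = \bar\beta / SE}.
#'
#' @param candidates an \code{fw_candidates} object.
#' @return Data frame: term, importance, estimate, se, ci95 (half-width),
#'   z, p, signif; terms ordered canonically (mains, interactions, then
#'   others), intercept excluded.
#' @export
conditional_average <- function(candidates) {
  fits <- candidates$fits
  w <- candidates$weight
  terms <- unique(unlist(lapply(fits, `[[`, "terms")))
  if (!length(terms))
    return(data.frame(term = character(0), importance = integer(0),
                      estimate = numeric(0), se = numeric(0),
                      ci95 = numeric(0), z = numeric(0), p = numeric(0),
                      signif = character(0), stringsAsFactors = FALSE))
  rows <- lapply(terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% f$terms, logical(1))
    wt <- w[has] / sum(w[has])
    est <- vapply(fits[has], function(f)
      f$coefficients$estimate[f$coefficients$term == tm], numeric(1))
    se <- vapply(fits[has], function(f)
      f$coefficients$se[f$coefficients$term == tm], numeric(1))
    b <- sum(wt * est)
    se_avg <- sum(wt * sqrt(se^2 + (est - b)^2))
    z <- b / se_avg
    p <- 2 * pnorm(-abs(z))
    data.frame(term = tm, importance = sum(has), estimate = b, se = se_avg,
               ci95 = 1.96 * se_avg, z = z, p = p,
               signif = signif_code(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  canon <- c("L", "S", "C", "L:C", "S:C", "L:S", "R")
  out <- out[order(match(out$term, canon, nomatch = 99), out$term), ]
  rownames(out) <- NULL
  out
}

signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
}

#' Variance inflation factors of a design matrix
#'
#' Each predictor is regressed on all the others (with an intercept);
#' \eqn{VIF_p = 1/(1 - R_p^2)}. Perfect collinearity yields \code{Inf}.
#'
#' @param x numeric matrix with at least two predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("vif() needs at least two predictors", call. = FALSE)
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(x))
}

#' All-subsets AICc model selection with conditional averaging
#'
#' The full protocol for one response: enumerate every submodel of the global
#' model under marginality (null model included), fit each, form the
#' candidate set within 6 AICc units of the best model, and average
#' coefficients conditionally. Also reports the full model's fit quality
#' (multiple R-squared for Gaussian responses; for binomial responses the
#' squared correlation between observed and fitted proportions, a pseudo
#' R-squared analogue) and the largest VIF of the global design.
#'
#' @inheritParams fit_submodels
#' @param mains,interactions,covariates global model structure, passed to
#'   \code{\link{enumerate_submodels}}.
#' @param delta_threshold AICc gap for the candidate set.
#' @return List of class \code{fw_selection}: \code{fits},
#'   \code{candidates}, \code{averaged} (the coefficient table),
#'   \code{r2_full}, \code{max_vif}, \code{response}.
#' @export
model_selection <- function(data, response,
                            mains = c("L", "S", "C"),
                            interactions = c("L:C", "S:C", "L:S"),
                            covariates = "R",
                            delta_threshold = 6) {
  models <- enumerate_submodels(mains, interactions, covariates)
  fits <- fit_submodels(models, data, response)
  cand <- candidate_set(fits, delta_threshold)
  avg <- conditional_average(cand)

  full_terms <- c(mains, interactions, covariates)
  full <- fits[[which(vapply(fits, function(f)
    setequal(f$terms, full_terms), logical(1)))[1]]]
  if (response$kind == "gaussian") {
    r2 <- summary(full$model)$r.squared
  } else {
    obs <- data[[response$successes]] / data[[response$trials]]
    r2 <- cor(obs, full$model$fitted.values)^2
  }
  # VIF over the independent variables (mains + free covariates); product
  # interaction columns are collinear with their parents by construction and
  # are not what a variance-inflation screen is about
  x_vif <- build_design(c(mains, covariates), data)
  structure(list(fits = fits, candidates = cand, averaged = avg,
                 r2_full = r2, max_vif = max(vif(x_vif)),
                 response = response),
            class = "fw_selection")
}

#' @export
print.fw_selection <- function(x, ...) {
  nm <- if (x$response$kind == "gaussian") x$response$var else
    paste0(x$response$successes, "/", x$response$trials)
  cat(sprintf("Model selection for %s (%s): %d models, %d candidates, R2(full) = %.2f, max VIF = %.2f\n",
              nm, x$response$kind, length(x$fits),
              length(x$candidates$fits), x$r2_full, x$max_vif))
  tab <- x$averaged
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-5s imp=%2d  %8.3f +/- %.3f %s\n", tab$term[i],
                tab$importance[i], tab$estimate[i], tab$ci95[i],
                tab$signif[i]))
  invisible(x)
}
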