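# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementation.

oracle_entropy <- function(b) {
  B <- sum(b)
  h <- 0
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b))) {
    p <- b[i, j] / B
    if (p > 0) h <- h - p * log(p)
  }
  h
}

oracle_generality <- function(b) {
  B <- sum(b)
  g <- 0
  for (j in seq_len(ncol(b))) {
    cs <- sum(b[, j])
    if (cs == 0) next
    hj <- 0
    for (i in seq_len(nrow(b))) {
      p <- b[i, j] / cs
      if (p > 0) hj <- hj - p * log(p)
    }
    g <- g + (cs / B) * exp(hj)
  }
  g
}

oracle_vulnerability <- function(b) oracle_generality(t(b))

# random sparse non-negative web with at least one positive cell
random_web <- function(nr, nc, fill = 0.6) {
  b <- matrix(0, nr, nc)
  pos <- runif(nr * nc) < fill
  if (!any(pos)) pos[1] <- TRUE
  b[pos] <- rexp(sum(pos), rate = 0.2)
  rownames(b) <- paste0("P", seq_len(nr))
  colnames(b) <- paste0("Lh", seq_len(nc))
  b
}

# exhaustive marginality-respecting submodel enumeration via expand.grid
oracle_enumerate <- function(mains, interactions, covariates) {
  terms <- c(mains, interactions, covariates)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(terms)))
  names(grid) <- terms
  n_ok <- 0
  for (r in seq_len(nrow(grid))) {
    ok <- TRUE
    for (ia in interactions) {
      if (!grid[r, ia]) next
      parents <- strsplit(ia, ":", fixed = TRUE)[[1]]
      if (!all(unlist(grid[r, parents]))) ok <- FALSE
    }
    if (ok) n_ok <- n_ok + 1
  }
  n_ok
}

# small diet table with prescribed consumer classes, for covariate tests
fake_diet <- function(consumers, classes) {
  d <- data.frame(
    taxon = consumers,
    food_taxon = "Somehost plantum",
    food_rank = "species",
    monophagous = FALSE,
    habitat_condition = classes == "specialist",
    diet_condition = FALSE,
    identified_to_species = TRUE,
    stringsAsFactors = FALSE)
  class(d) <- c("fw_diet", "data.frame")
  d
}

# hand-rolled fw_fit stand-in for averaging/candidate-set arithmetic tests
fake_fit <- function(terms, aicc, est = NULL, se = NULL, converged = TRUE) {
  co <- data.frame(term = c("(Intercept)", terms),
                   estimate = c(0, est %||% rep(0, length(terms))),
                   se = c(0, se %||% rep(0, length(terms))),
                   stringsAsFactors = FALSE)
  structure(list(terms = terms, family = "gaussian", coefficients = co,
                 loglik = NA_real_, k = length(terms) + 2, n = 28,
                 aicc = aicc, converged = converged, model = NULL),
            class = "fw_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
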