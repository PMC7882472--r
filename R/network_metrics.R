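# Weighted bipartite web indices: Shannon interaction diversity, generality,
# vulnerability, linkage density (effective-number / Bersier-style forms).
#
# All entropies use natural logarithms with exp() for effective numbers;
# effective numbers are base-invariant, so base 2 with 2^H would give the
# same G, V and LD. Empty cells contribute nothing (0 * log 0 := 0).

web_matrix <- function(web) {
  b <- if (inherits(web, "quantitative_web")) web$b else as.matrix(web)
  if (!is.numeric(b) || any(b < 0))
    stop("web matrix must be numeric and non-negative", call. = FALSE)
  if (sum(b) <= 0)
    stop("empty web: total interaction weight is 0", call. = FALSE)
  b
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon diversity of interactions
#'
#' Entropy (in nats) of the distribution of interaction weights over the
#' web's cells: \eqn{H = -\sum p_{ij} \log p_{ij}} with
#' \eqn{p_{ij} = b_{ij}/B}.
#'
#' @param web a \code{quantitative_web} or a non-negative matrix.
#' @return H in nats; 0 for a single link, at most \eqn{\log} (number of
#'   positive cells).
#' @export
interaction_diversity <- function(web) {
  b <- web_matrix(web)
  shannon(b / sum(b))
}

#' Weighted generality
#'
#' Effective number of plant species per leafhopper species: the
#' abundance-weighted mean over consumers of the exponential of each
#' consumer's diet entropy,
#' \eqn{G = \sum_j (b_{\cdot j}/B)\, e^{H_j}}.
#'
#' @inheritParams interaction_diversity
#' @return G, between 1 and the number of plant rows.
#' @export
generality <- function(web) {
  b <- web_matrix(web)
  B <- sum(b)
  colsum <- colSums(b)
  keep <- colsum > 0
  sum(vapply(which(keep), function(j) {
    (colsum[j] / B) * exp(shannon(b[, j] / colsum[j]))
  }, numeric(1)))
}

#' Weighted vulnerability
#'
#' Row-wise mirror of \code{\link{generality}}: the effective number of
#' leafhopper species per plant species,
#' \eqn{V = \sum_i (b_{i\cdot}/B)\, e^{H_i}}.
#'
#' @inheritParams interaction_diversity
#' @export
vulnerability <- function(web) {
  b <- web_matrix(web)
  generality(t(b))
}

#' Weighted linkage density
#'
#' Effective links per species: the mean of weighted generality and weighted
#' vulnerability, \eqn{LD = (G + V)/2}.
#'
#' @inheritParams interaction_diversity
#' @export
linkage_density <- function(web) {
  b <- web_matrix(web)
  (generality(b) + vulnerability(b)) / 2
}

#' Model covariates of a web: richness and specialist/generalist counts
#'
#' @param web a \code{quantitative_web}.
#' @param diet an \code{fw_diet} data frame (for the specialist
#'   classification of the retained consumers).
#' @return List with \code{richness_covariate} (plants with a positive cell
#'   plus consumers in the web), \code{n_specialists}, \code{n_generalists}.
#' @export
web_covariates <- function(web, diet) {
  b <- web_matrix(web)
  info <- diet_summary(diet)
  cls <- info$class[match(colnames(b), info$taxon)]
  if (anyNA(cls))
    stop("consumer(s) without specialist/generalist classification: ",
         paste(colnames(b)[is.na(cls)], collapse = ", "), call. = FALSE)
  list(
    richness_covariate = sum(rowSums(b) > 0) + ncol(b),
    n_specialists = sum(cls == "specialist"),
    n_generalists = sum(cls == "generalist")
  )
}

#' All web metrics of one fragment as a one-row data frame
#'
#' @inheritParams web_covariates
#' @return Data frame: fragment_id, H, G, V, LD, n_links, richness_covariate,
#'   n_specialists, n_generalists.
#' @export
web_metrics <- function(web, diet) {
  b <- web_matrix(web)
  cov <- web_covariates(web, diet)
  data.frame(
    fragment_id = web$fragment_id,
    H = interaction_diversity(b),
    G = generality(b),
    V = vulnerability(b),
    LD = linkage_density(b),
    n_links = sum(b > 0),
    richness_covariate = cov$richness_covariate,
    n_specialists = cov$n_specialists,
    n_generalists = cov$n_generalists,
    stringsAsFactors = FALSE
  )
}
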