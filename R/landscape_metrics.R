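# Incidence-function patch connectivity and design-variable independence.

#' Parameters of the incidence-function connectivity index
#'
#' The index of a focal patch is
#' \eqn{S_i = \sum_{j \ne i,\ d_{ij} \le radius} e^{-\alpha d_{ij}}
#' (a \cdot A_j)^\beta}, summed over all other habitat patches within the
#' radius, with centroid Euclidean distances \eqn{d_{ij}} in metres.
#'
#' \code{area_scale} (\eqn{a}) converts the patch areas in the table to the
#' unit used inside the index: 1 applies the formula to the areas exactly as
#' supplied (hectares), 1e4 expresses them in square metres. The magnitude of
#' published index values depends on this convention; index ranges of order
#' 20-849 over a 2000 m radius correspond to areas in square metres.
#'
#' @param alpha distance-decay rate, 1/metres.
#' @param beta area exponent (dimensionless).
#' @param radius search radius in metres.
#' @param area_scale factor applied to areas before the exponent.
#' @return List of class \code{fw_conn_params}.
#' @export
connectivity_params <- function(alpha = 0.001, beta = 0.5, radius = 2000,
                                area_scale = 1) {
  stopifnot(alpha > 0, radius > 0, area_scale > 0)
  structure(list(alpha = alpha, beta = beta, radius = radius,
                 area_scale = area_scale), class = "fw_conn_params")
}

#' Connectivity index of one focal patch
#'
#' @param focal id of the focal patch (present in \code{patches$id}).
#' @param patches data frame with columns id, x_m, y_m, area_ha.
#' @param params a \code{\link{connectivity_params}} object.
#' @return The non-negative index \eqn{S_i}; 0 when no other patch lies
#'   within the radius.
#' @examples
#' p <- data.frame(id = c("f", "n"), x_m = c(0, 1000), y_m = 0,
#'                 area_ha = c(1, 4))
#' connectivity("f", p)  # exp(-1) * sqrt(4) = 0.7357589
#' @export
connectivity <- function(focal, patches, params = connectivity_params()) {
  stopifnot(all(c("id", "x_m", "y_m", "area_ha") %in% names(patches)))
  if (!focal %in% patches$id)
    stop("focal patch '", focal, "' not found in the patch table",
         call. = FALSE)
  if (any(patches$area_ha <= 0) || any(!is.finite(patches$x_m)) ||
      any(!is.finite(patches$y_m)))
    stop("patches must have positive areas and finite coordinates",
         call. = FALSE)
  f <- patches[match(focal, patches$id), ]
  other <- patches[patches$id != focal, , drop = FALSE]
  d <- sqrt((other$x_m - f$x_m)^2 + (other$y_m - f$y_m)^2)
  inr <- d <= params$radius
  sum(exp(-params$alpha * d[inr]) *
        (params$area_scale * other$area_ha[inr])^params$beta)
}

#' Connectivity index of every focal patch in a table
#'
#' @param patches data frame with id, x_m, y_m, area_ha and a logical
#'   \code{focal} column marking the study fragments.
#' @inheritParams connectivity
#' @return Named numeric vector, one index per focal patch.
#' @export
compute_connectivity <- function(patches, params = connectivity_params()) {
  foc <- patches$id[as.logical(patches$focal)]
  setNames(vapply(foc, connectivity, numeric(1), patches = patches,
                  params = params), foc)
}

#' Spearman correlations among the three design variables
#'
#' Checks the independence of the study design: fragment size class (coded
#' small = 0, large = 1), log10 connectivity and percent arable land, with
#' ties mid-ranked. A constant variable has no defined rank correlation and
#' is reported as NA with a warning.
#'
#' @param design data frame with columns size_class ("small"/"large" or 0/1),
#'   connectivity and arable_pct.
#' @return 3 x 3 symmetric matrix of Spearman's rho.
#' @export
design_check <- function(design) {
  stopifnot(nrow(design) >= 3)
  size <- if (is.numeric(design$size_class)) design$size_class else
    as.integer(design$size_class == "large")
  m <- cbind(size_class = size,
             log_connectivity = log10(design$connectivity),
             arable_pct = design$arable_pct)
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant design variable(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; Spearman's rho undefined (NA)", call. = FALSE)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho) <- 1
  rho
}
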