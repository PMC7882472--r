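# End-to-end orchestration: communities -> webs -> metrics -> models,
# with specimen accounting and a run manifest.

#' Run the full analysis pipeline on one study
#'
#' Builds each fragment's community and quantitative food web, computes the
#' weighted network indices, joins the design variables (standardized arable
#' L, size class S small = 0 / large = 1, standardized log10 connectivity C,
#' standardized richness covariate R), and runs all-subsets AICc model
#' selection with conditional averaging for the four responses: the
#' specialist/generalist richness ratio (binomial) and linkage density,
#' generality and interaction diversity (Gaussian).
#'
#' @param study a list with \code{surveys} (\code{fw_surveys}), \code{diet}
#'   (\code{fw_diet}) and \code{design}, as returned by
#'   \code{\link{generate_study}} or \code{\link{toy_study}}, or assembled
#'   from \code{\link{load_surveys}} / \code{\link{load_diet}} /
#'   \code{\link{load_design}}.
#' @param delta_threshold AICc gap defining candidate sets (default 6).
#' @param fit_models set FALSE to stop after the metrics table (useful for
#'   small fixtures with too few fragments to fit the global model).
#' @return Object of class \code{fw_pipeline}: \code{communities},
#'   \code{webs}, \code{metrics} (per-fragment table), \code{model_data},
#'   \code{selections} (one \code{fw_selection} per response),
#'   \code{design_rho} (Spearman matrix), and \code{manifest} with specimen
#'   accounting (pooled = retained B + excluded, checked exactly).
#' @export
run_pipeline <- function(study, delta_threshold = 6, fit_models = TRUE) {
  design <- study$design
  fragments <- design$fragment_id
  communities <- lapply(fragments, function(f)
    fragment_community(study$surveys, f))
  names(communities) <- fragments
  webs <- lapply(communities, build_web, diet = study$diet)

  metrics <- do.call(rbind, lapply(webs, web_metrics, diet = study$diet))
  rownames(metrics) <- NULL

  pooled_total <- sum(study$surveys$counts$count)
  retained_total <- sum(vapply(webs, `[[`, numeric(1), "B"))
  excluded_total <- sum(vapply(webs, function(w)
    sum(w$exclusion_log$specimens), numeric(1)))
  if (abs(pooled_total - retained_total - excluded_total) > 1e-6)
    stop("specimen accounting failed: pooled != retained + excluded",
         call. = FALSE)

  md <- merge(metrics, design, by = "fragment_id")
  md <- md[match(fragments, md$fragment_id), ]
  md$L <- standardize01(md$arable_pct)
  md$S <- as.integer(md$size_class == "large")
  md$C <- standardize01(log10(md$connectivity))
  md$R <- standardize01(md$richness_covariate)

  selections <- NULL
  if (fit_models) {
    md$trials <- md$n_specialists + md$n_generalists
    responses <- list(
      `Specialist/Generalist` = list(kind = "binomial",
                                     successes = "n_specialists",
                                     trials = "trials"),
      `Linkage density` = list(kind = "gaussian", var = "LD"),
      `Generality` = list(kind = "gaussian", var = "G"),
      `Interaction diversity` = list(kind = "gaussian", var = "H"))
    selections <- lapply(responses, function(r)
      model_selection(md, r, delta_threshold = delta_threshold))
  }

  manifest <- list(
    n_fragments = length(fragments),
    n_plant_taxa_recorded = length(unique(
      study$surveys$covers$taxon[!study$surveys$covers$taxon %in%
                                   c(BARE_GROUND, LITTER)])),
    n_consumer_taxa_caught = length(unique(study$surveys$counts$taxon)),
    n_consumer_taxa_retained = length(unique(unlist(
      lapply(webs, `[[`, "consumers")))),
    n_plant_taxa_in_webs = length(unique(unlist(
      lapply(webs, `[[`, "plants")))),
    total_links = sum(metrics$n_links),
    specimens_pooled = pooled_total,
    specimens_retained = retained_total,
    specimens_excluded = excluded_total,
    excluded_share = excluded_total / pooled_total,
    exclusions_by_rule = table(do.call(rbind, lapply(
      webs, `[[`, "exclusion_log"))$rule)
  )

  structure(list(communities = communities, webs = webs, metrics = metrics,
                 model_data = md, selections = selections,
                 design_rho = design_check(design), manifest = manifest),
            class = "fw_pipeline")
}

#' @export
print.fw_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Food-web pipeline run:\n")
  cat(sprintf("  %d fragments; %d plant taxa recorded, %d in webs\n",
              m$n_fragments, m$n_plant_taxa_recorded, m$n_plant_taxa_in_webs))
  cat(sprintf("  %d leafhopper taxa caught, %d retained\n",
              m$n_consumer_taxa_caught, m$n_consumer_taxa_retained))
  cat(sprintf("  %d specimens pooled = %.1f retained + %d excluded (%.1f%%)\n",
              m$specimens_pooled, m$specimens_retained,
              m$specimens_excluded, 100 * m$excluded_share))
  cat(sprintf("  %d links across all webs\n", m$total_links))
  if (!is.null(x$selections)) {
    cat("\n")
    for (nm in names(x$selections)) {
      cat(nm, ": ")
      print(x$selections[[nm]])
    }
  }
  invisible(x)
}

#' Model-averaged coefficient table in journal layout
#'
#' Stacks the conditional-averaging results of every response into one table
#' with the full-model fit quality, each term's importance (count of
#' candidate models containing it), the averaged estimate with its 95\% CI
#' half-width, and significance codes.
#'
#' @param pipeline an \code{fw_pipeline} with fitted selections.
#' @return Data frame: response, r2, term, importance, estimate, ci95,
#'   signif.
#' @export
model_table <- function(pipeline) {
  stopifnot(!is.null(pipeline$selections))
  rows <- lapply(names(pipeline$selections), function(nm) {
    sel <- pipeline$selections[[nm]]
    av <- sel$averaged
    data.frame(response = nm, r2 = sel$r2_full, term = av$term,
               importance = av$importance, estimate = av$estimate,
               ci95 = av$ci95, signif = av$signif,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a fragment design table
#'
#' If the table lacks a connectivity column, it is computed from the patch
#' table with \code{\link{compute_connectivity}}.
#'
#' @param path design CSV (fragment_id, size_class, area_ha, arable_pct,
#'   optionally connectivity).
#' @param patches_path optional patches CSV (id, x_m, y_m, area_ha, focal).
#' @param params \code{\link{connectivity_params}} used when connectivity
#'   must be computed.
#' @return Design data frame with a connectivity column.
#' @export
load_design <- function(path, patches_path = NULL,
                        params = connectivity_params()) {
  design <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment_id", "size_class", "area_ha", "arable_pct")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"connectivity" %in% names(design)) {
    if (is.null(patches_path))
      stop("design has no connectivity column and no patches file was given",
           call. = FALSE)
    patches <- load_patches(patches_path)
    conn <- compute_connectivity(patches, params)
    design$connectivity <- as.numeric(conn[design$fragment_id])
  }
  design
}

#' Load a patch geometry table
#'
#' @param path patches CSV with id, x_m, y_m, area_ha, focal.
#' @return Data frame.
#' @export
load_patches <- function(path) {
  patches <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_m", "y_m", "area_ha", "focal")
  miss <- setdiff(need, names(patches))
  if (length(miss))
    stop("patches schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  patches$focal <- as.logical(patches$focal)
  patches
}
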