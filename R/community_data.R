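# Survey tables, relative cover, pooling, specialist classification.
#
# Input schemas (UTF-8 CSV, header row required):
#   covers.csv: fragment_id, transect_id, taxon, cover_pct
#               (special taxa "_bare_ground" and "_litter" carry those covers)
#   counts.csv: fragment_id, transect_id, occasion, taxon, count
#   diet.csv:   taxon, food_taxon, food_rank, monophagous,
#               habitat_condition, diet_condition, identified_to_species

BARE_GROUND <- "_bare_ground"
LITTER <- "_litter"

#' Load and validate the transect survey tables
#'
#' Reads the plant cover and leafhopper count CSVs, validates them against the
#' survey schema and cross-references the two files. All validation problems
#' are collected and reported in a single error so a malformed pair of files
#' can be fixed in one pass.
#'
#' Plant covers are recorded once per transect (a single botanical plot);
#' leafhopper counts additionally carry a sampling occasion (1-3).
#'
#' @param cover_path path to the plant cover CSV.
#' @param counts_path path to the leafhopper count CSV.
#' @return An object of class \code{fw_surveys}: a list with data frames
#'   \code{covers} and \code{counts}, taxon names trimmed and case-preserved.
#' @export
load_surveys <- function(cover_path, counts_path) {
  covers <- read.csv(cover_path, stringsAsFactors = FALSE)
  counts <- read.csv(counts_path, stringsAsFactors = FALSE)
  problems <- character(0)

  need_cov <- c("fragment_id", "transect_id", "taxon", "cover_pct")
  need_cnt <- c("fragment_id", "transect_id", "occasion", "taxon", "count")
  miss <- setdiff(need_cov, names(covers))
  if (length(miss))
    problems <- c(problems, sprintf("covers: missing column(s) %s",
                                    paste(miss, collapse = ", ")))
  miss <- setdiff(need_cnt, names(counts))
  if (length(miss))
    problems <- c(problems, sprintf("counts: missing column(s) %s",
                                    paste(miss, collapse = ", ")))
  if (length(problems))
    stop("survey schema error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  covers$taxon <- trimws(covers$taxon)
  counts$taxon <- trimws(counts$taxon)

  bad <- which(!is.finite(covers$cover_pct) |
                 covers$cover_pct < 0 | covers$cover_pct > 100)
  if (length(bad))
    problems <- c(problems, sprintf(
      "covers row %d: cover_pct %s outside [0, 100]", bad,
      format(covers$cover_pct[bad])))

  cnt <- counts$count
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    problems <- c(problems, sprintf(
      "counts row %d: count %s is not a non-negative integer", bad,
      format(cnt[bad])))

  bad <- which(!counts$occasion %in% 1:3)
  if (length(bad))
    problems <- c(problems, sprintf(
      "counts row %d: occasion %s not in 1..3", bad,
      format(counts$occasion[bad])))

  unknown <- setdiff(unique(counts$fragment_id), unique(covers$fragment_id))
  if (length(unknown))
    problems <- c(problems, sprintf(
      "counts: fragment_id '%s' has no botanical records in covers", unknown))

  if (length(problems))
    stop("survey validation failed (", length(problems), " problem(s)):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  structure(list(covers = covers, counts = counts), class = "fw_surveys")
}

#' @export
print.fw_surveys <- function(x, ...) {
  cat("Transect surveys:",
      length(unique(x$covers$fragment_id)), "fragments,",
      nrow(unique(x$covers[c("fragment_id", "transect_id")])), "transects,",
      sum(x$counts$count), "leafhopper specimens\n")
  invisible(x)
}

#' Relative plant cover on one transect
#'
#' Divides each species' cover by the transect total of plant cover plus bare
#' ground plus litter, so that the relative covers of all plants together with
#' relative bare ground and litter sum to one.
#'
#' @param cover named numeric vector of per-species percent cover.
#' @param bare_ground,litter percent cover of bare ground and litter.
#' @return Named numeric vector of fractions, same names as \code{cover}.
#' @examples
#' relative_cover(c(Breiecta = 10, other = 30), bare_ground = 5, litter = 5)
#' @export
relative_cover <- function(cover, bare_ground = 0, litter = 0) {
  stopifnot(is.numeric(cover), bare_ground >= 0, litter >= 0)
  denom <- sum(cover) + bare_ground + litter
  if (denom <= 0)
    stop("degenerate transect: total plant + bare ground + litter cover is 0",
         call. = FALSE)
  cover / denom
}

#' Pool leafhopper counts within one fragment
#'
#' Sums individuals per species over the fragment's transects and sampling
#' occasions. Species never observed (total 0) are dropped.
#'
#' @param counts data frame with columns fragment_id, transect_id, occasion,
#'   taxon, count, all belonging to a single fragment.
#' @return Named integer vector of pooled abundances, positive entries only.
#' @export
pool_abundances <- function(counts) {
  if (length(unique(counts$fragment_id)) > 1)
    stop("pool_abundances() expects counts from a single fragment; got: ",
         paste(unique(counts$fragment_id), collapse = ", "), call. = FALSE)
  if (nrow(counts)) {
    seen <- sort(unique(counts$occasion))
    missing_occ <- setdiff(1:3, seen)
    if (length(missing_occ))
      warning(sprintf("fragment %s: no counts for occasion(s) %s; treated as zeros",
                      counts$fragment_id[1],
                      paste(missing_occ, collapse = ", ")), call. = FALSE)
  }
  tot <- tapply(counts$count, counts$taxon, sum)
  tot <- tot[tot > 0]
  if (!length(tot)) return(setNames(integer(0), character(0)))
  setNames(as.integer(tot), names(tot))
}

# Per-transect relative covers for one fragment, as a list keyed by transect.
transect_relative_covers <- function(covers) {
  split_tr <- split(covers, covers$transect_id)
  lapply(split_tr, function(tr) {
    special <- tr$taxon %in% c(BARE_GROUND, LITTER)
    plants <- tr[!special, , drop = FALSE]
    bg <- sum(tr$cover_pct[tr$taxon == BARE_GROUND])
    lit <- sum(tr$cover_pct[tr$taxon == LITTER])
    cov <- tapply(plants$cover_pct, plants$taxon, sum)
    relative_cover(setNames(as.numeric(cov), names(cov)), bg, lit)
  })
}

#' Summarise one fragment's plant and leafhopper community
#'
#' Computes the fragment's mean relative plant cover (the arithmetic mean over
#' transects of per-transect relative covers, with species absent from a
#' transect contributing 0), its plant species richness over the six botanical
#' plots, and the pooled leafhopper abundances.
#'
#' Relative cover is computed per transect first and then averaged
#' (mean-of-ratios); transects with zero total cover are dropped with a
#' warning, and an error is raised only if every transect is degenerate.
#'
#' @param surveys an \code{fw_surveys} object (or a list with \code{covers}
#'   and \code{counts} data frames).
#' @param fragment_id which fragment to summarise.
#' @return An object of class \code{fw_community}: list with
#'   \code{fragment_id}, \code{mean_relative_cover} (named fractions, positive
#'   entries only), \code{plant_richness}, \code{pooled_abundance}.
#' @export
fragment_community <- function(surveys, fragment_id) {
  covers <- surveys$covers[surveys$covers$fragment_id == fragment_id, ,
                           drop = FALSE]
  counts <- surveys$counts[surveys$counts$fragment_id == fragment_id, ,
                           drop = FALSE]
  if (!nrow(covers))
    stop("no botanical records for fragment ", fragment_id, call. = FALSE)

  rel <- vector("list", 0)
  n_degenerate <- 0
  for (tr in split(covers, covers$transect_id)) {
    res <- tryCatch(transect_relative_covers(tr)[[1]],
                    error = function(e) NULL)
    if (is.null(res)) n_degenerate <- n_degenerate + 1 else
      rel[[length(rel) + 1]] <- res
  }
  if (!length(rel))
    stop("fragment ", fragment_id, ": all transects degenerate (zero cover)",
         call. = FALSE)
  if (n_degenerate)
    warning("fragment ", fragment_id, ": dropped ", n_degenerate,
            " degenerate transect(s)", call. = FALSE)

  taxa <- sort(unique(unlist(lapply(rel, names))))
  mat <- vapply(rel, function(r) {
    v <- setNames(numeric(length(taxa)), taxa)
    v[names(r)] <- r
    v
  }, numeric(length(taxa)))
  mat <- matrix(mat, nrow = length(taxa), dimnames = list(taxa, NULL))
  mean_rel <- rowMeans(mat)
  mean_rel <- mean_rel[mean_rel > 0]

  structure(list(
    fragment_id = fragment_id,
    mean_relative_cover = mean_rel,
    plant_richness = length(mean_rel),
    pooled_abundance = pool_abundances(counts)
  ), class = "fw_community")
}

#' @export
print.fw_community <- function(x, ...) {
  cat("Fragment", x$fragment_id, "community:", x$plant_richness,
      "plant species,", length(x$pooled_abundance), "leafhopper species,",
      sum(x$pooled_abundance), "specimens\n")
  invisible(x)
}

#' Classify a leafhopper as habitat specialist or generalist
#'
#' A species is a habitat specialist when it either (1) has specific habitat
#' requirements typical of calcareous grassland, or (2) feeds exclusively on
#' plants restricted to calcareous grassland. Either condition suffices.
#'
#' @param habitat_condition,diet_condition logical flags for the two
#'   conditions (vectorised).
#' @return Character vector, \code{"specialist"} or \code{"generalist"}.
#' @export
classify_specialist <- function(habitat_condition, diet_condition) {
  ifelse(habitat_condition | diet_condition, "specialist", "generalist")
}

#' Load and validate the diet database
#'
#' One row per (leafhopper taxon, food-plant taxon). A leafhopper whose food
#' plants are unknown is represented by a single row with an empty
#' \code{food_taxon}; \code{food_rank} is \code{"species"} or \code{"genus"}.
#'
#' @param path path to the diet CSV.
#' @return Data frame of class \code{fw_diet} with the input columns plus
#'   trimmed taxon names.
#' @export
load_diet <- function(path) {
  diet <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "food_taxon", "food_rank", "monophagous",
            "habitat_condition", "diet_condition", "identified_to_species")
  miss <- setdiff(need, names(diet))
  if (length(miss))
    stop("diet schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  diet$taxon <- trimws(diet$taxon)
  diet$food_taxon <- trimws(diet$food_taxon)
  for (fl in c("monophagous", "habitat_condition", "diet_condition",
               "identified_to_species"))
    diet[[fl]] <- as.logical(diet[[fl]])
  bad_rank <- diet$food_rank != "" & !diet$food_rank %in% c("species", "genus")
  if (any(bad_rank))
    stop("diet validation: food_rank must be 'species' or 'genus'; offending rows: ",
         paste(which(bad_rank), collapse = ", "), call. = FALSE)
  n_food <- tapply(diet$food_taxon != "", diet$taxon, sum)
  mono <- tapply(diet$monophagous, diet$taxon, any)
  bad <- names(n_food)[mono[names(n_food)] & n_food != 1]
  if (length(bad))
    stop("diet validation: monophagous taxa must list exactly one food taxon: ",
         paste(bad, collapse = ", "), call. = FALSE)
  class(diet) <- c("fw_diet", "data.frame")
  diet
}

#' Per-species summary of the diet database
#'
#' @param diet an \code{fw_diet} data frame (see \code{\link{load_diet}}).
#' @return Data frame with one row per leafhopper taxon: \code{taxon},
#'   \code{identified_to_species}, \code{diet_known}, \code{monophagous},
#'   \code{n_food_taxa} and \code{class}
#'   (\code{"specialist"}/\code{"generalist"}).
#' @export
diet_summary <- function(diet) {
  sp <- split(diet, diet$taxon)
  out <- do.call(rbind, lapply(sp, function(d) {
    n_food <- sum(d$food_taxon != "")
    data.frame(
      taxon = d$taxon[1],
      identified_to_species = all(d$identified_to_species),
      diet_known = n_food > 0,
      monophagous = any(d$monophagous),
      n_food_taxa = n_food,
      class = classify_specialist(any(d$habitat_condition),
                                  any(d$diet_condition)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Short species codes in the style of bipartite web plots
#'
#' First two letters of the genus plus first two letters of the specific
#' epithet (e.g. "Bromus erectus" -> "Brer"); name collisions are resolved by
#' appending a digit.
#'
#' @param taxa character vector of binomial names.
#' @return Character vector of codes, same length.
#' @export
species_codes <- function(taxa) {
  parts <- strsplit(taxa, "\\s+")
  code <- vapply(parts, function(p) {
    if (length(p) < 2) return(substr(p[1], 1, 4))
    paste0(substr(p[1], 1, 2), substr(p[2], 1, 2))
  }, character(1))
  # deduplicate with a numeric suffix, first occurrence keeps the bare code
  for (cd in unique(code[duplicated(code)])) {
    idx <- which(code == cd)
    code[idx[-1]] <- paste0(cd, seq_along(idx[-1]))
  }
  code
}
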