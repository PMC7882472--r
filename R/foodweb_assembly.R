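# Assembly of one quantitative plant-leafhopper web per fragment:
# exclusion rules, literature diet matching, proportional allocation.

#' Food plants of a consumer that are present in a fragment
#'
#' Matches a leafhopper's literature diet against the plants recorded in one
#' fragment. Species-rank diet entries match the exact plant taxon; genus-rank
#' entries match every recorded congeneric plant (the genus is compared
#' against the first word of the plant binomial). Only plants with positive
#' mean relative cover in the fragment are returned.
#'
#' @param consumer leafhopper taxon name.
#' @param diet an \code{fw_diet} data frame.
#' @param community an \code{fw_community} for the fragment.
#' @return Character vector of plant taxa (possibly empty).
#' @export
match_food_plants <- function(consumer, diet, community) {
  d <- diet[diet$taxon == consumer & diet$food_taxon != "", , drop = FALSE]
  if (!nrow(d))
    stop("match_food_plants() requires a consumer with known diet: ",
         consumer, call. = FALSE)
  plants <- names(community$mean_relative_cover)
  genera <- vapply(strsplit(plants, "\\s+"), `[`, character(1), 1)
  hits <- character(0)
  for (i in seq_len(nrow(d))) {
    if (d$food_rank[i] == "species") {
      hits <- c(hits, plants[plants == d$food_taxon[i]])
    } else {
      hits <- c(hits, plants[genera == d$food_taxon[i]])
    }
  }
  unique(hits)
}

#' Apply the three exclusion rules to a fragment's leafhopper community
#'
#' Rule 1 drops taxa not identified to species level; rule 2 drops taxa whose
#' food plants are unknown at species or genus rank. Both are global
#' properties of the diet database. Rule 3 is fragment-specific: it drops taxa
#' none of whose food plants were recorded on the fragment's transects.
#'
#' @param community an \code{fw_community}.
#' @param diet an \code{fw_diet} data frame.
#' @return List with \code{retained} (named abundance vector),
#'   \code{food_plants} (list keyed by retained taxon) and \code{log}
#'   (data frame taxon / rule / specimens, one row per excluded taxon).
#' @export
apply_exclusions <- function(community, diet) {
  ab <- community$pooled_abundance
  info <- diet_summary(diet)
  missing <- setdiff(names(ab), info$taxon)
  if (length(missing))
    stop("taxa in counts absent from the diet database: ",
         paste(missing, collapse = ", "),
         " (add explicit rows, with empty food_taxon if diet is unknown)",
         call. = FALSE)
  info <- info[match(names(ab), info$taxon), ]

  log <- data.frame(taxon = character(0), rule = character(0),
                    specimens = integer(0), stringsAsFactors = FALSE)
  note <- function(taxon, rule) {
    log[nrow(log) + 1L, ] <<- list(taxon, rule, unname(ab[taxon]))
  }

  keep <- rep(TRUE, length(ab))
  for (i in seq_along(ab)) {
    tx <- names(ab)[i]
    if (!info$identified_to_species[i]) {
      note(tx, "unidentified"); keep[i] <- FALSE
    } else if (!info$diet_known[i]) {
      note(tx, "diet_unknown"); keep[i] <- FALSE
    }
  }
  food <- list()
  for (tx in names(ab)[keep]) {
    fp <- match_food_plants(tx, diet, community)
    if (!length(fp)) {
      note(tx, "no_food_plant_here")
      keep[names(ab) == tx] <- FALSE
    } else {
      food[[tx]] <- fp
    }
  }
  list(retained = ab[keep], food_plants = food, log = log)
}

#' Allocate a consumer's abundance over its available food plants
#'
#' A single available food plant (including the monophagy case) receives the
#' full abundance. With several, abundance is split proportionally to the
#' plants' mean relative covers, re-normalised over the matched plants only,
#' so the allocation always sums to the abundance exactly.
#'
#' @param abundance pooled specimen count (> 0).
#' @param covers named numeric vector: mean relative cover of each available
#'   food plant in the fragment.
#' @return Named numeric allocation vector summing to \code{abundance}.
#' @export
allocate_abundance <- function(abundance, covers) {
  stopifnot(abundance > 0, length(covers) >= 1)
  if (length(covers) == 1) return(setNames(as.numeric(abundance), names(covers)))
  s <- sum(covers)
  if (s <= 0)
    stop("allocation error: all matched food-plant covers are zero ",
         "(consumer should have been excluded upstream)", call. = FALSE)
  alloc <- abundance * covers / s
  # enforce exact conservation against float round-off
  alloc[which.max(alloc)] <- alloc[which.max(alloc)] +
    (abundance - sum(alloc))
  alloc
}

#' Build the quantitative food web of one fragment
#'
#' Applies the exclusion rules, then allocates every retained leafhopper's
#' pooled abundance over its food plants present in the fragment. Cell
#' \eqn{b_{ij}} holds the abundance of consumer \eqn{j} allocated to plant
#' \eqn{i}; allocations are continuous (no integer rounding).
#'
#' @param community an \code{fw_community}.
#' @param diet an \code{fw_diet} data frame.
#' @return Object of class \code{quantitative_web}: list with
#'   \code{fragment_id}, \code{plants}, \code{consumers}, matrix \code{b},
#'   total \code{B} and the \code{exclusion_log}.
#' @export
build_web <- function(community, diet) {
  ex <- apply_exclusions(community, diet)
  if (!length(ex$retained))
    stop("empty web: no consumer in fragment ", community$fragment_id,
         " survives the exclusion rules", call. = FALSE)
  consumers <- names(ex$retained)
  plants <- sort(unique(unlist(ex$food_plants)))
  b <- matrix(0, nrow = length(plants), ncol = length(consumers),
              dimnames = list(plants, consumers))
  for (tx in consumers) {
    fp <- ex$food_plants[[tx]]
    b[fp, tx] <- allocate_abundance(ex$retained[[tx]],
                                    community$mean_relative_cover[fp])
  }
  structure(list(
    fragment_id = community$fragment_id,
    plants = plants,
    consumers = consumers,
    b = b,
    B = sum(b),
    exclusion_log = ex$log
  ), class = "quantitative_web")
}

#' @export
print.quantitative_web <- function(x, ...) {
  cat("Quantitative web, fragment", x$fragment_id, ":",
      length(x$plants), "plants x", length(x$consumers), "leafhoppers,",
      sum(x$b > 0), "links, B =", format(x$B), "\n")
  if (nrow(x$exclusion_log))
    cat("  excluded:", nrow(x$exclusion_log), "taxa (",
        sum(x$exclusion_log$specimens), "specimens )\n")
  invisible(x)
}

#' Long-format edge list of a quantitative web
#'
#' @param web a \code{quantitative_web}.
#' @return Data frame fragment_id / plant / consumer / weight, positive cells
#'   only, ordered by consumer then plant.
#' @export
as_edgelist <- function(web) {
  idx <- which(web$b > 0, arr.ind = TRUE)
  out <- data.frame(
    fragment_id = web$fragment_id,
    plant = rownames(web$b)[idx[, 1]],
    consumer = colnames(web$b)[idx[, 2]],
    weight = web$b[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$consumer, out$plant), , drop = FALSE]
}

#' Rebuild a quantitative web from its edge list
#'
#' Inverse of \code{\link{as_edgelist}}; the round trip is lossless up to
#' row/column order (rows and columns are sorted alphabetically).
#'
#' @param edges data frame with fragment_id, plant, consumer, weight.
#' @return A \code{quantitative_web} (without an exclusion log).
#' @export
web_from_edgelist <- function(edges) {
  stopifnot(length(unique(edges$fragment_id)) == 1)
  plants <- sort(unique(edges$plant))
  consumers <- sort(unique(edges$consumer))
  b <- matrix(0, length(plants), length(consumers),
              dimnames = list(plants, consumers))
  b[cbind(match(edges$plant, plants), match(edges$consumer, consumers))] <-
    edges$weight
  structure(list(fragment_id = edges$fragment_id[1], plants = plants,
                 consumers = consumers, b = b, B = sum(b),
                 exclusion_log = data.frame(taxon = character(0),
                                            rule = character(0),
                                            specimens = integer(0))),
            class = "quantitative_web")
}

#' Write all webs as a single long-format edge list CSV
#'
#' @param webs list of \code{quantitative_web} objects.
#' @param path output CSV path.
#' @return The combined edge list, invisibly.
#' @export
write_web_edgelists <- function(webs, path) {
  all <- do.call(rbind, lapply(webs, as_edgelist))
  write.csv(all, path, row.names = FALSE)
  invisible(all)
}
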