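# Synthetic study generator: landscapes, plant communities, a literature-style
# diet database and leafhopper counts with a known ground-truth effect
# structure, so the full pipeline can be exercised and power-checked.
#
# The default configuration emulates the study design the package targets:
# 14 small (0.06-0.60 ha) and 14 large (1.24-8.76 ha) calcareous grassland
# fragments, connectivity indices spanning about 20-849 within a 2000 m
# radius, 27-77% arable land, a pool of 167 plant taxa and 67 retainable
# leafhopper taxa of which 29 are habitat specialists, with 66% / 24%
# monophagy among specialists / generalists and roughly 5% of specimens
# belonging to taxa hit by the three exclusion rules.

#' Configuration of the synthetic study generator
#'
#' @param n_small,n_large fragments per size class.
#' @param area_small,area_large area ranges (ha) of the two classes.
#' @param arable_range percent arable land range in the 500 m buffer.
#' @param connectivity_range target range of the connectivity index; the two
#'   endpoints are always realised exactly by one fragment each.
#' @param conn_params \code{\link{connectivity_params}} used both to realise
#'   and to recompute the index (areas enter in square metres).
#' @param n_plant_taxa size of the regional plant species pool.
#' @param n_consumer_taxa,n_specialists retainable leafhopper taxa and how
#'   many of them are habitat specialists.
#' @param n_unidentified,n_diet_unknown,n_no_food_plant extra taxa designed
#'   to hit exclusion rules 1, 2 and 3 respectively.
#' @param theta named ground-truth coefficients on the logit of the
#'   probability that a fragment occupant is a specialist species, over the
#'   standardized design: intercept, L, S, C, L:C, S:C, L:S. Defaults follow
#'   the effect structure the package is built to detect, dominated by a
#'   positive size-by-connectivity interaction.
#' @param monophagy named probabilities that a specialist / generalist is
#'   monophagous.
#' @param mean_consumer_richness mean number of retainable leafhopper species
#'   per fragment (Poisson).
#' @param abundance_mu named per-species mean specimen counts for
#'   specialists and generalists (negative binomial, overdispersed).
#' @param nb_size negative-binomial size (dispersion); smaller is noisier.
#' @param excluded_occ_prob,excluded_mu per-fragment occurrence probability
#'   and mean abundance of the exclusion-rule taxa (together these set the
#'   excluded-specimen share near 5\%).
#' @return List of class \code{fw_config}.
#' @export
synthetic_config <- function(n_small = 14, n_large = 14,
                             area_small = c(0.06, 0.60),
                             area_large = c(1.24, 8.76),
                             arable_range = c(27, 77),
                             connectivity_range = c(20, 849),
                             conn_params = connectivity_params(
                               alpha = 0.001, beta = 0.5, radius = 2000,
                               area_scale = 1e4),
                             n_plant_taxa = 167,
                             n_consumer_taxa = 67, n_specialists = 29,
                             n_unidentified = 1, n_diet_unknown = 4,
                             n_no_food_plant = 4,
                             theta = c(`(Intercept)` = -0.1, L = 0.03,
                                       S = -1.02, C = 0.10, `L:C` = -0.05,
                                       `S:C` = 1.13, `L:S` = 0),
                             monophagy = c(specialist = 0.66,
                                           generalist = 0.24),
                             mean_consumer_richness = 24,
                             abundance_mu = c(specialist = 14,
                                              generalist = 7),
                             nb_size = 1.5,
                             excluded_occ_prob = 0.2, excluded_mu = 6) {
  stopifnot(n_small > 0, n_large > 0,
            diff(area_small) > 0, diff(area_large) > 0,
            diff(arable_range) > 0, diff(connectivity_range) > 0,
            n_specialists <= n_consumer_taxa,
            all(monophagy >= 0 & monophagy <= 1))
  structure(as.list(environment()), class = "fw_config")
}

# deterministic sub-seed per generator stage, < 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(flora = 11, landscape = 23, diet = 37, community = 53)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

# --- plant species pool -----------------------------------------------------

FW_GENERA <- c(
  "Bromus", "Carex", "Festuca", "Brachypodium", "Salvia", "Plantago",
  "Sanguisorba", "Helianthemum", "Thymus", "Lotus", "Medicago", "Trifolium",
  "Centaurea", "Scabiosa", "Knautia", "Galium", "Potentilla", "Hippocrepis",
  "Ononis", "Linum", "Prunella", "Teucrium", "Pimpinella", "Ranunculus",
  "Leontodon", "Hieracium", "Campanula", "Euphorbia", "Gentiana", "Koeleria",
  "Briza", "Dactylis", "Poa", "Avenula", "Origanum", "Asperula", "Anthyllis",
  "Cirsium", "Achillea", "Leucanthemum")

FW_EPITHETS <- c(
  "erectus", "flacca", "caryophyllea", "ovina", "rupicola", "pinnatum",
  "pratensis", "media", "minor", "nummularium", "praecox", "corniculatus",
  "lupulina", "montanum", "scabiosa", "jacea", "columbaria", "arvensis",
  "verum", "mollugo", "neumanniana", "comosa", "repens", "catharticum",
  "grandiflora", "chamaedrys", "saxifraga", "bulbosus", "hispidus",
  "pilosella", "rotundifolia", "cyparissias", "verna", "macrantha",
  "glomerata", "angustifolia", "vulgare", "cynanchica", "vulneraria",
  "acaulon", "millefolium", "perennis", "campestris", "alpina")

# regional flora: names, fragment-occupancy probabilities, cover mean-logs
generate_flora <- function(config, seed) {
  set.seed(derive_seed(seed, "flora"))
  combos <- expand.grid(g = FW_GENERA, e = FW_EPITHETS,
                        stringsAsFactors = FALSE)
  pick <- combos[sample.int(nrow(combos), config$n_plant_taxa), ]
  name <- paste(pick$g, pick$e)
  z <- rnorm(config$n_plant_taxa, 0, 1.2)
  data.frame(
    taxon = name,
    genus = pick$g,
    occupancy = plogis(-0.8 + z),       # commonness across fragments
    meanlog_cover = 1 + 0.6 * z + rnorm(config$n_plant_taxa, 0, 0.3),
    stringsAsFactors = FALSE
  )
}

# --- landscape --------------------------------------------------------------

#' Generate the fragment design table and patch geometry
#'
#' Draws fragment areas by size class, arable percentages, and target
#' connectivity indices spanning the configured range (log-uniform, with the
#' two endpoints realised exactly), then places background grassland patches
#' around each focal fragment so that the incidence-function index computed
#' from the geometry equals the target. The three design variables are
#' rejection-sampled to pairwise |Spearman rho| < 0.3, mirroring an
#' orthogonal study design.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed (stage-specific sub-seed derived internally).
#' @return List with \code{design} (fragment_id, size_class, area_ha,
#'   arable_pct, connectivity, x_m, y_m) and \code{patches} (id, x_m, y_m,
#'   area_ha, focal).
#' @export
generate_landscape <- function(config, seed) {
  set.seed(derive_seed(seed, "landscape"))
  n <- config$n_small + config$n_large
  size_class <- c(rep("small", config$n_small), rep("large", config$n_large))
  area <- c(runif(config$n_small, config$area_small[1], config$area_small[2]),
            runif(config$n_large, config$area_large[1], config$area_large[2]))

  cr <- config$connectivity_range
  ok <- FALSE
  for (attempt in 1:500) {
    s_target <- exp(runif(n, log(cr[1]), log(cr[2])))
    s_target[sample.int(n, 2)] <- cr  # realise both endpoints exactly
    arable <- runif(n, config$arable_range[1], config$arable_range[2])
    rho <- design_check(data.frame(size_class = size_class,
                                   connectivity = s_target,
                                   arable_pct = arable))
    if (max(abs(rho[upper.tri(rho)])) < 0.3) { ok <- TRUE; break }
  }
  if (!ok)
    stop("could not draw design variables with pairwise |rho| < 0.3 in 500 ",
         "attempts; loosen the configuration", call. = FALSE)

  # focal fragments far apart on a grid so neighbourhoods do not overlap
  gx <- ((seq_len(n) - 1) %% 6) * 6000
  gy <- ((seq_len(n) - 1) %/% 6) * 6000
  id <- sprintf("F%02d", seq_len(n))
  pr <- config$conn_params

  patches <- data.frame(id = id, x_m = gx, y_m = gy, area_ha = area,
                        focal = TRUE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- sample(4:12, 1)
    d <- runif(k, 150, 1950)
    ang <- runif(k, 0, 2 * pi)
    a <- exp(runif(k, log(0.05), log(6)))
    raw <- sum(exp(-pr$alpha * d) * (pr$area_scale * a)^pr$beta)
    a <- a * (s_target[i] / raw)^(1 / pr$beta)  # scale areas to hit target
    patches <- rbind(patches, data.frame(
      id = sprintf("bg_%s_%02d", id[i], seq_len(k)),
      x_m = gx[i] + d * cos(ang), y_m = gy[i] + d * sin(ang),
      area_ha = a, focal = FALSE, stringsAsFactors = FALSE))
  }
  conn <- compute_connectivity(patches, pr)
  design <- data.frame(fragment_id = id, size_class = size_class,
                       area_ha = area, arable_pct = arable,
                       connectivity = as.numeric(conn[id]),
                       x_m = gx, y_m = gy, stringsAsFactors = FALSE)
  list(design = design, patches = patches)
}

# --- diet database ----------------------------------------------------------

# taxa outside the grassland flora; diets pointing here always trigger the
# "no food plant recorded here" rule
FW_OFFSITE_PLANTS <- c("Quercus robur", "Urtica dioica", "Fagus sylvatica",
                       "Acer campestre")

FW_CONSUMER_GENERA <- c(
  "Adarrus", "Turrutus", "Mocydia", "Neophilaenus", "Aphrodes", "Arthaldeus",
  "Doratura", "Eupteryx", "Zyginidia", "Psammotettix", "Ribautodelphax",
  "Eurysula", "Dicranotropis", "Javesella", "Kelisia", "Anoscopus",
  "Deltocephalus", "Errastunus", "Euscelis", "Jassargus", "Megophthalmus",
  "Philaenus", "Rhopalopyx", "Streptanus", "Verdanus", "Elymana",
  "Cicadula", "Macrosteles", "Graphocraerus", "Hesium", "Stenocranus",
  "Chlorita", "Emelyanoviana", "Eupelix", "Batracomorphus", "Agallia",
  "Anaceratagallia", "Forcipata")

FW_CONSUMER_EPITHETS <- c(
  "multinotatus", "socialis", "crocea", "lineatus", "makarovi", "pascuellus",
  "stylata", "notata", "scutellaris", "confinis", "collina", "obsoleta",
  "hamata", "pellucida", "guttula", "albifrons", "pulicaris", "ocellaris",
  "incisus", "pseudocellaris", "scanicus", "spumarius", "elegantula",
  "sordidulus", "abdominalis", "sulphurella", "persimilis", "laevis",
  "ventralis", "dolabratus", "minutus", "viridula", "mollicula", "depressa",
  "irroratus", "venosa", "ribauti", "forcipata", "striola", "quadrinotata")

#' Generate the literature-style diet database
#'
#' Builds one diet row per (leafhopper, food taxon). Core taxa are split into
#' habitat specialists and generalists; monophagous species (probability per
#' class from the configuration) list a single species-rank host drawn from
#' the commoner half of the flora, polyphagous species list 2-6 hosts of
#' mixed species/genus rank. Extra taxa are constructed to hit each exclusion
#' rule: not identified to species, diet unknown, or feeding on plants never
#' recorded in the study fragments.
#'
#' @inheritParams generate_landscape
#' @param flora internal flora table (regenerated from the seed if omitted).
#' @return An \code{fw_diet} data frame.
#' @export
generate_diet <- function(config, seed, flora = generate_flora(config, seed)) {
  set.seed(derive_seed(seed, "diet"))
  combos <- expand.grid(g = FW_CONSUMER_GENERA, e = FW_CONSUMER_EPITHETS,
                        stringsAsFactors = FALSE)
  n_core <- config$n_consumer_taxa
  n_extra <- config$n_unidentified + config$n_diet_unknown +
    config$n_no_food_plant
  pick <- combos[sample.int(nrow(combos), n_core + n_extra), ]
  names_all <- paste(pick$g, pick$e)

  core <- names_all[seq_len(n_core)]
  extra <- names_all[n_core + seq_len(n_extra)]
  unidentified <- if (config$n_unidentified)
    paste(pick$g[n_core + seq_len(config$n_unidentified)], "sp.") else
      character(0)
  diet_unknown <- extra[config$n_unidentified + seq_len(config$n_diet_unknown)]
  no_food <- extra[config$n_unidentified + config$n_diet_unknown +
                     seq_len(config$n_no_food_plant)]

  is_spec <- c(rep(TRUE, config$n_specialists),
               rep(FALSE, n_core - config$n_specialists))
  common <- flora[flora$occupancy >= stats::median(flora$occupancy), ]

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (i in seq_len(n_core)) {
    tx <- core[i]
    cls_spec <- is_spec[i]
    habitat <- if (cls_spec) runif(1) < 0.8 else FALSE
    dietc <- if (cls_spec) (!habitat || runif(1) < 0.3) else FALSE
    mono <- runif(1) < (if (cls_spec) config$monophagy[["specialist"]]
                        else config$monophagy[["generalist"]])
    if (mono) {
      host <- sample(common$taxon, 1, prob = common$occupancy)
      add(taxon = tx, food_taxon = host, food_rank = "species",
          monophagous = TRUE, habitat_condition = habitat,
          diet_condition = dietc, identified_to_species = TRUE)
    } else {
      k <- sample(2:6, 1)
      ranks <- ifelse(runif(k) < 0.3, "genus", "species")
      sp_hosts <- sample(flora$taxon, sum(ranks == "species"),
                         prob = flora$occupancy)
      gn_hosts <- sample(unique(flora$genus), sum(ranks == "genus"))
      hosts <- character(k)
      hosts[ranks == "species"] <- sp_hosts
      hosts[ranks == "genus"] <- gn_hosts
      for (j in seq_len(k))
        add(taxon = tx, food_taxon = hosts[j], food_rank = ranks[j],
            monophagous = FALSE, habitat_condition = habitat,
            diet_condition = dietc, identified_to_species = TRUE)
    }
  }
  for (tx in unidentified)
    add(taxon = tx, food_taxon = sample(common$taxon, 1),
        food_rank = "species", monophagous = FALSE,
        habitat_condition = FALSE, diet_condition = FALSE,
        identified_to_species = FALSE)
  for (tx in diet_unknown)
    add(taxon = tx, food_taxon = "", food_rank = "",
        monophagous = FALSE, habitat_condition = FALSE,
        diet_condition = FALSE, identified_to_species = TRUE)
  for (i in seq_along(no_food))
    add(taxon = no_food[i],
        food_taxon = FW_OFFSITE_PLANTS[1 + (i - 1) %% length(FW_OFFSITE_PLANTS)],
        food_rank = "species", monophagous = FALSE,
        habitat_condition = FALSE, diet_condition = FALSE,
        identified_to_species = TRUE)

  diet <- do.call(rbind, rows)
  attr(diet, "core_taxa") <- core
  attr(diet, "specialist_taxa") <- core[is_spec]
  class(diet) <- c("fw_diet", "data.frame")
  diet
}

# --- communities ------------------------------------------------------------

# P(an occupant species is a specialist) on the logit scale, over the
# standardized design
specialist_probability <- function(L, S, C, theta) {
  plogis(theta[["(Intercept)"]] + theta[["L"]] * L + theta[["S"]] * S +
           theta[["C"]] * C + theta[["L:C"]] * L * C +
           theta[["S:C"]] * S * C + theta[["L:S"]] * L * S)
}

#' Generate transect surveys for every fragment of a design
#'
#' Plant covers follow a log-normal abundance model thinned by fragment and
#' transect; leafhopper counts are overdispersed (negative binomial), with
#' the expected share of specialist species among a fragment's occupants
#' following the configured logit model over the standardized design
#' (arable L, size class S, log10 connectivity C). Exclusion-rule taxa are
#' sprinkled across fragments at the configured rate.
#'
#' @inheritParams generate_diet
#' @param design the design table from \code{\link{generate_landscape}}.
#' @param diet the diet database from \code{\link{generate_diet}}.
#' @return List with data frames \code{covers} and \code{counts} in the
#'   survey CSV schemas.
#' @export
generate_community <- function(design, config, seed,
                               flora = generate_flora(config, seed),
                               diet = generate_diet(config, seed, flora)) {
  set.seed(derive_seed(seed, "community"))
  L <- standardize01(design$arable_pct)
  C <- standardize01(log10(design$connectivity))
  S <- as.integer(design$size_class == "large")
  p_spec <- specialist_probability(L, S, C, config$theta)

  spec_taxa <- attr(diet, "specialist_taxa")
  core_taxa <- attr(diet, "core_taxa")
  gen_taxa <- setdiff(core_taxa, spec_taxa)
  excl_taxa <- setdiff(unique(diet$taxon), core_taxa)
  # commoner species occur in more fragments
  w_spec <- setNames(rlnorm(length(spec_taxa), 0, 0.8), spec_taxa)
  w_gen <- setNames(rlnorm(length(gen_taxa), 0, 0.8), gen_taxa)

  # consumers settle where their food plants grow: per-taxon host sets,
  # used to restrict each fragment's occupant pool
  dd <- diet[diet$taxon %in% core_taxa & diet$food_taxon != "", ]
  host_species <- split(dd$food_taxon[dd$food_rank == "species"],
                        dd$taxon[dd$food_rank == "species"])
  host_genera <- split(dd$food_taxon[dd$food_rank == "genus"],
                       dd$taxon[dd$food_rank == "genus"])

  cover_rows <- list()
  count_rows <- list()
  nb1 <- function(n, mu) 1 + rnbinom(n, mu = pmax(mu - 1, 0.1),
                                     size = config$nb_size)

  for (f in seq_len(nrow(design))) {
    fid <- design$fragment_id[f]

    # ---- plants: fragment pool, then per-transect covers
    present <- runif(nrow(flora)) < flora$occupancy
    if (sum(present) < 12)
      present[order(flora$occupancy, decreasing = TRUE)[1:12]] <- TRUE
    fl <- flora[present, ]
    for (tr in 1:6) {
      on_tr <- runif(nrow(fl)) < 0.75
      if (!any(on_tr)) on_tr[1] <- TRUE
      cov <- rlnorm(sum(on_tr), fl$meanlog_cover[on_tr], 0.5)
      cov <- cov * runif(1, 55, 95) / sum(cov)
      cover_rows[[length(cover_rows) + 1L]] <- data.frame(
        fragment_id = fid, transect_id = tr,
        taxon = c(fl$taxon[on_tr], "_bare_ground", "_litter"),
        cover_pct = c(cov, runif(1, 2, 12), runif(1, 2, 12)),
        stringsAsFactors = FALSE)
    }

    # ---- leafhoppers: richness, class split, abundances; only taxa with a
    # food plant in this fragment can settle
    genera_here <- unique(fl$genus)
    has_food <- vapply(core_taxa, function(tx)
      any(host_species[[tx]] %in% fl$taxon) ||
        any(host_genera[[tx]] %in% genera_here), logical(1))
    spec_pool <- intersect(core_taxa[has_food], spec_taxa)
    gen_pool <- intersect(core_taxa[has_food], gen_taxa)
    s_tot <- max(8, rpois(1, config$mean_consumer_richness))
    s_tot <- min(s_tot, length(spec_pool) + length(gen_pool))
    n_sp <- rbinom(1, s_tot, p_spec[f])
    n_sp <- min(max(n_sp, s_tot - length(gen_pool)), length(spec_pool))
    occupants <- c(
      sample(spec_pool, n_sp, prob = w_spec[spec_pool]),
      sample(gen_pool, s_tot - n_sp, prob = w_gen[gen_pool]))
    mu <- ifelse(occupants %in% spec_taxa,
                 config$abundance_mu[["specialist"]],
                 config$abundance_mu[["generalist"]])
    ab <- nb1(length(occupants), mu)

    # exclusion-rule taxa occur at the configured background rate
    hit <- excl_taxa[runif(length(excl_taxa)) < config$excluded_occ_prob]
    occupants <- c(occupants, hit)
    ab <- c(ab, nb1(length(hit), config$excluded_mu))

    for (i in seq_along(occupants)) {
      cells <- rmultinom(1, ab[i], rep(1, 18))[, 1]  # 6 transects x 3 occ.
      pos <- which(cells > 0)
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        fragment_id = fid,
        transect_id = ((pos - 1) %% 6) + 1,
        occasion = ((pos - 1) %/% 6) + 1,
        taxon = occupants[i],
        count = cells[pos],
        stringsAsFactors = FALSE)
    }
  }
  list(covers = do.call(rbind, cover_rows),
       counts = do.call(rbind, count_rows))
}

#' Generate a complete synthetic study
#'
#' One call produces everything the pipeline consumes: the fragment design
#' and patch geometry, the transect survey tables, the diet database, and a
#' ground-truth record. Fully deterministic given (config, seed); each stage
#' draws from its own derived sub-seed so stages can be regenerated
#' independently.
#'
#' @inheritParams generate_landscape
#' @param dir optional directory; when given, writes covers.csv, counts.csv,
#'   diet.csv, design.csv, patches.csv and truth.json there.
#' @return List of class \code{fw_study}: \code{design}, \code{patches},
#'   \code{surveys} (an \code{fw_surveys}), \code{diet}, \code{truth},
#'   \code{config}, \code{seed}.
#' @export
generate_study <- function(config = synthetic_config(), seed = 1,
                           dir = NULL) {
  flora <- generate_flora(config, seed)
  land <- generate_landscape(config, seed)
  diet <- generate_diet(config, seed, flora)
  comm <- generate_community(land$design, config, seed, flora, diet)
  surveys <- structure(list(covers = comm$covers, counts = comm$counts),
                       class = "fw_surveys")
  truth <- list(
    seed = seed,
    theta = as.list(config$theta),
    monophagy = as.list(config$monophagy),
    n_fragments = nrow(land$design),
    abundance_model = "1 + negative binomial(mu - 1, size)",
    cover_model = "log-normal, thinned by fragment and transect"
  )
  study <- structure(list(design = land$design, patches = land$patches,
                          surveys = surveys, diet = diet, truth = truth,
                          config = config, seed = seed),
                     class = "fw_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a synthetic study to CSV files plus truth.json
#'
#' @param study an \code{fw_study}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$surveys$covers, file.path(dir, "covers.csv"),
            row.names = FALSE)
  write.csv(study$surveys$counts, file.path(dir, "counts.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(study$diet), file.path(dir, "diet.csv"),
            row.names = FALSE)
  write.csv(study$design, file.path(dir, "design.csv"), row.names = FALSE)
  write.csv(study$patches, file.path(dir, "patches.csv"), row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Fast design-level simulation of the specialist/generalist ratio
#'
#' Skips the community layer entirely: draws a standardized design of n
#' fragments (L uniform, S Bernoulli(1/2), C uniform), per-fragment species
#' totals (trials) and specialist species counts (binomial with the
#' configured logit model). Used for parameter-recovery and power checks of
#' the statistical engine at large n.
#'
#' @param n number of fragments.
#' @param theta named coefficient vector as in \code{\link{synthetic_config}}.
#' @param trials_mean mean species richness per fragment.
#' @param seed integer seed.
#' @return Data frame with L, S, C, R (standardized richness), successes
#'   (specialist species), trials (all species).
#' @export
simulate_ratio_data <- function(n, theta, trials_mean = 22, seed = 1) {
  set.seed(as.integer(seed))
  L <- standardize01(runif(n))
  C <- standardize01(runif(n))
  S <- rbinom(n, 1, 0.5)
  trials <- pmax(rpois(n, trials_mean), 5)
  p <- specialist_probability(L, S, C, theta)
  successes <- rbinom(n, trials, p)
  data.frame(L = L, S = S, C = C, R = standardize01(trials),
             successes = successes, trials = trials)
}

#' Tiny deterministic three-fragment fixture
#'
#' A hand-built miniature study (3 fragments x 6 transects x 3 occasions,
#' 5 plant and 6 leafhopper taxa) exercising every assembly path: monophagy,
#' genus-rank diet matching, proportional allocation, and all three
#' exclusion rules. No randomness; identical on every call.
#'
#' @return An \code{fw_study}-shaped list with \code{surveys}, \code{diet},
#'   \code{design} (with precomputed connectivity) and \code{patches}.
#' @export
toy_study <- function() {
  plants <- c("Bromus erectus", "Carex flacca", "Carex caryophyllea",
              "Salvia pratensis", "Plantago media")
  grid <- expand.grid(fragment_id = c("T1", "T2", "T3"), transect_id = 1:6,
                      stringsAsFactors = FALSE)
  cover_rows <- lapply(seq_len(nrow(grid)), function(i) {
    fid <- grid$fragment_id[i]; tr <- grid$transect_id[i]
    # fragment T3 lacks Salvia; covers vary deterministically by transect
    tx <- if (fid == "T3") plants[-4] else plants
    base <- c(30, 12, 6, 8, 10)[seq_along(tx)]
    data.frame(fragment_id = fid, transect_id = tr,
               taxon = c(tx, "_bare_ground", "_litter"),
               cover_pct = c(base + tr, 5, 5), stringsAsFactors = FALSE)
  })
  covers <- do.call(rbind, cover_rows)

  consumers <- data.frame(
    taxon = c("Adarrus multinotatus", "Turrutus socialis",
              "Arthaldeus pascuellus", "Mocydia sp.",
              "Doratura stylata", "Eupteryx notata"),
    stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(c("T1", "T2", "T3"), function(fid) {
    do.call(rbind, lapply(1:3, function(occ) {
      data.frame(fragment_id = fid, transect_id = 1:6, occasion = occ,
                 taxon = rep(consumers$taxon, each = 6)[seq_len(36)],
                 count = rep(c(2, 1, 1, 1, 0, 1), times = 6),
                 stringsAsFactors = FALSE)
    }))
  }))
  counts <- counts[counts$count > 0, ]

  diet <- data.frame(
    taxon = c("Adarrus multinotatus",                    # monophagous
              "Turrutus socialis", "Turrutus socialis",  # genus feeder
              "Arthaldeus pascuellus", "Arthaldeus pascuellus",
              "Mocydia sp.",                             # rule 1
              "Doratura stylata",                        # rule 2
              "Eupteryx notata"),                        # rule 3
    food_taxon = c("Bromus erectus", "Carex", "Bromus",
                   "Salvia pratensis", "Plantago media",
                   "Bromus erectus", "", "Quercus robur"),
    food_rank = c("species", "genus", "genus", "species", "species",
                  "species", "", "species"),
    monophagous = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    habitat_condition = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE),
    diet_condition = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       FALSE),
    identified_to_species = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                              TRUE),
    stringsAsFactors = FALSE)
  class(diet) <- c("fw_diet", "data.frame")

  patches <- data.frame(
    id = c("T1", "T2", "T3", "bg1", "bg2", "bg3"),
    x_m = c(0, 10000, 20000, 800, 10600, 20500),
    y_m = c(0, 0, 0, 600, 800, 900),
    area_ha = c(0.3, 2.0, 5.0, 1.0, 4.0, 2.0),
    focal = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  pr <- connectivity_params(area_scale = 1e4)
  conn <- compute_connectivity(patches, pr)
  design <- data.frame(
    fragment_id = c("T1", "T2", "T3"),
    size_class = c("small", "large", "large"),
    area_ha = c(0.3, 2.0, 5.0),
    arable_pct = c(30, 50, 70),
    connectivity = as.numeric(conn[c("T1", "T2", "T3")]),
    stringsAsFactors = FALSE)

  list(surveys = structure(list(covers = covers, counts = counts),
                           class = "fw_surveys"),
       diet = diet, design = design, patches = patches)
}
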