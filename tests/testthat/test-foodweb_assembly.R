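# Exclusion rules, diet matching, proportional allocation, web assembly.

toy <- toy_study()
communities <- lapply(c("T1", "T2", "T3"), function(f)
  fragment_community(toy$surveys, f))
names(communities) <- c("T1", "T2", "T3")

test_that("diet matching respects taxon rank and fragment presence", {
  cm <- communities$T1
  # species-rank entry matches the exact plant
  expect_equal(match_food_plants("Adarrus multinotatus", toy$diet, cm),
               "Bromus erectus")
  # genus-rank entries match every recorded congener
  hits <- match_food_plants("Turrutus socialis", toy$diet, cm)
  expect_setequal(hits, c("Carex flacca", "Carex caryophyllea",
                          "Bromus erectus"))
  # known diet, but no listed plant recorded in the fragment
  expect_length(match_food_plants("Eupteryx notata", toy$diet, cm), 0)
})

test_that("the three exclusion rules each drop their taxon, with a log", {
  ex <- apply_exclusions(communities$T1, toy$diet)
  expect_setequal(ex$log$rule,
                  c("unidentified", "diet_unknown", "no_food_plant_here"))
  expect_equal(nrow(ex$log), 3)
  expect_equal(ex$log$specimens, rep(18L, 3))
  expect_setequal(names(ex$retained),
                  c("Adarrus multinotatus", "Turrutus socialis",
                    "Arthaldeus pascuellus"))

  # independent oracle: filter the pooled taxa by the three rules explicitly
  info <- diet_summary(toy$diet)
  keep <- character(0)
  for (tx in names(communities$T1$pooled_abundance)) {
    row <- info[info$taxon == tx, ]
    if (!row$identified_to_species) next
    if (!row$diet_known) next
    if (!length(match_food_plants(tx, toy$diet, communities$T1))) next
    keep <- c(keep, tx)
  }
  expect_setequal(names(ex$retained), keep)
})

test_that("a counted taxon missing from the diet database is a hard error", {
  cm <- communities$T1
  cm$pooled_abundance <- c(cm$pooled_abundance, `Unknownus ghostus` = 5L)
  expect_error(apply_exclusions(cm, toy$diet), "Unknownus ghostus")
})

test_that("allocation is proportional to cover, renormalised, conserving", {
  expect_equal(allocate_abundance(12, c(`Bromus erectus` = 0.4)),
               c(`Bromus erectus` = 12))
  expect_equal(allocate_abundance(10, c(a = 3, b = 1)), c(a = 7.5, b = 2.5))
  expect_equal(allocate_abundance(8, c(a = 2, b = 2, c = 2, d = 2)),
               c(a = 2, b = 2, c = 2, d = 2))
  expect_error(allocate_abundance(5, c(a = 0, b = 0)), "zero")
  # scale equivariance: multiplying covers by a constant changes nothing
  set.seed(11)
  cov <- setNames(runif(5), letters[1:5])
  expect_equal(allocate_abundance(37, cov), allocate_abundance(37, 10 * cov))
  expect_equal(sum(allocate_abundance(37, cov)), 37)
})

test_that("a single monophagous consumer gives a 1x1 web with B = abundance", {
  sv <- list(covers = data.frame(
    fragment_id = "F", transect_id = 1,
    taxon = c("Bromus erectus", "_bare_ground"), cover_pct = c(60, 40)),
    counts = data.frame(fragment_id = "F", transect_id = 1, occasion = 1:3,
                        taxon = "Adarrus multinotatus", count = c(4, 5, 3)))
  suppressWarnings(cm <- fragment_community(sv, "F"))
  web <- build_web(cm, toy$diet)
  expect_equal(dim(web$b), c(1, 1))
  expect_equal(web$B, 12)
})

test_that("web column sums equal retained pooled abundances (toy + synthetic)", {
  for (f in names(communities)) {
    web <- build_web(communities[[f]], toy$diet)
    expect_equal(colSums(web$b),
                 communities[[f]]$pooled_abundance[web$consumers],
                 tolerance = 1e-9)
    expect_true(all(colSums(web$b > 0) >= 1))
    expect_true(all(rowSums(web$b > 0) >= 1))
    expect_equal(sum(colSums(web$b)), sum(rowSums(web$b)), tolerance = 1e-9)
  }
  st <- generate_study(synthetic_config(n_small = 3, n_large = 3), seed = 5)
  for (f in st$design$fragment_id) {
    cm <- fragment_community(st$surveys, f)
    web <- build_web(cm, st$diet)
    expect_equal(colSums(web$b), cm$pooled_abundance[web$consumers],
                 tolerance = 1e-9)
  }
})

test_that("specimens are conserved: pooled = B + excluded, exactly", {
  for (f in names(communities)) {
    cm <- communities[[f]]
    web <- build_web(cm, toy$diet)
    expect_equal(web$B + sum(web$exclusion_log$specimens),
                 sum(cm$pooled_abundance))
  }
})

test_that("a fragment whose every consumer fails exclusion is an empty-web error", {
  sv <- list(covers = data.frame(
    fragment_id = "F", transect_id = 1,
    taxon = c("Salvia pratensis", "_litter"), cover_pct = c(50, 20)),
    counts = data.frame(fragment_id = "F", transect_id = 1, occasion = 1:3,
                        taxon = "Eupteryx notata", count = c(1, 2, 1)))
  suppressWarnings(cm <- fragment_community(sv, "F"))
  expect_error(build_web(cm, toy$diet), "empty web")
})

test_that("permuting community input order does not change the web", {
  cm <- communities$T2
  web1 <- build_web(cm, toy$diet)
  cm2 <- cm
  perm <- rev(seq_along(cm2$pooled_abundance))
  cm2$pooled_abundance <- cm2$pooled_abundance[perm]
  cm2$mean_relative_cover <-
    cm2$mean_relative_cover[rev(seq_along(cm2$mean_relative_cover))]
  web2 <- build_web(cm2, toy$diet)
  expect_equal(web1$B, web2$B)
  expect_equal(web1$b[web1$plants, sort(web1$consumers)],
               web2$b[web1$plants, sort(web2$consumers)])
})

test_that("edge-list export round-trips losslessly", {
  web <- build_web(communities$T2, toy$diet)
  edges <- as_edgelist(web)
  back <- web_from_edgelist(edges)
  expect_equal(back$b[web$plants, web$consumers], web$b)
  expect_equal(back$B, web$B)

  path <- file.path(tempdir(), "edges.csv")
  webs <- lapply(communities, build_web, diet = toy$diet)
  write_web_edgelists(webs, path)
  reread <- read.csv(path, stringsAsFactors = FALSE)
  t2 <- web_from_edgelist(reread[reread$fragment_id == "T2", ])
  expect_equal(t2$b[web$plants, web$consumers], web$b, tolerance = 1e-12)
})
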