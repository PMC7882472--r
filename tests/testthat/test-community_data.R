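# Survey loading/validation, relative cover, pooling, classification.

write_toy_csvs <- function(dir = tempdir()) {
  toy <- toy_study()
  cp <- file.path(dir, "covers.csv")
  np <- file.path(dir, "counts.csv")
  write.csv(toy$surveys$covers, cp, row.names = FALSE)
  write.csv(toy$surveys$counts, np, row.names = FALSE)
  list(covers = cp, counts = np, dir = dir)
}

test_that("load_surveys reads the toy fixture: 3 fragments x 6 transects", {
  p <- write_toy_csvs(tempdir())
  sv <- load_surveys(p$covers, p$counts)
  transects <- unique(sv$covers[c("fragment_id", "transect_id")])
  expect_equal(nrow(transects), 18)
  expect_setequal(unique(sv$covers$fragment_id), c("T1", "T2", "T3"))
})

test_that("validation names offending rows and aggregates all problems", {
  p <- write_toy_csvs(tempdir())
  covers <- read.csv(p$covers)
  covers$cover_pct[2] <- 105
  bad <- file.path(p$dir, "bad_covers.csv")
  write.csv(covers, bad, row.names = FALSE)
  expect_error(load_surveys(bad, p$counts), "row 2.*105")

  # a second problem in the counts file is reported in the same error
  counts <- read.csv(p$counts)
  counts$count[1] <- -3
  badc <- file.path(p$dir, "bad_counts.csv")
  write.csv(counts, badc, row.names = FALSE)
  err <- tryCatch(load_surveys(bad, badc), error = conditionMessage)
  expect_match(err, "105")
  expect_match(err, "-3")
  expect_match(err, "2 problem")
})

test_that("schema and cross-reference errors are raised", {
  p <- write_toy_csvs(tempdir())
  covers <- read.csv(p$covers)
  names(covers)[4] <- "cover"
  bad <- file.path(p$dir, "schema_covers.csv")
  write.csv(covers, bad, row.names = FALSE)
  expect_error(load_surveys(bad, p$counts), "missing column")

  counts <- read.csv(p$counts)
  counts$fragment_id[1] <- "T99"
  badc <- file.path(p$dir, "xref_counts.csv")
  write.csv(counts, badc, row.names = FALSE)
  expect_error(load_surveys(p$covers, badc), "T99")
})

test_that("relative cover follows cover / (plants + bare + litter)", {
  rc <- relative_cover(c(A = 10, B = 30), bare_ground = 5, litter = 5)
  expect_equal(rc[["A"]], 0.2)
  expect_equal(relative_cover(c(A = 0, B = 50))[["A"]], 0)
  expect_error(relative_cover(c(A = 0), 0, 0), "degenerate")
})

test_that("relative covers and bare/litter shares sum to one (property)", {
  set.seed(41)
  for (rep in 1:20) {
    cov <- setNames(runif(8, 0, 30), paste0("sp", 1:8))
    bg <- runif(1, 0, 20); lit <- runif(1, 0, 20)
    rc <- relative_cover(cov, bg, lit)
    denom <- sum(cov) + bg + lit
    expect_equal(unname(rc), unname(cov / denom), tolerance = 1e-14)
    expect_equal(sum(rc) + (bg + lit) / denom, 1, tolerance = 1e-12)
  }
})

test_that("pooling sums over transects and occasions, dropping zeros", {
  one <- data.frame(fragment_id = "F", transect_id = 1, occasion = 1,
                    taxon = "A", count = 3)
  expect_warning(pa <- pool_abundances(one), "occasion")
  expect_equal(pa, c(A = 3L))

  zero <- rbind(one, data.frame(fragment_id = "F", transect_id = 2,
                                occasion = 1, taxon = "B", count = 0))
  expect_warning(pa <- pool_abundances(zero), "occasion")
  expect_false("B" %in% names(pa))

  expect_error(pool_abundances(data.frame(
    fragment_id = c("F", "G"), transect_id = 1, occasion = 1,
    taxon = "A", count = 1)), "single fragment")
})

test_that("pooled totals match brute-force summation and are order-independent", {
  set.seed(7)
  grid <- expand.grid(transect_id = 1:6, occasion = 1:3,
                      taxon = c("A", "B", "C"))
  grid$fragment_id <- "F"
  grid$count <- rpois(nrow(grid), 3)
  pooled <- pool_abundances(grid)
  for (tx in names(pooled)) {
    tot <- 0
    for (r in seq_len(nrow(grid)))
      if (grid$taxon[r] == tx) tot <- tot + grid$count[r]
    expect_equal(unname(pooled[tx]), tot)
  }
  shuffled <- grid[sample(nrow(grid)), ]
  expect_equal(pool_abundances(shuffled), pooled)
})

test_that("fragment community averages per-transect relative covers", {
  sv <- list(covers = data.frame(
    fragment_id = "F", transect_id = rep(1:2, each = 2),
    taxon = c("X", "_bare_ground", "Y", "_bare_ground"),
    cover_pct = c(20, 80, 50, 50)),
    counts = data.frame(fragment_id = character(0), transect_id = integer(0),
                        occasion = integer(0), taxon = character(0),
                        count = integer(0)))
  cm <- fragment_community(sv, "F")
  # X: rel 0.2 on transect 1, absent (0) on transect 2 -> mean 0.1
  expect_equal(cm$mean_relative_cover[["X"]], 0.1)
  expect_equal(cm$plant_richness, 2)
})

test_that("identical transects give the single-transect relative cover", {
  toy <- toy_study()
  cov1 <- toy$surveys$covers[toy$surveys$covers$fragment_id == "T1" &
                               toy$surveys$covers$transect_id == 1, ]
  sv <- list(covers = do.call(rbind, lapply(1:4, function(tr) {
    cov1$transect_id <- tr; cov1
  })), counts = toy$surveys$counts[0, ])
  cm <- fragment_community(sv, "T1")
  plants <- cov1[!cov1$taxon %in% c("_bare_ground", "_litter"), ]
  expected <- plants$cover_pct / sum(cov1$cover_pct)
  expect_equal(unname(cm$mean_relative_cover[plants$taxon]), expected)
})

test_that("fixture fragment community equals an explicit-loop oracle", {
  toy <- toy_study()
  cm <- fragment_community(toy$surveys, "T2")
  covers <- toy$surveys$covers[toy$surveys$covers$fragment_id == "T2", ]
  taxa <- setdiff(unique(covers$taxon), c("_bare_ground", "_litter"))
  for (tx in taxa) {
    acc <- 0
    for (tr in 1:6) {
      sl <- covers[covers$transect_id == tr, ]
      denom <- sum(sl$cover_pct)
      cv <- sl$cover_pct[sl$taxon == tx]
      acc <- acc + (if (length(cv)) cv / denom else 0)
    }
    expect_equal(cm$mean_relative_cover[[tx]], acc / 6, tolerance = 1e-12)
  }
  cnt <- toy$surveys$counts[toy$surveys$counts$fragment_id == "T2", ]
  expect_equal(sum(cm$pooled_abundance), sum(cnt$count))
})

test_that("specialist classification is condition (1) OR condition (2)", {
  expect_equal(classify_specialist(TRUE, FALSE), "specialist")
  expect_equal(classify_specialist(FALSE, TRUE), "specialist")
  expect_equal(classify_specialist(FALSE, FALSE), "generalist")
  expect_equal(classify_specialist(TRUE, TRUE), "specialist")
  # total: every combination receives exactly one of the two labels
  lab <- classify_specialist(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(lab %in% c("specialist", "generalist")))
})

test_that("species codes take two letters of genus and epithet, deduplicated", {
  cd <- species_codes(c("Bromus erectus", "Brachypodium pinnatum",
                        "Bromus erectus subsp.", "Briza media"))
  expect_equal(cd[1], "Brer")
  expect_equal(cd[2], "Brpi")
  expect_equal(cd[3], "Brer1")  # collision gets a digit
  expect_equal(cd[4], "Brme")
})
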