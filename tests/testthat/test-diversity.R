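test_that("samples are unique date x rounded-location combinations", {
  rec <- dplyr::bind_rows(
    make_records(c("a", "a"), lat = 10.00001, lon = 120, depth = 5),
    make_records("b", lat = 10.00001, lon = 120, date = as.Date("2010-06-02")),
    make_records("c", lat = 10.000049, lon = 120) # merges at 4 dp
  )
  s <- build_samples(rec)
  expect_equal(nrow(s), 2)
  s1 <- s[s$event_date == as.Date("2010-06-01"), ]
  expect_setequal(s1$species[[1]], c("a", "c"))
  expect_equal(s1$n_records, 3)
  # dateless records are excluded and counted
  rec$event_date[1] <- NA
  s2 <- build_samples(rec)
  expect_equal(attr(s2, "n_dateless"), 1)
  expect_equal(sum(s2$n_records), 3)
})

test_that("closed-form rarefaction reproduces the worked 3-sample case", {
  # samples {A}, {A,B}, {A}; all C(3,2) = 3 pairs hold 2, 1, 2 species
  inc <- inc_from_sets(list("A", c("A", "B"), "A"))
  expect_equal(rarefied_richness(inc, m = 2), 5 / 3, tolerance = 1e-12)
  # m = N returns S_obs exactly
  expect_equal(rarefied_richness(inc, m = 3), 2, tolerance = 1e-12)
  # m > N is missing, not an error
  expect_true(is.na(rarefied_richness(inc, m = 4)))
  expect_error(rarefied_richness(inc, m = 0), class = "hexrich_domain_error")
})

test_that("closed form equals exhaustive enumeration for all small cases", {
  set.seed(7)
  pool <- LETTERS[1:6]
  for (case in 1:40) {
    n_samp <- sample(2:8, 1)
    sets <- replicate(
      n_samp,
      sample(pool, sample(1:4, 1), replace = FALSE),
      simplify = FALSE
    )
    inc <- inc_from_sets(sets)
    for (m in unique(c(1, 2, n_samp - 1, n_samp))) {
      if (m < 1 || m > n_samp) next
      expect_equal(
        rarefied_richness(inc, m = m),
        enumerate_rarefaction(sets, m),
        tolerance = 1e-10
      )
    }
  }
})

test_that("a species present in every sample always counts fully", {
  sets <- purrr::map(1:5, ~ c("ubiquitous", sample(LETTERS, 2)))
  inc <- inc_from_sets(sets)
  for (m in 1:5) {
    # the ubiquitous species contributes exactly 1 for every m
    contrib <- 1 - exp(
      lchoose(inc$N - inc$n_i[["ubiquitous"]], m) - lchoose(inc$N, m)
    )
    expect_equal(contrib, 1)
  }
  # all species in all samples -> E[S_m] = S_obs for any m
  inc7 <- inc_from_sets(replicate(4, LETTERS[1:7], simplify = FALSE))
  expect_equal(rarefied_richness(inc7, m = 1), 7)
  expect_equal(rarefied_richness(inc7, m = 3), 7)
})

test_that("rarefaction is monotone in m, bounded by S_obs, order-invariant", {
  set.seed(11)
  sets <- replicate(
    8, sample(LETTERS[1:10], sample(1:5, 1)),
    simplify = FALSE
  )
  inc <- inc_from_sets(sets)
  es <- vapply(1:8, function(m) rarefied_richness(inc, m), numeric(1))
  expect_true(all(diff(es) > -1e-12))
  expect_true(all(es <= inc$S_obs + 1e-12))
  inc_perm <- inc_from_sets(rev(sets))
  expect_equal(
    rarefied_richness(inc_perm, m = 4), rarefied_richness(inc, m = 4)
  )
})

test_that("records-mode rarefaction agrees with vegan's individual-based rarefy", {
  skip_if_not_installed("vegan")
  set.seed(13)
  counts <- c(20, 11, 7, 4, 2, 1, 1)
  rec <- purrr::imap(counts, function(k, i) {
    make_records(rep(LETTERS[i], k), lat = 10, lon = 120)
  }) |> purrr::list_rbind()
  inc <- incidence_summary(rec)
  for (m in c(5, 15, 30)) {
    expect_equal(
      rarefied_richness(inc, m = m, mode = "records"),
      as.numeric(vegan::rarefy(matrix(counts, nrow = 1), m)),
      tolerance = 1e-10
    )
  }
})

test_that("bootstrap SE is seeded, zero for identical samples, and calibrated", {
  # identical samples -> every resample identical -> SE 0
  inc_same <- inc_from_sets(replicate(6, c("A", "B"), simplify = FALSE))
  expect_equal(rarefied_se(inc_same, m = 3, B = 50, seed = 1), 0)

  set.seed(17)
  sets <- replicate(
    10, sample(LETTERS[1:5], sample(1:3, 1)),
    simplify = FALSE
  )
  inc <- inc_from_sets(sets)
  se1 <- rarefied_se(inc, m = 5, B = 200, seed = 99)
  se2 <- rarefied_se(inc, m = 5, B = 200, seed = 99)
  expect_identical(se1, se2)

  # Monte-Carlo oracle: SD of the estimator over independent bootstrap
  # resamples computed by direct enumeration-free simulation
  B_big <- 1000
  se_big <- rarefied_se(inc, m = 5, B = B_big, seed = 7)
  sim <- withr::with_seed(123, {
    vapply(seq_len(10000), function(i) {
      take <- sample(10, 10, replace = TRUE)
      hexrich:::rarefy_expect(
        vapply(
          LETTERS[1:5],
          function(sp) {
            sum(vapply(sets[take], function(s) sp %in% s, logical(1)))
          },
          numeric(1)
        ),
        10, 5
      )
    }, numeric(1))
  })
  expect_equal(se_big, sd(sim), tolerance = 0.15)
})

test_that("per-cell diversity handles sparse cells and strata", {
  g <- shared_grid()
  rec <- dplyr::bind_rows(
    make_records("a", lat = 10, lon = 120, depth = 5),
    make_records(c("b", "c", "b"), lat = 40, lon = 150, depth = c(5, 600, NA))
  )
  rec <- assign_to_cell(rec, g)
  cd <- cell_diversity(rec, grid = g)
  one <- cd[cd$n_records == 1 & cd$stratum == "all", ]
  expect_equal(one$alpha, 1)
  expect_true(is.na(one$es)) # N < 50 -> ES missing
  # records without depth are in "all" but no depth stratum
  c2 <- cd[cd$stratum == "all" & cd$n_records == 3, ]
  expect_equal(c2$alpha, 2)
  sh <- cd[cd$stratum == "shallow" & cd$n_records > 0, ]
  expect_equal(sum(sh$n_records), 2)
  # unsampled cells are present with zero effort
  expect_equal(nrow(cd), nrow(g$cells) * 3)
  expect_true(all(cd$n_records[!cd$cell_id %in% rec$cell_id] == 0))
})

test_that("merging two cells' records never lowers alpha", {
  set.seed(23)
  recA <- make_records(sample(LETTERS[1:8], 30, TRUE), lat = 10, lon = 120)
  recB <- make_records(sample(LETTERS[5:12], 30, TRUE), lat = 10.01, lon = 120)
  alpha <- function(r) length(unique(r$species))
  merged <- dplyr::bind_rows(recA, recB)
  expect_gte(alpha(merged), alpha(recA))
  expect_gte(alpha(merged), alpha(recB))
})

test_that("band aggregation: gamma contains cell alphas; mean ES and SE", {
  g <- shared_grid()
  set.seed(29)
  rec <- make_records(
    sample(LETTERS[1:12], 200, TRUE),
    lat = runif(200, 11, 14), lon = runif(200, 140, 160),
    depth = 10,
    date = as.Date("2010-01-01") + sample(0:50, 200, TRUE)
  )
  rec <- assign_to_cell(rec, g)
  cd <- cell_diversity(rec, grid = g, strata = "all")
  bd <- band_diversity(rec, cd)
  b3 <- bd[bd$band == 3, ] # [10, 15)
  expect_equal(b3$n_records, 200)
  expect_gte(b3$gamma, max(cd$alpha))
  # hand-check mean/SE of ES over two values
  two <- tibble::tibble(
    cell_id = c("x", "y"), stratum = "all", n_records = c(60, 60),
    n_samples = c(60, 60), alpha = c(10, 20), es = c(10, 20),
    es_se = NA_real_, centroid_lat = c(12, 13), centroid_lon = c(150, 151)
  )
  bd2 <- band_diversity(rec, two)
  b3b <- bd2[bd2$band == 3, ]
  expect_equal(b3b$mean_es, 15)
  expect_equal(b3b$se_es, 5)
  # bands with no ocean: zero area with an all-land mask
  land <- env_raster(matrix(0, 180, 160), 0, 100, 30, "mask")
  bd3 <- band_diversity(rec, cd, ocean_mask = land)
  expect_true(all(bd3$ocean_area_km2 == 0))
})

test_that("depth profile collapses to occupied intervals with ES rules", {
  g <- shared_grid()
  set.seed(31)
  rec <- make_records(
    sample(LETTERS[1:10], 300, TRUE),
    lat = runif(300, 10, 11), lon = runif(300, 120, 121),
    depth = runif(300, 0, 50),
    date = as.Date("2010-01-01") + sample(0:200, 300, TRUE)
  )
  rec <- assign_to_cell(rec, g)
  dp <- depth_profile(rec)
  expect_equal(dp$interval, 1L) # all records in [0, 100)
  expect_equal(dp$n_records, 300)
  expect_equal(dp$gamma, length(unique(rec$species)))
  expect_false(is.na(dp$mean_es)) # enough samples for ES50
  # deep records absent -> no deeper intervals reported
  expect_equal(nrow(dp), 1)
})
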