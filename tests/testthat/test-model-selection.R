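# Toy model tables built in code.
toy_table <- function(n, y, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    species_count = y,
    es50 = y,
    n_records = rpois(n, 50) + 1,
    centroid_lat = runif(n, 0, 90),
    centroid_lon = runif(n, 100, 180),
    temperature = runif(n, 0, 29),
    salinity = runif(n, 32, 35)
  ))
}

test_that("candidate sets enumerate the design (13/11/11/9 models)", {
  expect_length(build_candidate_set("species_count", "shallow"), 13)
  expect_length(build_candidate_set("es50", "shallow"), 11)
  expect_length(build_candidate_set("species_count", "deep"), 11)
  sp_deep_es <- build_candidate_set("es50", "deep")
  expect_length(sp_deep_es, 9)
  # ES50 sets never include effort; env models always include spatial
  for (s in sp_deep_es) {
    expect_false(s$include_effort)
    if (length(s$env_terms)) expect_true(s$include_spatial)
  }
  # deep stratum excludes the shallow-only predictors
  all_deep <- unlist(lapply(sp_deep_es, function(s) s$env_terms))
  expect_false(any(c("productivity", "saturated_oxygen") %in% all_deep))
  expect_error(
    model_spec("bad", "es50", include_effort = TRUE),
    class = "hexrich_parameter_error"
  )
})

test_that("AICc follows the closed form and its domain limits", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-10, 2, 10), 25.7143, tolerance = 1e-4)
  # large-n limit: AICc -> AIC
  expect_lt(abs(aicc(-10, 2, 1e6) - (2 * 10 + 2 * 2)), 1e-3)
  # penalty monotone in k and always above AIC
  ks <- 1:6
  vals <- vapply(ks, function(k) aicc(-10, k, 30), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > vapply(ks, function(k) 20 + 2 * k, numeric(1))))
  expect_error(aicc(-10, 0, 10), class = "hexrich_domain_error")
  expect_error(aicc(-10, 5, 6), class = "hexrich_domain_error")
})

test_that("intercept-only count fit recovers the sample mean", {
  tab <- toy_table(20, rep(4L, 20))
  spec <- model_spec("intercept", "species_count", "shallow")
  fit <- fit_nb_smooth(spec, tab)
  expect_equal(unname(fit$fitted[1]), 4, tolerance = 1e-6)
  expect_true(fit$converged)
  # equal counts are equidispersed: theta is driven to the Poisson limit
  expect_gt(fit$theta, 1e5)
})

test_that("penalized NB fit matches glm.nb on a linear-term problem", {
  skip_if_not_installed("MASS")
  tab <- toy_table(300, 0L, seed = 5)
  tab$species_count <- withr::with_seed(6, {
    MASS::rnegbin(300, exp(1 + 0.08 * tab$temperature), theta = 3)
  })
  spec <- model_spec(
    "temperature", "species_count", "shallow",
    env_terms = "temperature", basis_size = 1
  )
  fit <- fit_nb_smooth(spec, tab)
  ref <- MASS::glm.nb(
    species_count ~ scale(temperature),
    data = tab
  )
  expect_equal(
    unname(fit$coefficients),
    unname(coef(ref)),
    tolerance = 1e-3
  )
  expect_equal(fit$theta, ref$theta, tolerance = 0.02)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("NB slope estimates are unbiased within sampling error", {
  skip_if_not_installed("MASS")
  hits <- withr::with_seed(77, {
    vapply(1:60, function(i) {
      x <- runif(400, -1, 1)
      y <- MASS::rnegbin(400, exp(0.5 + 0.8 * x), theta = 2)
      tab <- tibble::tibble(
        species_count = y, es50 = y, n_records = 10,
        centroid_lat = runif(400, 0, 90), centroid_lon = runif(400, 100, 180),
        temperature = x
      )
      spec <- model_spec(
        "temperature", "species_count", "shallow",
        env_terms = "temperature", basis_size = 1
      )
      fit <- fit_nb_smooth(spec, tab)
      # slope on the standardised scale; compare against truth * sd(x)
      b <- fit$coefficients[["temperature"]]
      se <- 0.8 * sd(x) / sqrt(400) * 4 # generous envelope ~ 3-4 SE
      abs(b - 0.8 * sd(x)) < se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Poisson-generated data drives the NB fit to the Poisson limit", {
  tab <- withr::with_seed(9, {
    x <- runif(200, 0, 1)
    toy_table(200, y = rpois(200, exp(1 + x)))
  })
  tab$temperature <- withr::with_seed(9, runif(200, 0, 1))
  tab$species_count <- withr::with_seed(10, rpois(200, exp(1 + tab$temperature)))
  spec_nb <- model_spec(
    "t", "species_count", "shallow",
    env_terms = "temperature", basis_size = 1
  )
  spec_po <- model_spec(
    "t", "species_count", "shallow",
    env_terms = "temperature", basis_size = 1, family = "poisson"
  )
  fit_nb <- fit_nb_smooth(spec_nb, tab)
  fit_po <- fit_nb_smooth(spec_po, tab)
  expect_lt(abs(fit_nb$loglik - fit_po$loglik), 0.5)
})

test_that("band-scale Poisson GLM matches a likelihood grid-search oracle", {
  # 2-parameter toy: log mu = b0 + b1 x
  x <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  y <- c(2, 3, 4, 8, 11, 21)
  tab <- tibble::tibble(
    band = 1:6, species_count = y, es50 = y, n_records = 1,
    temperature = x
  )
  spec <- model_spec(
    "temperature", "species_count", "shallow",
    env_terms = "temperature", family = "poisson"
  )
  fit <- fit_poisson_glm(spec, tab)
  # brute-force grid around the optimum
  grid_ll <- function(b0, b1) sum(dpois(y, exp(b0 + b1 * x), log = TRUE))
  b0s <- seq(0.5, 2.5, by = 1e-3)
  b1s <- seq(0.5, 2.0, by = 1e-3)
  ll <- outer(b0s, b1s, Vectorize(grid_ll))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(unname(fit$coefficients[1]), b0s[best[1]], tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[2]), b1s[best[2]], tolerance = 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-4)

  # exactly log-linear integer counts: saturated fit, coefficients exact
  tab2 <- tibble::tibble(
    band = 1:6, species_count = 2^(0:5), es50 = 2^(0:5), n_records = 1,
    temperature = 0:5
  )
  fit2 <- fit_poisson_glm(spec, tab2)
  expect_lt(fit2$deviance, 1e-8)
  expect_equal(unname(fit2$coefficients[2]), log(2), tolerance = 1e-8)

  # intercept-only fitted mean = mean of counts
  spec0 <- model_spec("intercept", "species_count", "shallow", family = "poisson")
  fit0 <- fit_poisson_glm(spec0, tab)
  expect_equal(unname(fit0$fitted[1]), mean(y), tolerance = 1e-8)
})

test_that("adding a term never decreases the log-likelihood (nesting)", {
  tab <- withr::with_seed(21, {
    t <- toy_table(150, rpois(150, 10))
    t$species_count <- rpois(150, exp(2 + 0.02 * t$temperature))
    t
  })
  specs <- list(
    model_spec("intercept", "species_count", "shallow", family = "poisson"),
    model_spec("effort", "species_count", "shallow",
      include_effort = TRUE, family = "poisson"
    ),
    model_spec("effort+temp", "species_count", "shallow",
      env_terms = "temperature", include_effort = TRUE,
      family = "poisson", basis_size = 1
    )
  )
  lls <- vapply(
    specs,
    function(s) fit_nb_smooth(s, tab)$loglik,
    numeric(1)
  )
  expect_true(all(diff(lls) > -1e-6))
})

test_that("selection tables rank, delta and flag correctly", {
  mk_fit <- function(label, aicc) {
    structure(
      list(
        spec = list(label = label), aicc = aicc, k = 2, n = 50,
        loglik = -aicc / 2, deviance_explained = 0.5, converged = TRUE
      ),
      class = "model_fit"
    )
  }
  st <- selection_table(list(
    mk_fit("a", 110), mk_fit("b", 100), mk_fit("c", 100.32)
  ))
  expect_equal(st$model, c("b", "c", "a"))
  expect_equal(st$delta_aicc, c(0, 0.32, 10))
  expect_equal(st$inconclusive, c(TRUE, TRUE, FALSE))
  # single fit -> delta 0; shuffling input leaves the order invariant
  expect_equal(selection_table(list(mk_fit("solo", 5)))$delta_aicc, 0)
  st2 <- selection_table(list(
    mk_fit("c", 100.32), mk_fit("a", 110), mk_fit("b", 100)
  ))
  expect_equal(st2$model, st$model)
  # non-converged fits are dropped with a warning
  bad <- mk_fit("bad", 1)
  bad$converged <- FALSE
  expect_warning(st3 <- selection_table(list(mk_fit("a", 110), bad)), "bad")
  expect_equal(st3$model, "a")
})

test_that("tidiers expose coefficients and fit summaries", {
  tab <- toy_table(30, rpois(30, 5), seed = 3)
  fit <- fit_nb_smooth(
    model_spec("intercept", "species_count", "shallow"), tab
  )
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$model, "intercept")
  expect_true(gl$AICc >= -2 * gl$logLik + 2 * gl$k)
})
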