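discern_spec <- list(name = "discern", direction = "benefit",
                     bounds_source = "scale", scale_min = 16, scale_max = 80)

test_that("min-max normalisation maps scale and observed bounds correctly", {
  expect_equal(normalise_metric(65, discern_spec), 0.765625)
  expect_equal(normalise_metric(c(16, 80), discern_spec), c(0, 1))

  fkg_spec <- list(name = "fkg", direction = "cost",
                   bounds_source = "observed")
  tab <- load_paper_fixture("table2")
  n <- normalise_metric(tab$fkg, fkg_spec)
  expect_equal(n[tab$leaflet_id == "Microsoft Copilot"], 1.0)
  expect_equal(n[tab$leaflet_id == "Perplexity AI (free)"], 0.0)
  expect_true(all(n >= 0 & n <= 1))

  expect_error(normalise_metric(81, discern_spec),
               class = "pil_out_of_bounds")
  expect_error(normalise_metric(5, fkg_spec), class = "pil_invalid_input")
  expect_warning(z <- normalise_metric(c(4, 4, 4), fkg_spec),
                 regexp = "zero observed range")
  expect_equal(z, c(0.5, 0.5, 0.5))
})

test_that("the composite is the weighted share of the attainable maximum", {
  scheme <- default_weight_scheme()
  perfect <- as.list(setNames(rep(1, nrow(scheme)), scheme$name))
  expect_equal(composite_score(perfect, scheme)$composite_pct, 100)
  worst <- as.list(setNames(rep(0, nrow(scheme)), scheme$name))
  expect_equal(composite_score(worst, scheme)$composite_pct, 0)
  expect_error(composite_score(perfect[-1], scheme), regexp = "fkg",
               class = "pil_schema")
})

test_that("ties share the smaller rank and tiny corpora are rejected", {
  tab <- generate_score_table(score_table_recipe(n_leaflets = 2, seed = 3))
  twin <- tab
  twin$leaflet_id <- c("a", "b")
  twin[2, -1] <- twin[1, -1]
  r <- suppressWarnings(rank_leaflets(twin))
  expect_equal(r$rank, c(1L, 1L))
  expect_equal(r$composite_pct[1], r$composite_pct[2])
  expect_error(rank_leaflets(tab[1, ]), class = "pil_invalid_input")
})

test_that("composites are bounded, weight-homogeneous and monotone", {
  for (seed in 1:25) {
    tab <- generate_score_table(score_table_recipe(n_leaflets = 8,
                                                   seed = seed))
    r <- rank_leaflets(tab)
    expect_true(all(r$composite_pct >= 0 & r$composite_pct <= 100))
    expect_true(all(sort(r$rank) == r$rank))

    scheme <- default_weight_scheme()
    scaled <- scheme
    scaled$weight <- scheme$weight * 3.7
    r2 <- rank_leaflets(tab, scaled)
    expect_equal(r2$composite_pct, r$composite_pct)

    # improving one leaflet's DISCERN never lowers its composite
    better <- tab
    i <- (seed %% nrow(tab)) + 1L
    better$discern[i] <- min(80, better$discern[i] + 5)
    rb <- rank_leaflets(better)
    id <- tab$leaflet_id[i]
    expect_gte(rb$weighted_sum[rb$leaflet_id == id],
               r$weighted_sum[r$leaflet_id == id])
  }
})

test_that("observed min-max ranking is invariant to positive affine transforms", {
  withr::local_seed(99)
  for (k in 1:10) {
    tab <- generate_score_table(score_table_recipe(n_leaflets = 8, seed = k))
    col <- sample(c("fkg", "fre", "ari", "gfi"), 1)
    a <- runif(1, 0.2, 5)
    b <- runif(1, -10, 10)
    warped <- tab
    warped[[col]] <- a * tab[[col]] + b
    r1 <- rank_leaflets(tab)
    r2 <- rank_leaflets(warped)
    expect_equal(r2$leaflet_id, r1$leaflet_id)
    expect_equal(r2$rank, r1$rank)
    expect_equal(r2[[col]], r1[[col]])
  }
})

test_that("sensitivity analysis ranks under each scaling and reports tau", {
  tab <- load_paper_fixture("table2")
  solo <- sensitivity_analysis(tab, methods = "paper_default")
  expect_identical(solo$rankings$paper_default, rank_leaflets(tab))
  expect_equal(unname(solo$tau), matrix(1))

  sa <- sensitivity_analysis(tab, methods = c("paper_default",
                                              "percentile_rank"))
  expect_named(sa$rankings, c("paper_default", "percentile_rank"))
  expect_true(all(sa$tau >= -1 & sa$tau <= 1))
  r1 <- sa$rankings$paper_default
  r2 <- sa$rankings$percentile_rank
  m <- match(r1$leaflet_id, r2$leaflet_id)
  expect_equal(sa$tau["paper_default", "percentile_rank"],
               oracle_kendall_tau(r1$rank, r2$rank[m]))

  full <- sensitivity_analysis(tab)
  expect_equal(dim(full$tau), c(4L, 4L))
  expect_true(all(full$rankings$zscore$composite_pct >= 0 &
                    full$rankings$zscore$composite_pct <= 100))

  expect_error(sensitivity_analysis(tab, methods = "minmax_v2"),
               class = "pil_invalid_input")
})
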