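test_that("shannon_diversity matches the hand formula and handles edge cases", {
  b <- c(4, 4, 2)
  p <- b / sum(b)
  expect_equal(shannon_diversity(b), -sum(p * log(p)))
  expect_equal(shannon_diversity(c(5, 0, 5)), log(2))
  expect_equal(shannon_diversity(c(0, 7, 0)), 0)
  expect_error(shannon_diversity(c(0, 0)), class = "mesonet_data_error")
  expect_error(shannon_diversity(c(-1, 2)), class = "mesonet_data_error")
})

test_that("temporal_stability is mu over sample sd", {
  # hand oracle: (8, 10, 12) -> mean 10, sd 2, stability 5
  st <- temporal_stability(c(999, 8, 10, 12), years = 2006:2009)
  expect_equal(st$stability, 5)
  expect_equal(st$mu, 10)
  expect_equal(st$sigma, 2)
  expect_equal(st$years_included, c(2007, 2009))
  # without dropping the first year
  st2 <- temporal_stability(c(8, 10, 12), drop_first_year = FALSE)
  expect_equal(st2$stability, 5)
  expect_error(temporal_stability(c(1, 2), drop_first_year = FALSE),
               class = "mesonet_data_error")
  expect_error(temporal_stability(c(9, 5, 5, 5)),
               class = "mesonet_degenerate_error")
})

test_that("invasion_impact is the post-minus-pre difference", {
  v <- c(10, 12, 17, 20)
  y <- 2010:2013
  expect_equal(invasion_impact(v, y), 17 - 12)
  expect_equal(invasion_impact(v, y, pre_year = 2011, post_year = 2013),
               20 - 12)
  expect_error(invasion_impact(v, 2001:2004), class = "mesonet_data_error")
})

test_that("trajectory_beta equals the Pearson correlation with year", {
  v <- c(1, 3, 2, 4)
  y <- 2012:2015
  expect_equal(trajectory_beta(v, y, c(2012, 2019)), 0.8)
  expect_equal(trajectory_beta(v, y, c(2012, 2019)), cor(v, y))
  # years outside the window are excluded
  expect_equal(trajectory_beta(c(99, v), c(2011, y), c(2012, 2019)), 0.8)
  expect_error(trajectory_beta(c(5, 5, 5), 2012:2014, c(2012, 2019)),
               class = "mesonet_degenerate_error")
})

test_that("invader_proportion is the invader share of biomass", {
  expect_equal(invader_proportion(c(6, 3, 1), c(FALSE, TRUE, TRUE)), 0.4)
  expect_error(invader_proportion(c(0, 0), c(TRUE, FALSE)),
               class = "mesonet_data_error")
})

test_that("plant_metrics aggregates series and past parameters correctly", {
  ds <- generate_dataset(small_config(seed = 5))
  pm <- plant_metrics(ds$plants, axes = ds$axes)
  n_meso <- length(unique(ds$plants$mesocosm_id))
  n_years <- length(unique(ds$plants$year))
  expect_equal(nrow(pm$by_year), n_meso * n_years)
  expect_equal(nrow(pm$by_mesocosm), n_meso)
  expect_true(all(c("stability", "productivity_sampling",
                    "diversity_sampling", "productivity_impact",
                    "diversity_impact", "productivity_trajectory",
                    "diversity_trajectory", "axis1_sampling", "axis1_impact",
                    "axis1_trajectory") %in% names(pm$by_mesocosm)))
  expect_false(anyNA(pm$by_mesocosm))

  # spot-check one mesocosm against direct computation
  id <- pm$by_mesocosm$mesocosm_id[1]
  d <- pm$by_year[pm$by_year$mesocosm_id == id, ]
  d <- d[order(d$year), ]
  expect_equal(pm$by_mesocosm$stability[1],
               temporal_stability(d$productivity, d$year)$stability)
  # diversity invasion impact spans two seasons: 2013 minus 2011
  expect_equal(pm$by_mesocosm$diversity_impact[1],
               d$shannon[d$year == 2013] - d$shannon[d$year == 2011])
  # productivity impact is 2012 minus 2011
  expect_equal(pm$by_mesocosm$productivity_impact[1],
               d$productivity[d$year == 2012] - d$productivity[d$year == 2011])
  # trajectories use the post-invasion window 2012..final
  expect_equal(pm$by_mesocosm$productivity_trajectory[1],
               trajectory_beta(d$productivity, d$year, c(2012, max(d$year))))
})

test_that("invasion raises diversity at onset and invader share grows", {
  ds <- generate_dataset(small_config(seed = 11))
  pm <- plant_metrics(ds$plants, axes = ds$axes)
  by <- pm$by_year
  pre <- by$invader_prop[by$year < 2012]
  post <- by$invader_prop[by$year >= 2013]
  expect_true(all(pre == 0))
  expect_gt(mean(post), 0.05)
  # the abandoned arable soil is invaded more strongly
  last <- by[by$year == max(by$year), ]
  expect_gt(mean(last$invader_prop[last$soil == "abandoned_arable"]),
            mean(last$invader_prop[last$soil == "natural_grassland"]))
})
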