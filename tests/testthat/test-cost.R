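test_that("upfront extrapolation reproduces the quoted 33-fraction costs", {
  expect_equal(extrapolate_upfront(18415, 30, 33), 20257)
  expect_equal(extrapolate_upfront(27772, 25, 33), 36659)
  expect_equal(extrapolate_upfront(12345, 28, 28), 12345)
  expect_error(extrapolate_upfront(100, 0, 33), "fraction")
  up <- default_upfront_costs()
  expect_equal(up$photon, 20257)
  expect_equal(up$proton, 36659)
  expect_equal(up$proton - up$photon, 16402)
})

test_that("mucositis management bundle sums to the hand-computed base-case total", {
  items <- default_cost_items()
  S <- rep(1, 10)
  got <- management_cost("mucositis", make_events("mucositis"), items, S, 0.03)
  expected <- 168.8 + 1514.1 + 37.0 + 154.2 +
    0.30 * 5686 + 0.15 * 2096 + 0.10 * 19672 + 2718
  expect_equal(expected, 8579.50)
  expect_equal(got, expected)
  # esophagitis shares the bundle but with a 10% emergency-room proportion
  got_eso <- management_cost("esophagitis", make_events("esophagitis"),
                             items, S, 0.03)
  expect_equal(got_eso, expected - (0.15 - 0.10) * 2096)
})

test_that("no event means no management cost", {
  items <- default_cost_items()
  S <- rep(1, 10)
  for (comp in complication_names()) {
    expect_equal(management_cost(comp, make_events(), items, S, 0.03), 0)
  }
})

test_that("hypothyroidism annuity integrates Levothyroxine over discounted survival", {
  items <- default_cost_items()
  expect_equal(
    management_cost("hypothyroidism", make_events("hypothyroidism"),
                    items, rep(1, 5), 0),
    174.2 * 5)
  S <- cumprod(runif(12, 0.9, 1))
  expect_equal(
    management_cost("hypothyroidism", make_events("hypothyroidism"),
                    items, S, 0.03),
    174.2 * discounted_life_years(S, 0.03))
})

test_that("chronic PEG annuity follows the dysphagia chronicity rule", {
  items <- default_cost_items()
  S <- rep(1, 20)
  stricture <- 1700 * 0.16
  chronic <- management_cost("dysphagia",
                             make_events("dysphagia", chronic = TRUE),
                             items, S, 0)
  resolved <- management_cost("dysphagia",
                              make_events("dysphagia", chronic = FALSE),
                              items, S, 0)
  expect_equal(chronic, 18836 * 0.10 * 20 + stricture)
  expect_equal(resolved, 18836 * 0.10 * 5 + stricture)
})

test_that("stricture dilation defaults to the midpoint of the quoted charge range", {
  items <- default_cost_items()
  row <- items[items$label == "stricture_dilation", ]
  expect_equal(row$amount, (1200 + 2200) / 2)
  expect_equal(row$amount, 1700)
  expect_equal(row$proportion, 0.16)
})

test_that("total cost equals the upfront cost when no complication occurred", {
  items <- default_cost_items()
  up <- default_upfront_costs()
  S <- rep(1, 10)
  expect_equal(total_cost("photon", up, make_events(), items, S, 0.03), 20257)
  expect_equal(total_cost("proton", up, make_events(), items, S, 0.03), 36659)
  up$proton <- 21659
  expect_equal(total_cost("proton", up, make_events(), items, S, 0.03), 21659)
})

test_that("identical event vectors leave only the upfront difference", {
  items <- default_cost_items()
  up <- default_upfront_costs()
  S <- cumprod(runif(25, 0.9, 1))
  for (ev in list(make_events("dysphagia", "xerostomia", chronic = TRUE),
                  make_events(complication_names()))) {
    d <- total_cost("proton", up, ev, items, S, 0.03) -
      total_cost("photon", up, ev, items, S, 0.03)
    expect_equal(d, 16402)
  }
})

test_that("total cost is monotone in events and zero proportions strip management", {
  items <- default_cost_items()
  up <- default_upfront_costs()
  S <- rep(1, 15)
  comps <- complication_names()
  prev <- total_cost("photon", up, make_events(), items, S, 0.03)
  for (k in seq_along(comps)) {
    cur <- total_cost("photon", up, make_events(comps[seq_len(k)]),
                      items, S, 0.03)
    expect_gte(cur, prev)
    prev <- cur
  }
  items0 <- items
  items0$proportion <- 0
  expect_equal(total_cost("photon", up, make_events(comps), items0, S, 0.03),
               up$photon)
})

test_that("sampled proportions and amounts override the base values", {
  items <- default_cost_items()
  S <- rep(1, 10)
  got <- management_cost("dysphagia", make_events("dysphagia", chronic = TRUE),
                         items, S, 0,
                         sampled = list(
                           stricture_dilation = list(proportion = 0.2,
                                                     amount = 2000),
                           chronic_peg_tube = list(proportion = 0)))
  expect_equal(got, 2000 * 0.2)
})

test_that("annuities agree with the geometric-series closed form", {
  items <- default_cost_items()
  for (case in list(c(0.95, 0.03, 40), c(0.99, 0.05, 25), c(0.9, 0, 10))) {
    s <- case[1]; r <- case[2]; H <- case[3]
    S <- s^(1:H)
    x <- s / (1 + r)
    closed <- s * (1 - x^H) / (1 - x) # year 1 undiscounted: leading term s
    expect_equal(discounted_life_years(S, r), closed, tolerance = 1e-9)
    got <- management_cost("hypothyroidism", make_events("hypothyroidism"),
                           items, S, r)
    expect_equal(got, 174.2 * closed, tolerance = 1e-9)
  }
})

test_that("unknown complications in the item table are rejected", {
  items <- default_cost_items()
  items$complication[1] <- "alopecia"
  expect_error(
    management_cost("mucositis", make_events("mucositis"), items, rep(1, 5), 0),
    "alopecia")
})
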