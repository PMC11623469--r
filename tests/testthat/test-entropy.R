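make_panel <- function(values_good, values_bad = NULL, years = NULL) {
  # one unit per value, single year, over tiny_specs()
  n <- length(values_good)
  units <- sprintf("u%d", seq_len(n))
  yr <- if (is.null(years)) rep(2010, n) else years
  df <- tibble::tibble(unit = units, year = yr, indicator = "good",
                       value = values_good)
  specs <- tiny_specs()[1, ]
  if (!is.null(values_bad)) {
    df <- dplyr::bind_rows(df,
      tibble::tibble(unit = units, year = yr, indicator = "bad",
                     value = values_bad))
    specs <- tiny_specs()
  }
  indicator_panel(df, specs)
}

test_that("min-max normalization maps pooled extremes by attribute sign", {
  norm <- normalize_indicators(make_panel(c(1, 3), c(1, 3)))
  expect_equal(norm$value[norm$indicator == "good"], c(0, 1))
  expect_equal(norm$value[norm$indicator == "bad"], c(1, 0))

  norm3 <- normalize_indicators(make_panel(c(2, 4, 8)))
  expect_equal(norm3$value, c(0, 1 / 3, 1))

  expect_error(normalize_indicators(make_panel(c(5, 5))), "good")
})

test_that("pooling is over all units and years jointly", {
  df <- tibble::tibble(unit = rep(c("a", "b"), 2),
                       year = rep(2010:2011, each = 2),
                       indicator = "good", value = c(0, 1, 2, 4))
  norm <- normalize_indicators(indicator_panel(df, tiny_specs()[1, ]))
  expect_equal(norm$value[norm$unit == "b" & norm$year == 2011], 1)
  expect_equal(sort(norm$value), c(0, 0.25, 0.5, 1))
})

test_that("entropy weights normalize, respect symmetry, and reward contrast", {
  # single indicator takes the whole weight
  w1 <- entropy_weights(normalize_indicators(make_panel(c(1, 2, 3))))
  expect_equal(w1$weight, 1)

  # identical normalized patterns (mirrored raw values) share weight equally
  w2 <- entropy_weights(normalize_indicators(make_panel(c(1, 2, 4),
                                                        c(4, 3, 1))))
  expect_equal(w2$weight, c(0.5, 0.5), tolerance = 1e-12)

  # normalized pattern (0, 0, 1): p = (0, 0, 1), e = 0 -> maximal information
  # against a flatter negative companion with spread-out proportions
  norm <- normalize_indicators(make_panel(c(1, 1, 2), c(1, 2, 3)))
  w3 <- entropy_weights(norm)
  e_good <- w3$entropy[w3$indicator == "good"]
  expect_equal(e_good, 0)
  expect_gt(w3$weight[w3$indicator == "good"],
            w3$weight[w3$indicator == "bad"])
  expect_equal(sum(w3$weight), 1, tolerance = 1e-12)
})

test_that("entropy values stay in [0, 1] with the pooled denominator", {
  set.seed(7)
  vals <- runif(12)
  p <- make_panel(vals, runif(12), years = rep(2010:2013, each = 3))
  w <- entropy_weights(normalize_indicators(p))
  expect_true(all(w$entropy >= 0 & w$entropy <= 1))
  expect_true(all(w$weight >= 0))
})

test_that("composite scores are the weighted sum of normalized values", {
  scores_eq <- function(w, x) sum(w * x)
  w <- tibble::tibble(indicator = c("good", "bad"), subsystem = "EEC",
                      weight = c(0.25, 0.75))
  norm_df <- tibble::tibble(unit = "a", year = 2010,
                            indicator = c("good", "bad"),
                            value = c(0.4, 0.8))
  norm <- structure(norm_df, specs = tiny_specs(),
                    class = class(tiny_panel()))
  sc <- composite_scores(norm, w)
  expect_equal(sc$U_EEC, scores_eq(c(0.25, 0.75), c(0.4, 0.8)))  # 0.7

  # bounds: all-1 and all-0 normalized values
  norm1 <- dplyr::mutate(norm, value = 1)
  norm0 <- dplyr::mutate(norm, value = 0)
  expect_equal(composite_scores(norm1, w)$U_EEC, 1)
  expect_equal(composite_scores(norm0, w)$U_EEC, 0)
})

test_that("scoring is invariant to positive rescaling of a raw indicator", {
  set.seed(11)
  df <- expand.grid(unit = c("a", "b", "c"), year = 2010:2013,
                    indicator = c("good", "bad"), stringsAsFactors = FALSE)
  df$value <- runif(nrow(df), 1, 5)
  p1 <- indicator_panel(df, tiny_specs())
  df2 <- dplyr::mutate(df, value = ifelse(indicator == "good",
                                          value * 37.5, value))
  p2 <- indicator_panel(df2, tiny_specs())
  s1 <- score_subsystems(p1)
  s2 <- score_subsystems(p2)
  expect_equal(s1$weights$weight, s2$weights$weight, tolerance = 1e-12)
  expect_equal(s1$scores$U_EEC, s2$scores$U_EEC, tolerance = 1e-12)
})

test_that("raising a positive-attribute cell never lowers that unit's score", {
  set.seed(12)
  df <- expand.grid(unit = sprintf("u%d", 1:4), year = 2010:2012,
                    indicator = c("good", "bad"), stringsAsFactors = FALSE)
  df$value <- runif(nrow(df), 1, 5)
  # bump an interior cell of the positive indicator, keeping extremes fixed
  target <- which(df$indicator == "good" & df$unit == "u2" & df$year == 2011)
  goods <- df$value[df$indicator == "good"]
  df$value[df$indicator == "good"][which.max(goods)] <- 10   # fixed max
  df$value[df$indicator == "good"][which.min(goods)] <- 0.5  # fixed min
  base <- score_subsystems(indicator_panel(df, tiny_specs()))
  df_up <- df
  df_up$value[target] <- min(df$value[target] + 1, 9.9)
  up <- score_subsystems(indicator_panel(df_up, tiny_specs()))
  u_base <- base$scores$U_EEC[base$scores$unit == "u2" &
                                base$scores$year == 2011]
  u_up <- up$scores$U_EEC[up$scores$unit == "u2" & up$scores$year == 2011]
  expect_gte(u_up, u_base - 1e-9)
})
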