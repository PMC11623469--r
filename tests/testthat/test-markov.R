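state_tbl <- function(units, years, values) {
  tibble::tibble(unit = rep(units, each = length(years)),
                 year = rep(years, times = length(units)),
                 D = values)
}

test_that("pooled quartile discretization matches the brute-force oracle", {
  tbl <- state_tbl("u1", 2010:2017, 1:8)
  st <- discretize_ccd(tbl)
  expect_equal(as.character(st$state),
               rep(c("low", "lower-middle", "upper-middle", "high"),
                   each = 2))
  expect_equal(attr(st, "cutpoints"), unname(quantile(1:8, c(.25, .5, .75))))

  # a value equal to a cutpoint belongs to the upper class
  st2 <- discretize_ccd(tbl, cutpoints = c(2, 4, 6))
  expect_equal(as.character(st2$state[c(2, 4, 6)]),
               c("lower-middle", "upper-middle", "high"))

  # quantile states are rank-based: monotone transforms change nothing
  tbl3 <- dplyr::mutate(tbl, D = exp(D))
  expect_equal(discretize_ccd(tbl3)$state, st$state)

  expect_error(discretize_ccd(state_tbl("u1", 2010:2013, rep(1, 4))),
               "distinct")
})

test_that("transition counts follow hand-enumerated toy sequences", {
  # u1: low, low, high -> one low->low and one low->high transition
  tbl <- tibble::tibble(unit = c("u1", "u1", "u1"), year = 2010:2012,
                        state = factor(c("low", "low", "high"),
                                       levels = ccd_states(), ordered = TRUE))
  tm <- transition_matrix(tbl)
  expect_equal(unname(tm$counts["low", "low"]), 1L)
  expect_equal(unname(tm$counts["low", "high"]), 1L)
  expect_equal(tm$n_transitions, 2L)
  expect_equal(unname(tm$probs["low", c("low", "high")]), c(0.5, 0.5))
  # rows never observed are undefined, not zero
  expect_true(all(is.na(tm$probs["high", ])))
})

test_that("constant states give the identity matrix; rows sum to one", {
  tbl <- tibble::tibble(unit = rep(c("a", "b", "c", "d"), each = 3),
                        year = rep(2010:2012, 4),
                        state = factor(rep(ccd_states(), each = 3),
                                       levels = ccd_states(), ordered = TRUE))
  tm <- transition_matrix(tbl)
  expect_equal(unname(tm$probs), diag(4))
  expect_equal(unname(rowSums(tm$probs)), rep(1, 4))
})

test_that("spatial lag is the weighted neighbour average", {
  W2 <- spatial_weights(matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  tbl <- tibble::tibble(unit = c("a", "b"), year = 2010, D = c(0.2, 0.6))
  lag <- spatial_lag(tbl, W2)
  expect_equal(lag$lag[match(c("a", "b"), lag$unit)], c(0.6, 0.2))

  # uniform values: lag equals the common value everywhere
  W5 <- ring_weights(5)
  tbl5 <- tibble::tibble(unit = rownames(W5), year = 2010, D = 0.4)
  expect_equal(spatial_lag(tbl5, W5)$lag, rep(0.4, 5))

  # star graph: center's lag is the mean of the leaves
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A[1, 2:4] <- A[2:4, 1] <- 1
  Ws <- spatial_weights(A)
  tbls <- tibble::tibble(unit = letters[1:4], year = 2010,
                         D = c(0.9, 0.1, 0.2, 0.6))
  lag_s <- spatial_lag(tbls, Ws)
  expect_equal(lag_s$lag[lag_s$unit == "a"], mean(c(0.1, 0.2, 0.6)))
})

test_that("spatially conditioned matrices partition the traditional counts", {
  set.seed(51)
  units <- sprintf("u%d", 1:9)
  W <- ring_weights(9, units)
  tbl <- tibble::tibble(unit = rep(units, each = 8),
                        year = rep(2010:2017, 9),
                        D = runif(72))
  st <- discretize_ccd(tbl)
  trad <- transition_matrix(st)
  lag <- spatial_lag(tbl, W)
  spat <- spatial_transition_matrices(st, lag)
  total <- Reduce(`+`, lapply(spat, function(m) m$counts))
  expect_equal(total, trad$counts)
  for (m in spat) {
    rs <- rowSums(m$counts)
    ok <- rs > 0
    expect_equal(unname(rowSums(m$probs)[ok]), rep(1, sum(ok)))
  }
})

test_that("degenerate conditioning reproduces the traditional matrix", {
  set.seed(52)
  units <- sprintf("u%d", 1:6)
  tbl <- tibble::tibble(unit = rep(units, each = 5),
                        year = rep(2010:2014, 6), D = runif(30))
  st <- discretize_ccd(tbl)
  # all lags forced into the top class
  lag <- tibble::tibble(unit = tbl$unit, year = tbl$year, lag = 0.99)
  spat <- spatial_transition_matrices(st, lag,
                                      cutpoints = c(0.25, 0.5, 0.75))
  expect_equal(spat[["high"]]$counts, transition_matrix(st)$counts)
  expect_equal(spat[["low"]]$n_transitions, 0L)
})

test_that("Moran's I matches closed forms and is relabeling invariant", {
  W2 <- spatial_weights(matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  # two mutual neighbours with opposite values: perfect dispersion
  expect_error(morans_i(c(1, -1), W2), "at least 3")
  W4 <- spatial_weights(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                              c(0, 0, 0, 1), c(0, 0, 1, 0)))
  # two disconnected pairs, constant within, distinct between -> I = +1
  m <- morans_i(c(1, 1, -1, -1), W4, n_perm = 99, seed = 1)
  expect_equal(m$I, 1)
  expect_equal(m$expected, -1 / 3)
  # perfect dispersion on one pair each
  m2 <- morans_i(c(1, -1, 1, -1), W4, n_perm = 99, seed = 1)
  expect_equal(m2$I, -1)

  # consistent relabeling of units and W leaves I unchanged
  set.seed(53)
  W9 <- ring_weights(9)
  y <- runif(9)
  perm <- sample(9)
  Wp <- spatial_weights(unclass(W9)[perm, perm] > 0)
  m_orig <- morans_i(y, W9, n_perm = 9, seed = 2)
  m_perm <- morans_i(y[perm], Wp, n_perm = 9, seed = 2)
  expect_equal(m_orig$I, m_perm$I, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 9), W9), "variance")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(54)
  W <- ring_weights(12)
  y <- runif(12)
  ours <- morans_i(y, W, n_perm = 9, seed = 3)
  theirs <- ape::Moran.I(y, unclass(W))
  expect_equal(ours$I, theirs$observed, tolerance = 1e-10)
  expect_equal(ours$expected, theirs$expected, tolerance = 1e-10)
})

test_that("sticky synthetic chains are recovered near their true diagonal", {
  # diagonal-dominant 4-state chain, 31 units x 13 years (403 observations)
  P <- matrix(0.05 / 3, 4, 4)
  diag(P) <- 0.95 - 0.05 / 3  # rows sum to 1 after adding the off-diagonals
  P <- P / rowSums(P)
  set.seed(55)
  err <- replicate(50, {
    states <- matrix(0L, 31, 13)
    states[, 1] <- sample(1:4, 31, replace = TRUE)
    for (t in 2:13) {
      for (i in 1:31) {
        states[i, t] <- sample(1:4, 1, prob = P[states[i, t - 1], ])
      }
    }
    tbl <- tibble::tibble(unit = rep(sprintf("u%d", 1:31), each = 13),
                          year = rep(2010:2022, 31),
                          state = factor(ccd_states()[as.vector(t(states))],
                                         levels = ccd_states(),
                                         ordered = TRUE))
    est <- transition_matrix(tbl)$probs
    mean(abs(diag(est) - diag(P)), na.rm = TRUE)
  })
  expect_lt(mean(err), 0.05)
})
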