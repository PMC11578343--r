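test_that("Tukey-fence filter removes exactly the out-of-fence values", {
  out <- iqr_filter(c(1:10, 100))
  expect_equal(out$removed, 11L)        # only the 100
  expect_equal(out$values, 1:10)
  # all-equal values: zero IQR, fences at the value, nothing removed
  same <- iqr_filter(rep(5, 10))
  expect_equal(same$removed, integer(0))
  expect_equal(same$values, rep(5, 10))
  # pass-through with a warning below the minimum sample size
  expect_warning(small <- iqr_filter(c(1, 2, 3)))
  expect_equal(small$values, c(1, 2, 3))
  # idempotent on its own output for a unimodal fixture
  twice <- iqr_filter(out$values)
  expect_equal(twice$removed, integer(0))
})

test_that("Tukey-fence removal rate on Gaussian data matches theory", {
  withr::with_seed(55, x <- rnorm(1000))
  out <- iqr_filter(x)
  rate <- length(out$removed) / 1000
  # theoretical fence-exceedance rate for a normal population is ~0.7%
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.02)
})

test_that("rank-sum p-values match exhaustive enumeration for tiny samples", {
  enumerate_p <- function(a, b) {
    m <- length(a); n <- length(b)
    pooled <- c(a, b)
    ranks <- rank(pooled)
    u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
    combos <- utils::combn(m + n, m)
    u_all <- apply(combos, 2, function(ii) sum(ranks[ii]) - m * (m + 1) / 2)
    min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  }
  df <- data.frame(g = rep(c("a", "b"), times = c(3, 3)),
    y = c(1, 2, 3, 10, 11, 12))
  res <- rank_sum_test(df, y, g)
  expect_equal(res$statistic, 0) # Mann-Whitney U: complete separation
  expect_equal(res$p.value, enumerate_p(c(1, 2, 3), c(10, 11, 12)))
  withr::with_seed(19, {
    for (rep in 1:10) {
      m <- sample(3:5, 1); n <- sample(3:5, 1)
      a <- runif(m); b <- runif(n) + runif(1, -0.5, 0.5)
      df <- data.frame(g = rep(c("a", "b"), times = c(m, n)), y = c(a, b))
      res <- rank_sum_test(df, y, g)
      expect_equal(res$p.value, enumerate_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("identical groups are not declared different", {
  df <- data.frame(g = rep(c("a", "b"), each = 20), y = rep(seq(1, 5, length.out = 20), 2))
  expect_gt(rank_sum_test(df, y, g, exact = FALSE)$p.value, 0.05)
  df3 <- data.frame(g = rep(c("a", "b", "c"), each = 20),
    y = rep(seq(1, 5, length.out = 20), 3))
  expect_gt(kruskal_rank_test(df3, y, g)$p.value, 0.05)
  expect_error(rank_sum_test(data.frame(g = "a", y = 1), y, g),
    class = "nps_stats_error")
})

test_that("Kruskal-Wallis type-I error is near the nominal level", {
  withr::with_seed(77, {
    hits <- 0L
    for (i in 1:1000) {
      df <- data.frame(g = rep(c("a", "b", "c"), each = 50), y = rnorm(150))
      if (kruskal_rank_test(df, y, g)$p.value < 0.05) hits <- hits + 1L
    }
  })
  expect_gt(hits / 1000, 0.03)
  expect_lt(hits / 1000, 0.07)
})

test_that("signed-rank variant requires a paired design", {
  df <- data.frame(g = rep(c("a", "b"), times = c(3, 4)), y = rnorm(7))
  expect_error(signed_rank_test(df, y, g), class = "nps_stats_error")
  dfp <- data.frame(g = rep(c("a", "b"), each = 5),
    y = c(1, 2, 3, 4, 5, 1.4, 3.1, 3.2, 6.5, 5.3))
  expect_s3_class(signed_rank_test(dfp, y, g), "tbl_df")
})

test_that("cross-zone heterogeneity scores standardized per-zone variation", {
  # population where every cell keeps its z-score across zones scores zero
  cells <- 1:30
  withr::with_seed(3, z <- rnorm(30))
  flat <- tidyr::expand_grid(cell_id = cells, zone = 1:4) |>
    dplyr::mutate(Gp = 100 * zone + 10 * zone * z[cell_id])
  sc_flat <- cross_zone_variance(flat, Gp)
  expect_equal(sc_flat$score, rep(0, 30), tolerance = 1e-12)
  expect_equal(sc_flat$n_zones, rep(4L, 30))
  # standardization: each zone column has unit variance
  std <- flat |> dplyr::group_by(zone) |>
    dplyr::mutate(zv = as.numeric(scale(Gp)))
  expect_equal(as.numeric(tapply(std$zv, std$zone, var)), rep(1, 4))
  # zone-alternating population scores higher than a zone-stable one
  withr::with_seed(8, {
    stable <- tidyr::expand_grid(cell_id = cells, zone = 1:4) |>
      dplyr::mutate(Gp = rep(rlnorm(30, log(200), 0.4), each = 4) *
        (1 + rnorm(120, 0, 0.02)))
    # alternation pattern varies between cells, so it survives the
    # population-level per-zone standardization
    alt <- stable |>
      dplyr::mutate(Gp = Gp * ifelse((zone + cell_id) %% 2 == 0, 2, 0.5))
  })
  expect_lt(median(cross_zone_variance(stable, Gp)$score),
    median(cross_zone_variance(alt, Gp)$score))
  # single-zone cells get NA
  one <- data.frame(cell_id = c(1, 1, 2), zone = c(1, 2, 1), Gp = c(1, 2, 3))
  sc1 <- cross_zone_variance(one, Gp)
  expect_true(is.na(sc1$score[sc1$cell_id == 2]))
})

test_that("modulus heatmap builds for grouped populations", {
  df <- tidyr::expand_grid(cell_id = 1:20, zone = 1:4) |>
    dplyr::mutate(Gp = rlnorm(80, log(200), 0.4),
      group = ifelse(cell_id <= 10, "control", "treated"))
  p <- plot_modulus_heatmap(df, Gp, group)
  expect_s3_class(p, "ggplot")
})
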