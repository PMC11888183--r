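test_that("shift test matches exact enumeration and flips sign on swap", {
  pt <- c(a = 0.1, b = 0.2, c = 0.8, d = 0.9)
  res <- pseudotime_shift_test(pt, c("a", "b"), c("c", "d"))
  expect_equal(res$p_shift, 1 / 6)
  expect_lt(res$z_shift, 0)

  rev <- pseudotime_shift_test(pt, c("c", "d"), c("a", "b"))
  expect_equal(rev$z_shift, -res$z_shift)
  expect_error(pseudotime_shift_test(pt, character(), c("a")), "non-empty")
})

test_that("Mann-Whitney equals the exhaustive enumeration oracle for
           n1 + n2 <= 12", {
  set.seed(55)
  for (rep in 1:30) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    x <- runif(n1)
    y <- runif(n2)
    for (alt in c("less", "greater")) {
      got <- mann_whitney(x, y, alt)
      expect_true(got$exact)
      expect_equal(got$p, enumerate_mw_p(x, y, alt))
      # and agrees with the reference implementation
      expect_equal(got$p,
                   stats::wilcox.test(x, y, alternative = alt,
                                      exact = TRUE)$p.value)
    }
  }
})

test_that("approximate Mann-Whitney p is calibrated and tie-degenerate
           input returns 1", {
  set.seed(77)
  ps <- replicate(300, {
    pool <- runif(110)
    mann_whitney(pool[1:30], pool[31:110], "less")$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_equal(mann_whitney(rep(1, 5), rep(1, 5), "less")$p, 1)
})

test_that("KDE profiles follow the Gaussian closed form on the unit grid", {
  prof <- kde_density_profile(c(0.3, 0.5, 0.7))
  expect_length(prof$grid, 40)
  expect_length(prof$density, 40)
  expect_equal(prof$grid, seq(0, 1, length.out = 40))
  expect_true(all(prof$density >= 0))

  # one-point sample at forced bandwidth: peak ~ dnorm peak / bw
  single <- kde_density_profile(0.5, bandwidth = 0.1)
  peak <- single$density[which.min(abs(single$grid - 0.5))]
  expect_equal(peak, 1 / (0.1 * sqrt(2 * pi)), tolerance = 0.01)

  # cross-check against the FFT KDE in base R
  set.seed(3)
  x <- rbeta(500, 3, 2)
  mine <- kde_density_profile(x, bandwidth = 0.08)
  ref <- stats::density(x, bw = 0.08, from = 0, to = 1, n = 40)
  expect_equal(mine$density, ref$y, tolerance = 1e-3)

  # mass conservation up to boundary leakage
  mid <- kde_density_profile(runif(300, 0.25, 0.75))
  integral <- sum(diff(mid$grid) *
                    (utils::head(mid$density, -1) +
                       utils::tail(mid$density, -1)) / 2)
  expect_gt(integral, 0.9)
  expect_lt(integral, 1.01)

  # automatic bandwidth needs spread; explicit bandwidth lifts that
  expect_error(kde_density_profile(rep(0.5, 3)), "distinct")
  expect_silent(kde_density_profile(rep(0.5, 3), bandwidth = 0.1))
})

test_that("windowed enrichment counts 31 windows and detects separation", {
  set.seed(21)
  base <- kde_density_profile(runif(200))
  win <- windowed_enrichment(base, base)
  expect_length(win$window_p_enrich, 31)
  expect_length(win$window_p_deplete, 31)
  # identical profiles: full ties, never significant
  expect_true(all(win$window_p_enrich >= 0.05))
  expect_true(all(win$window_p_deplete >= 0.05))

  # complete separation in a window: exact extreme p
  hi <- base
  hi$density <- base$density + 1
  sep <- windowed_enrichment(hi, base)
  expect_equal(sep$window_p_enrich[1], 1 / choose(20, 10))

  # rank-based: invariant to adding a constant to both profiles
  shift_a <- base
  shift_b <- kde_density_profile(runif(150))
  w1 <- windowed_enrichment(shift_b, shift_a)
  shift_a$density <- shift_a$density + 3
  shift_b$density <- shift_b$density + 3
  w2 <- windowed_enrichment(shift_b, shift_a)
  expect_equal(w1$window_p_enrich, w2$window_p_enrich)
  expect_equal(w1$window_p_deplete, w2$window_p_deplete)

  bad <- kde_density_profile(runif(50), n_points = 30)
  expect_error(windowed_enrichment(bad, base), "grid")
})

test_that("direction calls require concordant window, Z sign and adjusted
           shift significance", {
  w_low <- rep(1, 31); w_low[3] <- 0.001
  w_high <- rep(1, 31); w_high[29] <- 0.001
  expect_equal(classify_target(list(z_shift = -3, p_two_adj = 0.001,
                                    window_p_enrich = w_low)),
               "pro_differentiation")
  expect_equal(classify_target(list(z_shift = 3, p_two_adj = 0.001,
                                    window_p_enrich = w_high)),
               "pro_progenitor")
  # discordant Z sign
  expect_equal(classify_target(list(z_shift = 3, p_two_adj = 0.001,
                                    window_p_enrich = w_low)), "none")
  # windows alone are not enough without the adjusted shift test
  expect_equal(classify_target(list(z_shift = -3, p_two_adj = 0.4,
                                    window_p_enrich = w_low)), "none")
  expect_error(classify_target(list(z_shift = -3, p_two_adj = 0.001)),
               "window")
})

test_that("target phenotyping recovers a planted shift and the detection
           rate grows with effect size and cells", {
  mk_run <- function(seed, deltas, n_per = 150, n_bg = 2500) {
    set.seed(seed)
    genes <- names(deltas)
    pt <- c()
    assign <- list()
    for (g in genes) {
      t <- runif(n_per) * (1 + deltas[[g]])
      names(t) <- paste0(g, "_cell", seq_len(n_per))
      pt <- c(pt, t)
      assign[[g]] <- data.frame(cell_id = names(t),
                                assigned_guides = paste0(g, "_g1"),
                                status = "single", target_gene = g)
    }
    bg <- runif(n_bg)
    names(bg) <- paste0("bg_cell", seq_len(n_bg))
    nulls <- sprintf("NULL%02d", 1:10)
    bg_gene <- rep(nulls, length.out = n_bg)
    pt <- c(pt, bg)
    assign$bg <- data.frame(cell_id = names(bg),
                            assigned_guides = paste0(bg_gene, "_g1"),
                            status = "single", target_gene = bg_gene)
    target_phenotypes(pt, do.call(rbind, assign))
  }

  rates <- sapply(c(D0 = 0, D2 = -0.2, D4 = -0.4), function(d) {
    hits <- 0
    for (s in 1:8) {
      ph <- mk_run(800 + s, list(TARG = d))
      hits <- hits + (ph$classification[ph$gene == "TARG"] ==
                        "pro_differentiation")
    }
    hits / 8
  })
  expect_true(all(diff(rates) >= 0))
  expect_equal(unname(rates["D0"]), 0)
  expect_gte(unname(rates["D4"]), 7 / 8)

  # more cells per target does not reduce detection
  rate_small <- mean(sapply(1:6, function(s) {
    ph <- mk_run(900 + s, list(TARG = -0.25), n_per = 40)
    ph$classification[ph$gene == "TARG"] == "pro_differentiation"
  }))
  rate_large <- mean(sapply(1:6, function(s) {
    ph <- mk_run(900 + s, list(TARG = -0.25), n_per = 300)
    ph$classification[ph$gene == "TARG"] == "pro_differentiation"
  }))
  expect_gte(rate_large, rate_small)

  # genes below min_cells are not tested
  ph <- mk_run(1000, list(TARG = -0.4))
  expect_false(any(grepl("tiny", ph$gene)))
})
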