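quad_table <- function(values, labels) {
  tibble::tibble(source_id = sprintf("q%d", seq_along(values)),
                 label = labels, f1 = values)
}

test_that("histograms use shared equal-width edges, last bin right-inclusive", {
  ft <- quad_table(c(0, 1, 2, 3), c("normal", "normal", "suspicious", "suspicious"))
  h <- nb_histogram(ft, "f1", n_bins = 2)
  expect_equal(h$breaks, c(0, 1.5, 3))
  expect_equal(h$counts_normal, c(2, 0))
  expect_equal(h$counts_suspicious, c(0, 2)) # 3 falls in the inclusive last bin
  expect_equal(sum(h$counts_normal) + sum(h$counts_suspicious), 4)
})

test_that("a zero-range feature collapses to one degenerate bin", {
  ft <- quad_table(rep(2, 4), c("normal", "normal", "suspicious", "suspicious"))
  h <- nb_histogram(ft, "f1", n_bins = 5)
  expect_equal(h$n_bins, 1L)
  expect_equal(h$counts_normal, 2L)
  expect_equal(h$counts_suspicious, 2L)
  expect_error(nb_histogram(ft, "f1", n_bins = 1), "at least 2")
})

test_that("bin counts match a direct interval-membership oracle", {
  withr::with_seed(23, {
    x <- runif(80, -2, 5)
    lab <- sample(c("normal", "suspicious"), 80, TRUE)
  })
  ft <- quad_table(x, lab)
  h <- nb_histogram(ft, "f1", n_bins = 12)
  edges <- seq(min(x), max(x), length.out = 13)
  for (b in 1:12) {
    in_bin <- x >= edges[b] & (if (b == 12) x <= edges[13] else x < edges[b + 1])
    expect_equal(h$counts_suspicious[b], sum(in_bin & lab == "suspicious"))
    expect_equal(h$counts_normal[b], sum(in_bin & lab == "normal"))
  }
})

fake_hist <- function(cs, cn) {
  structure(list(feature = "f", n_bins = length(cs), breaks = NULL,
                 counts_suspicious = cs, counts_normal = cn),
            class = "feature_histogram_pair")
}

test_that("posterior arithmetic matches the direct formula", {
  h <- fake_hist(c(10, 40), c(5, 95))
  pp <- nb_posterior(1L, list(h), c(normal = 2 / 3, suspicious = 1 / 3))
  expect_equal(pp, (0.2 * 1 / 3) / (0.2 * 1 / 3 + 0.05 * 2 / 3)) # = 2/3
  expect_equal(pp, 2 / 3)
})

test_that("posterior symmetry and zero-likelihood cases", {
  h <- fake_hist(c(3, 7), c(3, 7))
  expect_equal(nb_posterior(1L, list(h), c(normal = .5, suspicious = .5)), 0.5)
  expect_equal(nb_posterior(2L, list(h), c(normal = .5, suspicious = .5)), 0.5)
  hz <- fake_hist(c(0, 10), c(4, 6))
  expect_equal(nb_posterior(1L, list(hz), c(normal = .5, suspicious = .5)), 0)
  # both likelihoods zero -> fall back to the suspicious prior
  hb <- fake_hist(c(0, 10), c(0, 4))
  expect_equal(nb_posterior(1L, list(hb), c(normal = .7, suspicious = .3)), 0.3)
})

test_that("multi-feature posteriors multiply per-feature likelihoods", {
  h1 <- fake_hist(c(8, 2), c(2, 8))
  h2 <- fake_hist(c(6, 4), c(4, 6))
  pri <- c(normal = 0.5, suspicious = 0.5)
  pp <- nb_posterior(c(1L, 1L), list(h1, h2), pri)
  ls <- 0.8 * 0.6; ln <- 0.2 * 0.4
  expect_equal(pp, ls / (ls + ln))
})

test_that("LOOCV on four identical images returns the held-out prior", {
  ft <- quad_table(rep(1, 4), c("normal", "normal", "suspicious", "suspicious"))
  pp <- nb_loocv(ft, "f1", n_bins = 4)
  expect_equal(pp$pp_suspicious, c(2/3, 2/3, 1/3, 1/3))
})

test_that("disjoint class supports give posteriors of exactly 0 and 1", {
  # two images per bin so leave-one-out never empties a class histogram
  ft <- quad_table(c(1, 1, 2, 2, 3, 3, 11, 11, 12, 12, 13, 13),
                   rep(c("normal", "suspicious"), each = 6))
  pp <- nb_loocv(ft, "f1", n_bins = 12)
  expect_equal(pp$pp_suspicious, rep(c(0, 1), each = 6))
})

test_that("an image alone in its bin falls back to the held-out prior", {
  ft <- quad_table(c(1, 2, 3, 11, 12, 13),
                   c(rep("normal", 3), rep("suspicious", 3)))
  pp <- nb_loocv(ft, "f1", n_bins = 12)
  # each held-out image empties its own bin: both likelihoods are zero and
  # the posterior collapses to the suspicious prior among the other images
  expect_equal(pp$pp_suspicious[1], 3 / 5)
  expect_equal(pp$pp_suspicious[4], 2 / 5)
})

test_that("label-permuted posteriors average to the class prior", {
  withr::with_seed(31, {
    x <- rnorm(120)
    lab <- sample(rep(c("normal", "suspicious"), c(80, 40)))
  })
  pp <- nb_loocv(quad_table(x, lab), "f1", n_bins = 6)
  expect_lt(abs(mean(pp$pp_suspicious) - 1 / 3), 0.1)
})

test_that("Laplace smoothing keeps posteriors strictly inside (0, 1)", {
  ft <- quad_table(c(1, 2, 3, 11, 12, 13),
                   c(rep("normal", 3), rep("suspicious", 3)))
  pp <- nb_loocv(ft, "f1", n_bins = 12, laplace = TRUE)
  expect_true(all(pp$pp_suspicious > 0 & pp$pp_suspicious < 1))
})

test_that("sensitivity-first thresholds follow the (m+1)-th smallest rule", {
  pp <- tibble::tibble(source_id = as.character(1:6),
                       label = c(rep("suspicious", 3), rep("normal", 3)),
                       pp_suspicious = c(0.3, 0.6, 0.9, 0.1, 0.5, 0.7))
  expect_equal(nb_threshold(pp, 0), 0.3)
  g0 <- glance(nb_report(pp, nb_threshold(pp, 0)))
  expect_equal(g0$sensitivity, 1)
  expect_equal(nb_threshold(pp, 1), 0.6)
  g1 <- glance(nb_report(pp, nb_threshold(pp, 1)))
  expect_equal(g1$sensitivity, 2 / 3)
  expect_error(nb_threshold(pp, 3), "smaller")
})

test_that("ties at the minimum stay above the inclusive threshold", {
  pp <- tibble::tibble(source_id = as.character(1:4),
                       label = c("suspicious", "suspicious", "normal", "normal"),
                       pp_suspicious = c(0.4, 0.4, 0.4, 0.2))
  thr <- nb_threshold(pp, 0)
  expect_equal(thr, 0.4)
  r <- tidy(nb_report(pp, thr))
  expect_equal(r$call, c("suspicious", "suspicious", "suspicious", "normal"))
})

test_that("the sens100 threshold achieves sensitivity 1 on its own table (property)", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 30
      pp <- tibble::tibble(source_id = as.character(1:n),
                           label = sample(c("normal", "suspicious"), n, TRUE,
                                          prob = c(.6, .4)),
                           pp_suspicious = runif(n))
    })
    if (length(unique(pp$label)) < 2) next
    g <- glance(nb_report(pp, nb_threshold(pp, 0)))
    expect_equal(g$sensitivity, 1)
  }
})

test_that("ROC sweep matches a brute-force per-threshold confusion count", {
  withr::with_seed(37, {
    n <- 100
    lab <- sample(c("normal", "suspicious"), n, TRUE)
    sc <- round(runif(n), 2) # duplicates on purpose
  })
  sw <- roc_sweep(sc, lab)
  expect_equal(sw$threshold, c(sort(unique(sc)), Inf))
  for (i in seq_len(nrow(sw))) {
    t <- sw$threshold[i]
    expect_equal(sw$sensitivity[i], mean(sc[lab == "suspicious"] >= t))
    expect_equal(sw$specificity[i], mean(sc[lab == "normal"] < t))
  }
  # monotone in the threshold; endpoints present
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(utils::tail(sw$specificity, 1), 1)
})

test_that("degenerate sweeps keep the two endpoint operating points", {
  sw <- roc_sweep(c(0.9, 0.1), c("suspicious", "normal"))
  expect_true(any(sw$sensitivity == 1 & sw$specificity == 1))
  sw2 <- roc_sweep(c(0.5, 0.5, 0.5), c("suspicious", "normal", "normal"))
  expect_equal(sw2$sensitivity, c(1, 0))
  expect_equal(sw2$specificity, c(0, 1))
})

test_that("nb_search enumerates all subsets and ranks by specificity", {
  ft <- cluster_table(n_per_class = 10, p = 4, sep = 5, seed = 55)
  s <- nb_search(ft, subset_size = 2, n_bins = 6, top = Inf)
  expect_equal(attr(s, "n_candidates"), choose(4, 2))
  expect_equal(nrow(s), choose(4, 2))
  expect_true(all(diff(s$specificity) <= 0))
  expect_equal(s$sensitivity[1], 1) # sens100 thresholding
})
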