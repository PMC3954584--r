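three_point_table <- function() {
  tibble::tibble(source_id = c("p0", "p1", "p3"),
                 label = c("normal", "suspicious", "normal"),
                 f1 = c(0, 1, 3))
}

test_that("fractional distances follow d/d_max on collinear points", {
  nt <- knn_neighbors(three_point_table(), "f1", standardize = FALSE)
  q <- nt[nt$source_id == "p1", ]
  expect_equal(q$neighbor_id, c("p0", "p3"))
  expect_equal(q$distance, c(1, 2))
  expect_equal(q$f, c(0.5, 1))
})

test_that("a duplicated feature row is its twin's first neighbour at f = 0", {
  ft <- tibble::tibble(source_id = c("a", "b", "c", "d"),
                       label = c("normal", "normal", "suspicious", "suspicious"),
                       f1 = c(2, 2, 5, 9))
  nt <- knn_neighbors(ft, "f1", standardize = FALSE)
  first <- nt[nt$source_id == "a" & nt$rank == 1, ]
  expect_equal(first$neighbor_id, "b")
  expect_equal(first$f, 0)
})

test_that("neighbour table matches an exhaustive pairwise-distance oracle", {
  withr::with_seed(17, {
    n <- 50
    ft <- tibble::tibble(source_id = sprintf("s%02d", 1:n),
                         label = sample(c("normal", "suspicious"), n, TRUE),
                         f1 = rnorm(n), f2 = rnorm(n))
    nt <- knn_neighbors(ft, c("f1", "f2"), standardize = FALSE)
    x <- cbind(ft$f1, ft$f2)
    for (i in c(1, 25, 50)) {
      d <- sqrt(colSums((t(x) - x[i, ])^2))
      d[i] <- Inf
      ord <- order(d)[1:25]
      got <- nt[nt$source_id == ft$source_id[i], ]
      expect_equal(got$neighbor_id, ft$source_id[ord])
      expect_equal(got$distance, d[ord])
      expect_equal(got$f, d[ord] / d[ord[25]])
    }
  })
})

test_that("votes follow the +1/-1, tie-to-suspicious and 1-f weighting rules", {
  nb <- tibble::tibble(neighbor_label = c("suspicious", "normal", "normal"),
                       f = c(0.2, 0.9, 1))
  v <- knn_vote(nb, knn_config(k = 3))
  expect_equal(v$score, -1) # majority normal
  expect_equal(v$call, "normal")
  v2 <- knn_vote(nb[1:2, ], knn_config(k = 2))
  expect_equal(v2$score, 0)
  expect_equal(v2$call, "suspicious") # score >= 0 is suspicious
  v3 <- knn_vote(nb[1:2, ], knn_config(k = 2, distance_weighting = TRUE))
  expect_equal(v3$score, 0.8 - 0.1)
  expect_equal(v3$call, "suspicious")
  expect_error(knn_vote(nb, knn_config(k = 9)), "exceeds")
})

test_that("prior weighting up-weights the rarer class", {
  nb <- tibble::tibble(neighbor_label = c("suspicious", "normal", "normal"),
                       f = c(0, 0.5, 1))
  pri <- c(normal = 0.75, suspicious = 0.25)
  v <- knn_vote(nb, knn_config(k = 3, prior_weighting = TRUE), pri)
  expect_equal(v$score, 4 - 4 / 3 - 4 / 3)
  expect_equal(v$call, "suspicious")
})

test_that("LOOCV separates two well-separated clusters perfectly at k = 1", {
  ft <- cluster_table(n_per_class = 15, sep = 8)
  r <- knn_loocv(ft, c("f1", "f2", "f3"), knn_config(k = 1))
  g <- glance(r)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
})

test_that("label-permuted data scores near chance (permutation null)", {
  ft <- cluster_table(n_per_class = 25, sep = 8, seed = 10)
  withr::with_seed(10, ft$label <- sample(ft$label))
  g <- glance(knn_loocv(ft, c("f1", "f2", "f3"), knn_config(k = 5)))
  bal_acc <- (g$sensitivity + g$specificity) / 2
  expect_lt(abs(bal_acc - 0.5), 0.22) # ~3 binomial SDs at n = 50
})

test_that("LOOCV report equals a hand enumeration on a small table", {
  ft <- tibble::tibble(
    source_id = sprintf("i%d", 1:6),
    label = c("normal", "normal", "normal", "suspicious", "suspicious", "suspicious"),
    f1 = c(0, 1, 2, 10, 11, 30))
  # k = 2, unweighted: each point's two nearest others vote
  r <- tidy(knn_loocv(ft, "f1", knn_config(k = 2, standardize = FALSE)))
  # i1,i2,i3 see two normals -> normal; i4,i5 see each other + a normal or
  # suspicious; i4: neighbours i5 (d1), i3 (d8) -> S+N = 0 -> suspicious;
  # i5: i4 (d1), i3 (d9) -> suspicious; i6: i5 (d19), i4 (d20) -> suspicious
  expect_equal(r$call, c("normal", "normal", "normal",
                         "suspicious", "suspicious", "suspicious"))
  g <- glance(knn_loocv(ft, "f1", knn_config(k = 2, standardize = FALSE)))
  expect_equal(unlist(g[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 0, tn = 3, fn = 0))
})

test_that("unweighted votes with odd k can never tie", {
  ft <- cluster_table(n_per_class = 10, sep = 1, seed = 6)
  for (k in c(1, 3, 5)) {
    r <- tidy(knn_loocv(ft, c("f1", "f2"), knn_config(k = k)))
    expect_true(all(r$score != 0))
  }
})

test_that("prior weighting at k = 1 only adds suspicious calls", {
  ft <- cluster_table(n_per_class = 12, sep = 2, seed = 30)
  ft <- ft[-(20:24), ] # suspicious class rarer than normal
  un <- tidy(knn_loocv(ft, c("f1", "f2"), knn_config(k = 1)))
  pw <- tidy(knn_loocv(ft, c("f1", "f2"), knn_config(k = 1, prior_weighting = TRUE)))
  expect_true(all(pw$call[un$call == "suspicious"] == "suspicious"))
})

test_that("subset search finds the planted informative feature at every k", {
  withr::with_seed(19, {
    n <- 40
    ft <- tibble::tibble(source_id = sprintf("s%02d", 1:n),
                         label = rep(c("normal", "suspicious"), each = n / 2))
    for (j in 1:6) ft[[paste0("f", j)]] <- rnorm(n)
    ft$f4 <- ft$f4 + 6 * (ft$label == "suspicious")
  })
  s <- knn_search(ft, subset_size = 1, k_range = 1:10)
  expect_equal(attr(s, "n_candidates"), 6)
  expect_true(all(purrr::map_lgl(s$subset, ~ "f4" %in% .x)))
  s2 <- knn_search(ft, subset_size = 2, k_range = c(1, 5))
  expect_equal(attr(s2, "n_candidates"), choose(6, 2))
  expect_true(all(purrr::map_lgl(s2$subset, ~ "f4" %in% .x)))
})

test_that("search results are invariant to input row order", {
  ft <- cluster_table(n_per_class = 10, sep = 3, seed = 44)
  s1 <- knn_search(ft, subset_size = 1, k_range = c(1, 3))
  withr::with_seed(1, ft2 <- ft[sample(nrow(ft)), ])
  s2 <- knn_search(ft2, subset_size = 1, k_range = c(1, 3))
  expect_equal(s1$sensitivity, s2$sensitivity)
  expect_equal(s1$specificity, s2$specificity)
  expect_equal(s1$subset, s2$subset)
})

test_that("degenerate inputs are refused", {
  ft <- cluster_table(4)
  expect_error(knn_loocv(ft, "nope", knn_config()), "Unknown feature")
  ft$label <- "normal"
  expect_error(knn_loocv(ft, "f1", knn_config()), "both")
})
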