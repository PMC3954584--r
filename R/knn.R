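#' Leave-one-out nearest-neighbour table
#'
#' For every image, finds its `n_store` (default 25) nearest other images by
#' Euclidean distance on the selected (optionally z-standardized) features,
#' and records their ordering and fractional distance `f = d / d_max`, where
#' `d_max` is the distance to the farthest stored neighbour. Distance ties
#' break by ascending row index; if `d_max = 0` all `f` are 0.
#'
#' @param features Feature table (see [feature_table()]): `source_id`,
#'   `label`, feature columns.
#' @param subset Feature subset as names or 1-based positions among the
#'   feature columns.
#' @param standardize z-score each selected feature over the full table
#'   before computing distances (default `TRUE`).
#' @param n_store Number of neighbours stored per image (default 25).
#' @return A tibble with columns `source_id`, `rank`, `neighbor_id`,
#'   `neighbor_label`, `distance`, `f`.
#' @export
knn_neighbors <- function(features, subset, standardize = TRUE, n_store = 25L) {
  fm <- feature_matrix(features)
  idx <- resolve_subset(subset, colnames(fm$x))
  nt <- neighbor_core(fm$x[, idx, drop = FALSE], standardize, n_store)
  n <- nrow(fm$x)
  tibble::tibble(
    source_id = rep(fm$source_id, each = ncol(nt$nbr)),
    rank = rep(seq_len(ncol(nt$nbr)), n),
    neighbor_id = fm$source_id[as.vector(t(nt$nbr))],
    neighbor_label = fm$label[as.vector(t(nt$nbr))],
    distance = as.vector(t(nt$dist)),
    f = as.vector(t(nt$f))
  )
}

# Core neighbour computation on a plain matrix. Returns n x m matrices of
# neighbour row indices, distances and fractional distances.
neighbor_core <- function(x, standardize = TRUE, n_store = 25L) {
  n <- nrow(x)
  if (n < 2) abort("Need at least two images.")
  if (standardize) {
    s <- apply(x, 2, sd)
    s[s == 0] <- 1
    x <- scale(x, center = colMeans(x), scale = s)
  }
  d2 <- sq_dist(x)
  m <- min(n_store, n - 1L)
  nbr <- matrix(0L, n, m)
  dst <- matrix(0, n, m)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di)[seq_len(m)] # order() breaks ties by ascending index
    nbr[i, ] <- ord
    dst[i, ] <- sqrt(pmax(di[ord], 0))
  }
  dmax <- dst[, m]
  f <- dst / ifelse(dmax > 0, dmax, 1)
  f[dmax == 0, ] <- 0
  list(nbr = nbr, dist = dst, f = f)
}

sq_dist <- function(x) {
  g <- tcrossprod(x)
  q <- diag(g)
  outer(q, q, "+") - 2 * g
}

#' Configure a KNN vote
#'
#' The four variants of the classifier: unweighted, distance-weighted,
#' prior-probability-weighted, and both. Suspicious neighbours vote `+1`,
#' normal neighbours `-1`; distance weighting multiplies a vote by
#' `1 - f` (fractional distance), prior weighting by `1 / prior` of the
#' neighbour's class. A vote total `>= 0` calls the image suspicious.
#'
#' @param k Number of neighbours used, 1..25.
#' @param distance_weighting,prior_weighting Enable the two weightings.
#' @param standardize z-standardize features before distances.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 2L, distance_weighting = FALSE,
                       prior_weighting = FALSE, standardize = TRUE) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), distance_weighting = distance_weighting,
                 prior_weighting = prior_weighting, standardize = standardize),
            class = "knn_config")
}

#' Tally a weighted KNN vote
#'
#' @param neighbors Tibble of the first `k` neighbour records for one image
#'   (columns `neighbor_label` and `f`, as in [knn_neighbors()]).
#' @param cfg A [knn_config()].
#' @param priors Named class priors `c(normal = , suspicious = )` used when
#'   `cfg$prior_weighting` is on.
#' @return List with `score` and `call` (`"suspicious"` iff `score >= 0`).
#' @export
knn_vote <- function(neighbors, cfg, priors = c(normal = 0.5, suspicious = 0.5)) {
  lab <- neighbors$neighbor_label
  if (cfg$k > length(lab)) abort("`k` exceeds the number of stored neighbours.")
  lab <- lab[seq_len(cfg$k)]
  f <- neighbors$f[seq_len(cfg$k)]
  sgn <- ifelse(lab == "suspicious", 1, -1)
  w_dist <- if (cfg$distance_weighting && any(f > 0)) 1 - f else 1
  w_prior <- if (cfg$prior_weighting) 1 / priors[lab] else 1
  score <- sum(sgn * w_dist * w_prior)
  list(score = unname(score),
       call = if (score >= 0) "suspicious" else "normal")
}

#' Leave-one-out KNN classification of a feature table
#'
#' Classifies every image by a weighted vote over its `k` nearest other
#' images and summarizes performance with [confusion_metrics()]. Class
#' priors for prior weighting are the label frequencies of the full table.
#'
#' @inheritParams knn_neighbors
#' @param cfg A [knn_config()].
#' @return A `triage_report`: list with `calls` (per-image tibble: source_id,
#'   label, score, call) and `metrics` (one-row tibble). Use [tidy()] /
#'   [glance()].
#' @export
knn_loocv <- function(features, subset, cfg = knn_config()) {
  fm <- feature_matrix(features)
  check_two_classes(fm$label)
  idx <- resolve_subset(subset, colnames(fm$x))
  nt <- neighbor_core(fm$x[, idx, drop = FALSE], cfg$standardize)
  scores <- knn_scores(nt, fm$label, cfg)[, cfg$k]
  calls <- ifelse(scores >= 0, "suspicious", "normal")
  report <- tibble::tibble(source_id = fm$source_id, label = fm$label,
                           score = scores, call = calls)
  new_triage_report(report,
                    method = "knn",
                    config = list(subset = colnames(fm$x)[idx], k = cfg$k,
                                  distance_weighting = cfg$distance_weighting,
                                  prior_weighting = cfg$prior_weighting))
}

# Vote scores for all k = 1..m at once: per-neighbour contributions, then a
# cumulative sum along the rank axis.
knn_scores <- function(nt, labels, cfg) {
  lab_n <- matrix(labels[nt$nbr], nrow(nt$nbr))
  sgn <- ifelse(lab_n == "suspicious", 1, -1)
  w <- sgn
  if (cfg$distance_weighting) {
    wd <- 1 - nt$f
    wd[rowSums(nt$f > 0) == 0, ] <- 1 # degenerate all-zero distances
    w <- w * wd
  }
  if (cfg$prior_weighting) {
    pri <- prop.table(table(factor(labels, c("normal", "suspicious"))))
    w <- w / ifelse(lab_n == "suspicious", pri[["suspicious"]], pri[["normal"]])
  }
  t(apply(w, 1, cumsum))
}

#' Exhaustive small-subset KNN feature search
#'
#' Evaluates every feature subset of the given size (41, 820 or 10660
#' candidates for sizes 1, 2, 3 on the 41-feature table) with leave-one-out
#' KNN at each `k`, and reports, per `k`, the subset with the highest
#' sensitivity; ties break by higher specificity, then by lexicographic
#' subset position.
#'
#' @inheritParams knn_loocv
#' @param subset_size 1, 2 or 3.
#' @param k_range Neighbour counts to sweep (default 1..25).
#' @param cfg A [knn_config()] template (its `k` is ignored).
#' @return A tibble with one row per `k`: `k`, `subset` (list column of
#'   feature names), `sensitivity`, `specificity`; attribute `n_candidates`
#'   records how many subsets were evaluated.
#' @export
knn_search <- function(features, subset_size = 3L, k_range = 1:25,
                       cfg = knn_config()) {
  stopifnot(subset_size %in% 1:3)
  fm <- feature_matrix(features)
  check_two_classes(fm$label)
  x <- fm$x
  if (cfg$standardize) {
    s <- apply(x, 2, sd); s[s == 0] <- 1
    x <- scale(x, center = colMeans(x), scale = s)
  }
  n <- nrow(x)
  m <- min(25L, n - 1L)
  k_range <- k_range[k_range <= m]
  is_s <- fm$label == "suspicious"
  subsets <- combn(ncol(x), subset_size)
  # per-feature squared-difference matrices let each subset's distances be a
  # cheap sum instead of a fresh O(n^2 p) pass
  sqd <- lapply(seq_len(ncol(x)), function(j) sq_dist(x[, j, drop = FALSE]))

  best <- matrix(-1, length(k_range), 2) # sens, spec per k
  best_sub <- vector("list", length(k_range))
  cfg2 <- cfg
  cfg2$standardize <- FALSE
  for (s_i in seq_len(ncol(subsets))) {
    cols <- subsets[, s_i]
    d2 <- sqd[[cols[1]]]
    for (j in cols[-1]) d2 <- d2 + sqd[[j]]
    nt <- neighbor_from_d2(d2, m)
    sc <- knn_scores(nt, fm$label, cfg2)
    calls <- sc[, k_range, drop = FALSE] >= 0
    sens <- colMeans(calls[is_s, , drop = FALSE])
    spec <- colMeans(!calls[!is_s, , drop = FALSE])
    better <- sens > best[, 1] | (sens == best[, 1] & spec > best[, 2])
    for (ki in which(better)) {
      best[ki, ] <- c(sens[ki], spec[ki])
      best_sub[[ki]] <- cols
    }
  }
  out <- tibble::tibble(
    k = k_range,
    subset = purrr::map(best_sub, ~ colnames(x)[.x]),
    sensitivity = best[, 1],
    specificity = best[, 2]
  )
  attr(out, "n_candidates") <- ncol(subsets)
  out
}

# neighbour structure straight from a squared-distance matrix (already
# standardized features)
neighbor_from_d2 <- function(d2, m) {
  n <- nrow(d2)
  nbr <- matrix(0L, n, m)
  dst <- matrix(0, n, m)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di)[seq_len(m)]
    nbr[i, ] <- ord
    dst[i, ] <- sqrt(pmax(di[ord], 0))
  }
  dmax <- dst[, m]
  f <- dst / ifelse(dmax > 0, dmax, 1)
  f[dmax == 0, ] <- 0
  list(nbr = nbr, dist = dst, f = f)
}

check_two_classes <- function(labels) {
  if (length(unique(labels[labels %in% c("normal", "suspicious")])) < 2) {
    abort("Need both a normal and a suspicious class.")
  }
}
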