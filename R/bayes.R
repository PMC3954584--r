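#' Identically binned class histograms for one feature
#'
#' Equal-width bins over the global `[min, max]` of the feature across all
#' images (both classes share the edges); the right edge of the last bin is
#' inclusive. A zero-range feature collapses to a single degenerate bin
#' holding every image.
#'
#' @param features Feature table ([feature_table()]).
#' @param feature Feature name or 1-based position.
#' @param n_bins Number of bins, >= 2.
#' @return A `feature_histogram_pair`: list with `feature`, `n_bins`,
#'   `breaks`, `counts_suspicious`, `counts_normal`.
#' @export
nb_histogram <- function(features, feature, n_bins = 12L) {
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  fm <- feature_matrix(features)
  j <- resolve_subset(feature, colnames(fm$x))
  if (length(j) != 1) abort("`feature` must select a single feature.")
  x <- fm$x[, j]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    breaks <- c(rng[1], rng[1]) # degenerate single bin
    bin <- rep(1L, length(x))
    nb <- 1L
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- bin_of(x, breaks)
    nb <- as.integer(n_bins)
  }
  structure(list(
    feature = colnames(fm$x)[j], n_bins = nb, breaks = breaks,
    counts_suspicious = tabulate(bin[fm$label == "suspicious"], nb),
    counts_normal = tabulate(bin[fm$label == "normal"], nb),
    bin = bin # per-image bin membership, same row order as `features`
  ), class = "feature_histogram_pair")
}

# Bin index with last-bin-inclusive right edge; values outside the global
# range are clamped into the end bins (with a warning).
bin_of <- function(x, breaks) {
  nb <- length(breaks) - 1L
  if (nb < 1L) return(rep(1L, length(x)))
  if (any(x < breaks[1] | x > breaks[nb + 1L])) {
    warn("Feature values outside the histogram range were clamped to the end bins.")
  }
  w <- (breaks[nb + 1L] - breaks[1]) / nb
  b <- floor((x - breaks[1]) / w) + 1L
  pmin(pmax(as.integer(b), 1L), nb)
}

#' Normalized suspicious posterior from class histograms
#'
#' Per feature, the class likelihood is the bin count over the class total
#' (literal counts, no smoothing unless `laplace`); the joint likelihood is
#' the product over the subset features (naive independence) and the
#' suspicious posterior is normalized against the normal posterior. If both
#' unnormalized posteriors are zero the suspicious prior is returned.
#'
#' @param bins Integer vector: the image's bin index in each histogram.
#' @param hists List of `feature_histogram_pair`s, one per subset feature.
#' @param priors Named priors `c(normal = , suspicious = )`.
#' @param exclude_label Optional label of an image to remove from the counts
#'   (leave-one-out): its own bin count and class total are decremented.
#' @param laplace Add-one smoothing of bin counts (default `FALSE`).
#' @return `pp_suspicious` in `[0, 1]`.
#' @export
nb_posterior <- function(bins, hists, priors, exclude_label = NULL,
                         laplace = FALSE) {
  l_s <- 1; l_n <- 1
  for (i in seq_along(hists)) {
    h <- hists[[i]]
    cs <- h$counts_suspicious
    cn <- h$counts_normal
    if (!is.null(exclude_label)) {
      if (exclude_label == "suspicious") cs[bins[i]] <- cs[bins[i]] - 1L
      else cn[bins[i]] <- cn[bins[i]] - 1L
    }
    if (laplace) { cs <- cs + 1L; cn <- cn + 1L }
    tot_s <- sum(cs); tot_n <- sum(cn)
    if (tot_s <= 0 || tot_n <= 0) abort("A class histogram is empty.")
    l_s <- l_s * cs[bins[i]] / tot_s
    l_n <- l_n * cn[bins[i]] / tot_n
  }
  num <- l_s * priors[["suspicious"]]
  den <- num + l_n * priors[["normal"]]
  if (den == 0) return(priors[["suspicious"]])
  num / den
}

#' Leave-one-out histogram naive Bayes posteriors
#'
#' Bin edges are fixed once on the full table; for each image, its own
#' counts are removed from its class's histograms and the class priors are
#' recomputed from the remaining images before its posterior is evaluated.
#'
#' @param features Feature table.
#' @param subset 1-3 features (names or positions).
#' @param n_bins Bins per feature histogram (2..25; default 12).
#' @param laplace Add-one smoothing (default `FALSE`).
#' @return An `nb_posteriors` tibble: `source_id`, `label`, `pp_suspicious`;
#'   attributes `subset` and `n_bins`.
#' @export
nb_loocv <- function(features, subset, n_bins = 12L, laplace = FALSE) {
  fm <- feature_matrix(features)
  check_two_classes(fm$label)
  idx <- resolve_subset(subset, colnames(fm$x))
  if (length(idx) > 3) abort("`subset` may have at most three features.")
  hists <- lapply(idx, function(j) nb_histogram(features, j, n_bins))
  n <- nrow(fm$x)
  n_s <- sum(fm$label == "suspicious")
  n_n <- sum(fm$label == "normal")
  pp <- vapply(seq_len(n), function(i) {
    lab <- fm$label[i]
    pri <- c(normal = (n_n - (lab == "normal")) / (n - 1),
             suspicious = (n_s - (lab == "suspicious")) / (n - 1))
    nb_posterior(vapply(hists, function(h) h$bin[i], integer(1)),
                 hists, pri, exclude_label = lab, laplace = laplace)
  }, numeric(1))
  out <- tibble::tibble(source_id = fm$source_id, label = fm$label,
                        pp_suspicious = pp)
  attr(out, "subset") <- colnames(fm$x)[idx]
  attr(out, "n_bins") <- n_bins
  class(out) <- c("nb_posteriors", class(out))
  out
}

#' Sensitivity-first threshold selection
#'
#' An image is called suspicious when its posterior is at or above the
#' threshold. For 100% sensitivity the threshold is the lowest suspicious
#' posterior; allowing `m` false negatives moves it to the `(m+1)`-th
#' smallest suspicious posterior, trading sensitivity for specificity.
#'
#' @param pp An `nb_posteriors` table (or any tibble with `label` and
#'   `pp_suspicious`).
#' @param allowed_misses `m >= 0`: number of suspicious images allowed below
#'   the threshold (0 targets 100% sensitivity).
#' @return The threshold value.
#' @export
nb_threshold <- function(pp, allowed_misses = 0L) {
  ps <- sort(pp$pp_suspicious[pp$label == "suspicious"])
  if (!length(ps)) abort("No suspicious images in the posterior table.")
  if (allowed_misses >= length(ps)) {
    abort("`allowed_misses` must be smaller than the number of suspicious images.")
  }
  ps[allowed_misses + 1L]
}

#' Classify posteriors at a threshold and report performance
#'
#' @inheritParams nb_threshold
#' @param threshold Posterior threshold; calls are suspicious iff
#'   `pp_suspicious >= threshold`.
#' @return A `triage_report` (see [knn_loocv()]).
#' @export
nb_report <- function(pp, threshold) {
  calls <- ifelse(pp$pp_suspicious >= threshold, "suspicious", "normal")
  report <- tibble::tibble(source_id = pp$source_id, label = pp$label,
                           score = pp$pp_suspicious, call = calls)
  new_triage_report(report, method = "naive_bayes",
                    config = list(subset = attr(pp, "subset"),
                                  n_bins = attr(pp, "n_bins"),
                                  threshold = threshold))
}

#' ROC sweep over posterior thresholds
#'
#' Sweeps the threshold over every distinct posterior value plus one point
#' above the maximum (where nothing is called suspicious), computing
#' sensitivity and specificity under the inclusive `>=` call rule.
#'
#' @param pp A posterior table with `label` and a score column, or a numeric
#'   score vector.
#' @param labels Labels, required when `pp` is a vector.
#' @return A `roc_sweep` tibble: `threshold`, `sensitivity`, `specificity`;
#'   sensitivity is nonincreasing and specificity nondecreasing in the
#'   threshold.
#' @export
roc_sweep <- function(pp, labels = NULL) {
  sc <- extract_scores(pp, labels)
  check_two_classes(sc$label)
  thr <- c(sort(unique(sc$score)), Inf)
  is_s <- sc$label == "suspicious"
  sens <- vapply(thr, function(t) mean(sc$score[is_s] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sc$score[!is_s] < t), numeric(1))
  out <- tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
  class(out) <- c("roc_sweep", class(out))
  out
}

extract_scores <- function(pp, labels = NULL) {
  if (is.data.frame(pp)) {
    score_col <- intersect(c("pp_suspicious", "score"), names(pp))[1]
    if (is.na(score_col) || !"label" %in% names(pp)) {
      abort("Need a `label` column and a `pp_suspicious`/`score` column.")
    }
    list(score = pp[[score_col]], label = pp$label)
  } else {
    if (is.null(labels)) abort("`labels` required when scores are a vector.")
    list(score = pp, label = labels)
  }
}

#' Exhaustive small-subset naive Bayes search
#'
#' Evaluates every subset of the given size (41/820/10660 candidates for
#' sizes 1/2/3 on 41 features) with leave-one-out posteriors, thresholds at
#' the sensitivity-first rule, and ranks subsets by specificity at the
#' achieved sensitivity.
#'
#' @inheritParams nb_loocv
#' @param subset_size 1, 2 or 3.
#' @param allowed_misses Passed to [nb_threshold()].
#' @param top Number of top rows to keep (default 5; `Inf` for all).
#' @return Tibble `subset` (list column), `threshold`, `sensitivity`,
#'   `specificity`, sorted by specificity (then sensitivity) descending;
#'   attribute `n_candidates`.
#' @export
nb_search <- function(features, subset_size = 1L, n_bins = 12L,
                      allowed_misses = 0L, laplace = FALSE, top = 5) {
  stopifnot(subset_size %in% 1:3)
  fm <- feature_matrix(features)
  check_two_classes(fm$label)
  subsets <- combn(ncol(fm$x), subset_size)
  rows <- purrr::map(seq_len(ncol(subsets)), function(s_i) {
    pp <- nb_loocv(features, subsets[, s_i], n_bins = n_bins, laplace = laplace)
    thr <- nb_threshold(pp, allowed_misses)
    g <- glance(nb_report(pp, thr))
    tibble::tibble(subset = list(colnames(fm$x)[subsets[, s_i]]),
                   threshold = thr, sensitivity = g$sensitivity,
                   specificity = g$specificity)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$specificity),
                        dplyr::desc(.data$sensitivity))
  out <- head(out, n = top)
  attr(out, "n_candidates") <- ncol(subsets)
  out
}
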