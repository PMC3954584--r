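# Independent oracles and fixture builders used across the suite.

make_record <- function(px, pixel_size_um = 200, bit_depth = 8L,
                        label = "unknown", source_id = "fix") {
  image_record(px, pixel_size_um, bit_depth = bit_depth, label = label,
               source_id = source_id)
}

# O(N^4) double-sum orthonormal DCT-II, straight from the definition.
dct2_bruteforce <- function(x) {
  n <- nrow(x)
  a <- function(k) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0
    for (r in 0:(n - 1)) for (c in 0:(n - 1)) {
      s <- s + x[r + 1, c + 1] *
        cos(pi * (2 * r + 1) * u / (2 * n)) *
        cos(pi * (2 * c + 1) * v / (2 * n))
    }
    out[u + 1, v + 1] <- a(u) * a(v) * s
  }
  out
}

# BFS flood fill, 8-connectivity: labels foreground pixels of a logical matrix.
flood_label8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            fg[rr, cc] && lab[rr, cc] == 0L) {
          q <- (cc - 1L) * nr + rr
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Two seeded Gaussian clusters as a labelled feature table.
cluster_table <- function(n_per_class = 15, p = 3, sep = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
    ft <- tibble::tibble(
      source_id = sprintf("img%02d", seq_len(2 * n_per_class)),
      label = rep(c("normal", "suspicious"), each = n_per_class))
    for (j in seq_len(p)) ft[[paste0("f", j)]] <- x[, j]
    ft
  })
}

# Disc + small square fixture: large bright disc touching the left half,
# a small bright tag square near the opposite corner.
disc_tag_image <- function(side = 48, disc_val = 200, tag_val = 220) {
  px <- matrix(0, side, side)
  ctr <- side / 2
  for (r in seq_len(side)) for (c in seq_len(side)) {
    if ((r - ctr)^2 + (c - side / 4)^2 <= (side / 5)^2) px[r, c] <- disc_val
  }
  px[3:6, (side - 5):(side - 2)] <- tag_val
  list(img = make_record(px), disc = px == disc_val, tag = px == tag_val)
}
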