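# Independent oracles and shared fixtures. The oracles deliberately use
# plain nested loops / exhaustive search so they share no code path with the
# package implementations they check.

# Brute-force raw moment: explicit double loop over pixels.
oracle_raw_moment <- function(image, p, q) {
  acc <- 0
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      acc <- acc + (c - 1)^p * (r - 1)^q * image[r, c]
    }
  }
  acc
}

oracle_central_moment <- function(image, p, q) {
  m00 <- oracle_raw_moment(image, 0, 0)
  xbar <- oracle_raw_moment(image, 1, 0) / m00
  ybar <- oracle_raw_moment(image, 0, 1) / m00
  acc <- 0
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      acc <- acc + (c - 1 - xbar)^p * (r - 1 - ybar)^q * image[r, c]
    }
  }
  acc
}

oracle_eta <- function(image, p, q) {
  mu00 <- oracle_central_moment(image, 0, 0)
  oracle_central_moment(image, p, q) / mu00^((p + q) / 2 + 1)
}

random_test_image <- function(nr, nc, seed) {
  withr::with_seed(seed, matrix(sample(0:255, nr * nc, replace = TRUE),
                                nr, nc))
}

# Smooth asymmetric two-blob shape: non-degenerate low-order moments, smooth
# enough that interpolated rotation/scale error stays small.
smooth_test_shape <- function(n = 256) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  blob <- function(cx, cy, sx, sy, a) {
    a * exp(-(((xs - cx) / sx)^2 + ((ys - cy) / sy)^2) / 2)
  }
  blob(n * 0.45, n * 0.5, n * 0.14, n * 0.09, 180) +
    blob(n * 0.62, n * 0.62, n * 0.06, n * 0.06, 120)
}

# Exhaustive k-NN oracle implementing the documented tie-break contract:
# neighbours ordered by (distance, training index); vote ties broken by
# smallest summed distance, then lowest ordinal grade.
oracle_knn_predict <- function(train_x, train_y, query, k,
                               metric = "euclidean") {
  lv <- kl_grades()
  n <- nrow(train_x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    diff <- train_x[i, ] - query
    d[i] <- if (metric == "euclidean") sqrt(sum(diff^2)) else sum(abs(diff))
  }
  nb <- order(d, seq_len(n))[seq_len(k)]
  labs <- as.character(train_y[nb])
  votes <- vapply(lv, function(g) sum(labs == g), numeric(1))
  top <- lv[votes == max(votes)]
  if (length(top) > 1) {
    sums <- vapply(top, function(g) sum(d[nb][labs == g]), numeric(1))
    top <- top[sums == min(sums)]
    top <- top[1] # lv is ordinal-ordered, so first = lowest ordinal
  }
  top
}

# Five well-separated Gaussian clusters in the 7-D feature space.
make_cluster_data <- function(n_per_class, seed, sd_frac = 0.1) {
  centers <- 2 * diag(5) %*% matrix(c(diag(5), matrix(0, 5, 2)), 5, 7)
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  withr::with_seed(seed, {
    rows <- lapply(1:5, function(g) {
      x <- matrix(rnorm(n_per_class * 7, 0, sd_frac * between),
                  n_per_class, 7) +
        matrix(centers[g, ], n_per_class, 7, byrow = TRUE)
      colnames(x) <- paste0("phi", 1:7)
      cbind(as.data.frame(x),
            grade = rep(kl_grades()[g], n_per_class))
    })
    out <- do.call(rbind, rows)
    out$grade <- kl_grade(out$grade)
    tibble::as_tibble(out)
  })
}

quiet_cli <- function(args) {
  suppressMessages(kl_cli(args))
}

# Moment comparisons at 1e-12 relative to the moment's natural scale
# (m00 * extent^(p+q)); a plain relative comparison is ill-conditioned for
# moments that are analytically zero (e.g. mu10) where both routes return
# cancellation noise.
expect_moment_equal <- function(actual, expected, img, p, q,
                                denom = 1) {
  scale <- max(sum(img) * max(dim(img))^(p + q) / denom,
               abs(expected), .Machine$double.xmin)
  expect_lte(abs(actual - expected), 1e-12 * scale)
}
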