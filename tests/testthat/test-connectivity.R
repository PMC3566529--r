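test_that("spearman_cor is Pearson on average ranks, monotone-invariant", {
  a <- c(0.3, 1.1, 2.2, 2.9, 5.5)
  expect_equal(as.numeric(spearman_cor(a, a)), 1)
  expect_equal(as.numeric(spearman_cor(a, exp(a))), 1)
  expect_equal(as.numeric(spearman_cor(a, -a^3)), -1)
  expect_equal(as.numeric(spearman_cor(c(1, 2, 3), c(10, 20, 15))), 0.5)

  set.seed(14)
  for (i in 1:30) {
    x <- sample(1:5, 12, replace = TRUE)     # heavy ties
    y <- rnorm(12) + x
    expect_equal(as.numeric(spearman_cor(x, y)),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  r <- spearman_cor(rep(2, 5), rnorm(5))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(spearman_cor(1:3, 1:4), "length")
})

test_that("matrix Spearman agrees with the scalar route column by column", {
  set.seed(15)
  ref <- rnorm(20)
  M <- cbind(rnorm(20), sample(1:3, 20, TRUE), rep(1, 20), ref)
  out <- infoconn:::spearman_vs_matrix(ref, M)
  for (j in 1:4) {
    expect_equal(out$r[j], as.numeric(spearman_cor(ref, M[, j])),
                 tolerance = 1e-12)
  }
  expect_true(out$degenerate[3])
  expect_equal(out$r[4], 1)
})

test_that("the IC map is 1 at the seed's own center", {
  sub <- tiny_session(volume = c(9L, 9L, 9L), n_runs = 3L, block_trs = 3L,
                      rest_trs = 1L, base_snr = 2, rng_seed = 41L,
                      region_center = c(5L, 5L, 5L), radius = 2)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(5L, 5L, 5L), 2, ds$mask)
  m <- ic_map(ds, seed, sub$labels, c("A", "B", "C", "D"), radius_vox = 2)
  expect_equal(m$values[5, 5, 5], 1, tolerance = 1e-12)
  expect_equal(m$method, "IC")
  expect_false(m$fisher_transformed)
  expect_true(all(is.finite(m$values[ds$mask])))
  td <- tidy(m)
  expect_equal(nrow(td), sum(ds$mask))
  expect_equal(td$value[td$i == 5 & td$j == 5 & td$k == 5], 1)
})

test_that("IC rests on ranks only: monotone transforms do not change it", {
  set.seed(16)
  a <- rnorm(30); b <- a + rnorm(30)
  r0 <- as.numeric(spearman_cor(a, b))
  expect_equal(as.numeric(spearman_cor(exp(a), b)), r0)
  expect_equal(as.numeric(spearman_cor(a, 5 * b - 2)), r0)
  expect_equal(as.numeric(spearman_cor(atan(a), exp(b))), r0)
})

test_that("FC is 1 against the seed's own mean series and partials out covariates", {
  sub <- tiny_session(volume = c(7L, 7L, 7L), n_runs = 3L, block_trs = 3L,
                      rest_trs = 1L, base_snr = 1, rng_seed = 51L,
                      region_center = c(4L, 4L, 4L), radius = 2)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(4L, 4L, 4L), 2, ds$mask)
  conds <- c("A", "B", "C", "D")
  sel <- select_condition_trs(sub$labels, conds)
  seed_mean <- colMeans(extract_patterns(ds, seed))[sel]

  # plant the seed-mean series in one far-away voxel
  ds2 <- ds
  ds2$data[7, 7, 7, sel] <- seed_mean
  fm <- fc_map(ds2, seed, sub$labels, conds)
  expect_equal(fm$values[7, 7, 7], 1, tolerance = 1e-10)

  # a voxel equal to a covariate is flattened by partialling
  nuis <- data.frame(wm = rnorm(dim(ds$data)[4]))
  ds3 <- ds
  ds3$data[7, 7, 7, ] <- nuis$wm
  fm2 <- fc_map(ds3, seed, sub$labels, conds, nuisance = nuis)
  expect_lt(abs(fm2$values[7, 7, 7]), 1e-8)
})

test_that("partial correlation matches the two-stage OLS oracle", {
  set.seed(17)
  n <- 25
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.5 * z1 + rnorm(n)
  y <- cbind(0.7 * z1 - z2 + 0.4 * x + rnorm(n), rnorm(n))
  out <- infoconn:::partial_cor_vs_matrix(x, y, cbind(z1, z2))
  for (j in 1:2) {
    rx <- residuals(lm(x ~ z1 + z2))
    ry <- residuals(lm(y[, j] ~ z1 + z2))
    expect_equal(out$r[j], cor(rx, ry), tolerance = 1e-12)
  }
})

test_that("searchlight-granularity FC uses searchlight-mean timeseries", {
  sub <- tiny_session(volume = c(7L, 7L, 7L), n_runs = 3L, block_trs = 3L,
                      rest_trs = 1L, base_snr = 1, rng_seed = 52L,
                      region_center = c(4L, 4L, 4L), radius = 2)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(4L, 4L, 4L), 2, ds$mask)
  conds <- c("A", "B", "C", "D")
  fm <- fc_map(ds, seed, sub$labels, conds, granularity = "searchlight",
               radius_vox = 2)
  # at the seed center the searchlight equals the seed region
  expect_equal(fm$values[4, 4, 4], 1, tolerance = 1e-10)
  expect_equal(fm$granularity, "searchlight")
})

test_that("Fisher transform is artanh with a double-transform guard", {
  sub <- tiny_session(volume = c(6L, 6L, 6L), n_runs = 2L, block_trs = 3L,
                      rest_trs = 1L, base_snr = 1, rng_seed = 53L,
                      region_center = c(3L, 3L, 3L), radius = 2)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(3L, 3L, 3L), 2, ds$mask)
  m <- ic_map(ds, seed, sub$labels, c("A", "B", "C", "D"), radius_vox = 1)
  f <- fisher_map(m)
  expect_true(f$fisher_transformed)
  ok <- ds$mask & !is.na(m$values) & abs(m$values) < 0.999
  expect_equal(f$values[ok], atanh(m$values[ok]), tolerance = 1e-10)
  expect_equal(atanh(0.5), 0.5 * log(3))     # closed form sanity
  ord <- order(m$values[ds$mask])
  expect_equal(order(f$values[ds$mask]), ord)  # monotone map-level
  expect_error(fisher_map(f), "already")
})

test_that("smoothing: identity at fwhm 0 and exact on constant maps", {
  sub <- tiny_session(volume = c(6L, 6L, 6L), n_runs = 2L, block_trs = 3L,
                      rest_trs = 1L, rng_seed = 54L,
                      region_center = c(3L, 3L, 3L), radius = 2)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(3L, 3L, 3L), 2, ds$mask)
  m <- ic_map(ds, seed, sub$labels, c("A", "B", "C", "D"), radius_vox = 1)
  expect_equal(smooth_map(m, 0)$values, m$values)

  mc <- m
  mc$values[mc$mask] <- 0.4
  sm <- smooth_map(mc, 6)
  expect_equal(sm$values[mc$mask], rep(0.4, sum(mc$mask)), tolerance = 1e-10)
  expect_equal(sm$smoothed_fwhm_mm, 6)
})

test_that("smoothing a delta matches direct mask-aware convolution", {
  mask <- array(TRUE, dim = c(7, 7, 7))
  mask[1:2, , ] <- FALSE                      # asymmetric mask support
  values <- array(0, dim = c(7, 7, 7))
  values[4, 4, 4] <- 1
  vox <- c(2, 2.5, 3)
  fwhm <- 5
  sm <- infoconn:::make_smoother(mask, fwhm, vox)(values)

  sigma <- (fwhm / vox) / (2 * sqrt(2 * log(2)))
  w <- function(d) prod(stats::dnorm(d / sigma) / sigma)
  oracle <- array(NA_real_, dim = c(7, 7, 7))
  idx <- which(mask, arr.ind = TRUE)
  for (n in seq_len(nrow(idx))) {
    v <- idx[n, ]
    num <- 0; den <- 0
    for (p in seq_len(nrow(idx))) {
      u <- idx[p, ]
      if (all(abs(u - v) <= ceiling(3 * sigma))) {
        wt <- w(u - v)
        den <- den + wt
        num <- num + wt * values[u[1], u[2], u[3]]
      }
    }
    oracle[v[1], v[2], v[3]] <- num / den
  }
  expect_equal(sm[mask], oracle[mask], tolerance = 1e-6)
  expect_true(all(is.na(sm[!mask])))
})

test_that("searchlight characterization reports activation, accuracy and maps", {
  sub <- tiny_session(volume = c(8L, 8L, 8L), n_runs = 3L, block_trs = 3L,
                      rest_trs = 1L, base_snr = 3, rng_seed = 55L,
                      region_center = c(4L, 4L, 4L), radius = 2,
                      base_mean = 1.5)
  ds <- zscore_within_run(sub$dataset)
  seed <- build_sphere(c(4L, 4L, 4L), 2, ds$mask)
  conds <- c("A", "B", "C", "D")
  m <- ic_map(ds, seed, sub$labels, conds, radius_vox = 2)
  tab <- characterize_searchlights(ds, sub$labels, conds, radius_vox = 2,
                                   maps = list(ic = m), seed = seed)
  expect_equal(nrow(tab), sum(ds$mask))
  center_row <- tab[tab$i == 4 & tab$j == 4 & tab$k == 4, ]
  expect_gt(center_row$accuracy, 0.6)          # informative region decodes
  expect_gt(center_row$mean_activation, 0)     # task-positive after z-score
  expect_equal(center_row$ic, 1)
  expect_true(center_row$seed_overlap)

  far <- tab[sqrt((tab$i - 4)^2 + (tab$j - 4)^2 + (tab$k - 4)^2) > 4.5, ]
  expect_lt(abs(mean(far$accuracy) - 0.25), 0.08)  # chance away from signal
  expect_false(any(far$seed_overlap))
})

test_that("seed_overlap_zone matches a brute-force membership check", {
  mask <- array(TRUE, dim = c(10, 10, 10))
  seed <- build_sphere(c(5, 5, 5), 2, mask)
  zone <- seed_overlap_zone(mask, seed, radius_vox = 2)
  centers <- which(mask, arr.ind = TRUE)
  for (n in sample(nrow(centers), 60)) {
    sl <- build_sphere(centers[n, ], 2, mask)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    overlap <- any(key(sl$members) %in% key(seed$members))
    expect_equal(zone[centers[n, , drop = FALSE]], overlap)
  }
})
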