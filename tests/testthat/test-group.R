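# Minimal connectivity_map stand-ins for group-stage tests: real maps from a
# tiny IC analysis, one per "subject".
make_tiny_ic_maps <- function(n_subjects = 3, rng_seed = 60L,
                              volume = c(7L, 7L, 7L)) {
  lapply(seq_len(n_subjects), function(s) {
    sub <- tiny_session(volume = volume, n_runs = 3L, block_trs = 3L,
                        rest_trs = 1L, base_snr = 2,
                        rng_seed = rng_seed + s,
                        region_center = as.integer(ceiling(volume / 2)),
                        radius = 2)
    ds <- zscore_within_run(sub$dataset)
    seed <- build_sphere(ceiling(volume / 2), 2, ds$mask)
    ic_map(ds, seed, sub$labels, c("A", "B", "C", "D"), radius_vox = 2,
           keep_series = TRUE, subject = s)
  })
}

test_that("the voxelwise one-sample t matches the closed form and t.test", {
  vals <- c(1, 2, 3, 4, 5)
  out <- infoconn:::ttest_columns(matrix(vals, ncol = 1))
  expect_equal(out$t, mean(vals) / (sd(vals) / sqrt(5)), tolerance = 1e-12)
  tt <- t.test(vals, alternative = "greater")
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p, unname(tt$p.value), tolerance = 1e-12)

  sym <- infoconn:::ttest_columns(matrix(c(-2, -1, 1, 2), ncol = 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 0.5)

  degen <- infoconn:::ttest_columns(matrix(rep(3, 4), ncol = 1))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)

  set.seed(61)
  S <- matrix(rnorm(8 * 20), 8, 20)
  out2 <- infoconn:::ttest_columns(S)
  for (j in sample(20, 5)) {
    ref <- t.test(S[, j], alternative = "greater")
    expect_equal(out2$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out2$p[j], unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("group_ttest needs 2+ subjects and maps onto the mask", {
  maps <- make_tiny_ic_maps(3)
  tt <- group_ttest(maps)
  expect_equal(tt$n_subjects, 3)
  expect_equal(dim(tt$t_map), dim(maps[[1]]$values))
  expect_true(all(tt$p_map[!maps[[1]]$mask] == 1))
  expect_error(group_ttest(maps[1]), "2 subjects")
})

test_that("cluster labeling matches an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(62)
  for (conn in c(6L, 18L, 26L)) {
    binary <- array(runif(10 * 9 * 8) < 0.25, dim = c(10, 9, 8))
    out <- label_clusters(binary, conn)
    vox <- which(binary, arr.ind = TRUE)
    n <- nrow(vox)
    off <- infoconn:::neighbor_offsets(conn)
    edges <- integer(0)
    key <- paste(vox[, 1], vox[, 2], vox[, 3])
    lut <- setNames(seq_len(n), key)
    for (v in seq_len(n)) {
      nb <- sweep(off, 2, vox[v, ], "+")
      hit <- lut[paste(nb[, 1], nb[, 2], nb[, 3])]
      hit <- unname(hit[!is.na(hit)])
      if (length(hit)) edges <- c(edges, rbind(v, hit))
    }
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    expect_equal(sort(out$clusters$size_voxels, decreasing = TRUE),
                 sort(as.integer(comp$csize), decreasing = TRUE),
                 info = paste("connectivity", conn))
    # same partition, not just same sizes
    expect_equal(nrow(out$clusters), comp$no)
    expect_equal(length(unique(paste(out$labels[vox], comp$membership))),
                 comp$no)
  }
})

test_that("cluster labeling handles simple constructed cases", {
  b <- array(FALSE, dim = c(5, 5, 5))
  b[1, 1, 1] <- TRUE; b[5, 5, 5] <- TRUE
  out <- label_clusters(b)
  expect_equal(out$clusters$size_voxels, c(1L, 1L))

  b2 <- array(FALSE, dim = c(5, 5, 5))
  b2[2:3, 2:3, 2:3] <- TRUE
  out2 <- label_clusters(b2)
  expect_equal(out2$clusters$size_voxels, 8L)

  # diagonal voxels connect under 26- but not 6-adjacency
  b3 <- array(FALSE, dim = c(4, 4, 4))
  b3[1, 1, 1] <- TRUE; b3[2, 2, 2] <- TRUE
  expect_equal(nrow(label_clusters(b3, 6)$clusters), 2)
  expect_equal(nrow(label_clusters(b3, 26)$clusters), 1)

  empty <- label_clusters(array(FALSE, c(3, 3, 3)))
  expect_equal(nrow(empty$clusters), 0)
})

test_that("block permutation preserves the multiset and within-block order", {
  values <- c(10.1, 10.2, 10.3, 20.1, 20.2, 20.3, 30.1, 30.2, 30.3)
  block <- rep(1:3, each = 3)
  set.seed(63)
  for (i in 1:20) {
    out <- permute_seed_series(values, block)
    expect_equal(sort(out), sort(values))
    for (b in 1:3) {
      seg <- out[block == b]
      expect_equal(seg, sort(seg))           # within-block order intact
      expect_equal(diff(seg), c(0.1, 0.1), tolerance = 1e-9)
    }
  }
  expect_error(permute_seed_series(values, c(block[-9], NA)), "block")
})

test_that("three equal blocks reach all 6 orderings uniformly", {
  values <- c(1, 1, 2, 2, 3, 3)
  block <- rep(1:3, each = 2)
  set.seed(64)
  draws <- replicate(900, paste(permute_seed_series(values, block),
                                collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 6)
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("blocks swap only within matching-length groups", {
  values <- c(1, 2, 3, 7, 101, 102)          # lengths 3, 1, 2
  block <- c(1, 1, 1, 2, 3, 3)
  set.seed(65)
  for (i in 1:25) {
    out <- permute_seed_series(values, block)
    expect_equal(out, values)                # no equal-length partners
  }
  values2 <- c(1, 2, 7, 8)
  block2 <- c(1, 1, 2, 2)
  seen <- replicate(200, paste(permute_seed_series(values2, block2),
                               collapse = ","))
  expect_setequal(unique(seen), c("1,2,7,8", "7,8,1,2"))
})

test_that("within-run permutation keeps blocks in their own run", {
  values <- 1:8
  block <- rep(1:4, each = 2)
  run <- rep(1:2, each = 4)
  set.seed(66)
  for (i in 1:25) {
    out <- permute_seed_series(values, block, run, within_run = TRUE)
    expect_setequal(out[1:4], 1:4)
    expect_setequal(out[5:8], 5:8)
  }
})

test_that("corrected_min_cluster selects the alpha-quantile order statistic", {
  expect_equal(corrected_min_cluster(10:1, alpha = 0.2), 9)
  expect_equal(corrected_min_cluster(10:1, alpha = 0.5), 6)
  null1000 <- sample(1:1000)
  expect_equal(corrected_min_cluster(null1000, alpha = 0.05), 951)
  expect_equal(corrected_min_cluster(null1000, alpha = 0.05),
               sort(null1000, decreasing = TRUE)[50])
  # non-increasing in alpha
  set.seed(67)
  null <- rpois(200, 4)
  ks <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5),
               function(a) corrected_min_cluster(null, a), numeric(1))
  expect_true(all(diff(ks) <= 0))
  expect_error(corrected_min_cluster(null, 0), "alpha")
  expect_error(corrected_min_cluster(integer(0), 0.05), "Empty")
})

test_that("apply_correction keeps only strictly-larger suprathreshold clusters", {
  dims <- c(8, 8, 8)
  t_map <- array(0, dims)
  p_map <- array(1, dims)
  blob <- as.matrix(expand.grid(i = 2:3, j = 2:3, k = 2))       # 4 voxels
  blob6 <- rbind(blob, cbind(i = 2:3, j = 4, k = 2))            # 6 voxels
  t_map[blob6] <- 6
  p_map[blob6] <- 1e-4
  tt <- list(t_map = t_map, p_map = p_map, n_subjects = 5)

  res <- apply_correction(tt, threshold_p = 0.001, min_cluster_size = 5)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$size_voxels, 6L)
  expect_equal(res$clusters$peak_t, 6)

  # a cluster exactly at the threshold size is excluded (strict >)
  res_eq <- apply_correction(tt, threshold_p = 0.001, min_cluster_size = 6)
  expect_equal(nrow(res_eq$clusters), 0)

  res_none <- apply_correction(list(t_map = array(0, dims),
                                    p_map = array(1, dims), n_subjects = 5),
                               min_cluster_size = 0)
  expect_equal(nrow(res_none$clusters), 0)

  # exclusion zone removes voxels before clustering
  zone <- array(FALSE, dims); zone[, 4, ] <- TRUE
  res_ex <- apply_correction(tt, threshold_p = 0.001, min_cluster_size = 3,
                             exclude = zone)
  expect_equal(res_ex$clusters$size_voxels, 4L)
})

test_that("the permutation null is deterministic and nonnegative", {
  maps <- make_tiny_ic_maps(3)
  null1 <- build_null(maps, fwhm_mm = 4, n_subject_perms = 8,
                      n_group_maps = 25, threshold_p = 0.05, seed = 99)
  null2 <- build_null(maps, fwhm_mm = 4, n_subject_perms = 8,
                      n_group_maps = 25, threshold_p = 0.05, seed = 99)
  expect_identical(null1$max_cluster_sizes, null2$max_cluster_sizes)
  expect_length(null1$max_cluster_sizes, 25)
  expect_true(all(null1$max_cluster_sizes >= 0))
  null3 <- build_null(maps, fwhm_mm = 4, n_subject_perms = 8,
                      n_group_maps = 25, threshold_p = 0.05, seed = 100)
  expect_false(identical(null1$max_cluster_sizes, null3$max_cluster_sizes))
  expect_error(build_null(maps, 4, n_subject_perms = 0), "subject_perms")
})

test_that("group_connectivity is deterministic end to end under a fixed seed", {
  maps <- make_tiny_ic_maps(3)
  g1 <- group_connectivity(maps, fwhm_mm = 4, threshold_p = 0.01,
                           n_subject_perms = 6, n_group_maps = 20, seed = 7)
  g2 <- group_connectivity(maps, fwhm_mm = 4, threshold_p = 0.01,
                           n_subject_perms = 6, n_group_maps = 20, seed = 7)
  expect_identical(g1$clusters, g2$clusters)
  expect_identical(g1$min_cluster_size, g2$min_cluster_size)
  expect_identical(g1$null$max_cluster_sizes, g2$null$max_cluster_sizes)
  expect_s3_class(tidy(g1), "tbl_df")
  expect_equal(glance(g1)$n_subjects, 3)
})

test_that("under a true global null corrected detections stay near alpha", {
  # noise-only brains: no decodable patterns anywhere, so the seed's
  # discriminability series shares nothing with any non-overlapping
  # searchlight; the permutation correction should then admit detections
  # (outside the seed's own reporting-excluded neighborhood) in roughly
  # alpha of replicates
  n_rep <- 6
  detected <- logical(n_rep)
  for (rep in seq_len(n_rep)) {
    spec <- synthetic_spec(volume_shape = c(16L, 16L, 16L),
                           mask_radius_vox = 7.5,
                           n_runs = 6L, block_trs = 4L, rest_trs = 2L,
                           regions = list(), rng_seed = 8100L + rep)
    maps <- list()
    for (s in 1:6) {
      sub <- generate_subject(spec, s)
      ds <- preprocess_bold(sub$dataset, sub$nuisance)
      lab <- shift_labels(sub$labels, spec$hemodynamic_delay_trs)
      seed <- build_sphere(c(8L, 8L, 8L), 2, ds$mask)
      maps[[s]] <- ic_map(ds, seed, lab, spec$conditions, radius_vox = 2,
                          keep_series = TRUE, subject = s)
    }
    zone <- seed_overlap_zone(maps[[1]]$mask, seed, radius_vox = 2,
                              extra_vox = 2)
    g <- group_connectivity(maps, fwhm_mm = 8, threshold_p = 0.001,
                            alpha = 0.05, n_subject_perms = 20,
                            n_group_maps = 60, exclude = zone,
                            seed = 9200L + rep)
    detected[rep] <- nrow(g$clusters) > 0
  }
  expect_lte(sum(detected), 2)   # P(>=3 | n=6, p=0.05) < 0.3%
})
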