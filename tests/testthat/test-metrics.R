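test_that("nearest-surface distances: identity and facing faces", {
  g <- voxel_grid(c(20, 10, 10))
  occ_a <- array(FALSE, g$shape); occ_a[6, 6, 6] <- TRUE
  occ_b <- array(FALSE, g$shape); occ_b[16, 6, 6] <- TRUE  # centres 10 mm apart
  a <- binary_mask(g, occ_a); b <- binary_mask(g, occ_b)
  expect_equal(nearest_surface_distances(a, a), rep(0, 6))
  d <- nearest_surface_distances(a, b)
  expect_equal(min(d), 9)  # facing faces: 10 - 0.5 - 0.5
})

test_that("kd-tree distances equal the O(n^2) brute-force oracle", {
  for (seed in 1:10) {
    sp <- list(c(1, 1, 1), c(1, 1, 3), c(2, 0.5, 1))[[seed %% 3 + 1]]
    g <- voxel_grid(c(12, 11, 10), spacing = sp)
    a <- random_mask(g, p = 0.25, seed = seed)
    b <- random_mask(g, p = 0.25, seed = seed + 1000)
    if (!any(a$occupancy) || !any(b$occupancy)) next
    sa <- extract_surface(a); sb <- extract_surface(b)
    expect_equal(nearest_surface_distances(sa, sb),
                 bf_nn(sa$centers, sb$centers), tolerance = 1e-9)
  }
})

test_that("Dice: identity, disjoint, nested, and analytic sphere value", {
  g <- voxel_grid(c(16, 16, 8))
  a <- random_mask(g, p = 0.3, seed = 3)
  expect_equal(dice(a, a), 1)
  occ1 <- array(FALSE, g$shape); occ1[1:3, 1:3, 1:3] <- TRUE
  occ2 <- array(FALSE, g$shape); occ2[10:12, 10:12, 5:7] <- TRUE
  expect_equal(dice(binary_mask(g, occ1), binary_mask(g, occ2)), 0)
  # nested masks A subset of B: dice = 2|A| / (|A|+|B|) exactly
  occ3 <- occ1; occ3[1:5, 1:5, 1:5] <- TRUE
  expect_equal(dice(binary_mask(g, occ1), binary_mask(g, occ3)),
               2 * sum(occ1) / (sum(occ1) + sum(occ3)))
  expect_error(dice(binary_mask(g, array(FALSE, g$shape)),
                    binary_mask(g, array(FALSE, g$shape))), "undefined")
})

test_that("concentric spheres r=20/R=25 give the analytic Dice", {
  g <- voxel_grid(c(64, 64, 64))
  ctr <- c(31.5, 31.5, 31.5)
  expect_equal(dice(sphere_mask(g, ctr, 20), sphere_mask(g, ctr, 25)),
               2 * 20^3 / (20^3 + 25^3), tolerance = 0.01 / 0.677)
})

test_that("surface Dice: identity, symmetry, oracle, monotone tolerance", {
  g <- voxel_grid(c(14, 12, 10), spacing = c(1, 1, 2))
  a <- random_mask(g, p = 0.3, seed = 11)
  b <- random_mask(g, p = 0.3, seed = 12)
  expect_equal(surface_dice(a, a), 1)
  cfg <- tolerance_config(sdsc_tolerance = 2)
  expect_equal(surface_dice(a, b, cfg), surface_dice(b, a, cfg))
  # area-weighted brute-force value
  sa <- extract_surface(a); sb <- extract_surface(b)
  dab <- bf_nn(sa$centers, sb$centers); dba <- bf_nn(sb$centers, sa$centers)
  expect_equal(surface_dice(a, b, cfg),
               (sum(sa$areas[dab <= 2]) + sum(sb$areas[dba <= 2])) /
                 (sum(sa$areas) + sum(sb$areas)))
  # non-decreasing in tolerance; limits
  tols <- c(0, 1, 3, 5, 10, 1e6)
  vals <- vapply(tols, function(t)
    surface_dice(a, b, tolerance_config(sdsc_tolerance = t)), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)
})

test_that("directed percentile Hausdorff: identity, offset spheres, asymmetry", {
  g <- voxel_grid(c(60, 50, 50))
  ctr <- c(22.5, 24.5, 24.5)
  s0 <- sphere_mask(g, ctr, 15)
  expect_equal(directed_percentile_hd(s0, s0), 0)
  cfg100 <- tolerance_config(hd_percentile = 100)
  for (t in c(2, 5)) {
    st <- sphere_mask(g, ctr + c(t, 0, 0), 15)
    hd100 <- directed_percentile_hd(st, s0, cfg100)
    expect_lt(abs(hd100 - t), sqrt(3))
    expect_lte(directed_percentile_hd(st, s0), hd100)
  }
  # small mask near the edge of a large one: direction matters
  small <- sphere_mask(g, ctr + c(8, 0, 0), 3)
  big <- sphere_mask(g, ctr, 15)
  expect_gt(abs(directed_percentile_hd(small, big, cfg100) -
                  directed_percentile_hd(big, small, cfg100)), 1)
  # symmetric variant is the max of both directions
  expect_equal(directed_percentile_hd(small, big, cfg100, symmetric = TRUE),
               max(directed_percentile_hd(small, big, cfg100),
                   directed_percentile_hd(big, small, cfg100)))
})

test_that("percentile uses linear interpolation over per-element distances", {
  g <- voxel_grid(c(30, 10, 10))
  occ_a <- array(FALSE, g$shape); occ_a[5, 5, 5] <- TRUE
  occ_b <- array(FALSE, g$shape); occ_b[25, 5, 5] <- TRUE
  a <- binary_mask(g, occ_a); b <- binary_mask(g, occ_b)
  d <- bf_nn(extract_surface(a)$centers, extract_surface(b)$centers)
  expect_equal(directed_percentile_hd(a, b,
                                      tolerance_config(hd_percentile = 75)),
               unname(quantile(d, 0.75, type = 7)))
})

test_that("MDA: identity, one-voxel dilation, brute-force equality", {
  g <- voxel_grid(c(20, 20, 20))
  occ <- array(FALSE, g$shape); occ[8:13, 8:13, 8:13] <- TRUE
  m <- binary_mask(g, occ)
  expect_equal(mean_distance_to_agreement(m, m), c(mean = 0, sd = 0))
  # dilate by one voxel (6-neighbourhood closure of a cube = bigger cube)
  occ_d <- array(FALSE, g$shape); occ_d[7:14, 7:14, 7:14] <- TRUE
  md <- mean_distance_to_agreement(binary_mask(g, occ_d), m)
  expect_lt(abs(md[["mean"]] - 1), 0.5)
  # population SD against the oracle
  a <- random_mask(g, p = 0.1, seed = 21)
  b <- random_mask(g, p = 0.1, seed = 22)
  d <- bf_nn(extract_surface(a)$centers, extract_surface(b)$centers)
  got <- mean_distance_to_agreement(a, b)
  expect_equal(got[["mean"]], mean(d), tolerance = 1e-9)
  expect_equal(got[["sd"]], sqrt(mean((d - mean(d))^2)), tolerance = 1e-9)
})

test_that("all metrics are invariant under a shared voxel-aligned shift", {
  g <- voxel_grid(c(24, 24, 16), spacing = c(1, 1, 3))
  occ_a <- array(FALSE, g$shape); occ_a[4:10, 4:10, 3:7] <- TRUE
  occ_b <- array(FALSE, g$shape); occ_b[6:12, 5:11, 4:8] <- TRUE
  a <- binary_mask(g, occ_a); b <- binary_mask(g, occ_b)
  # translate both occupancies by the same voxel offset
  tr <- function(occ, by = c(7, 7, 6)) {
    out <- array(FALSE, g$shape)
    out[(1 + by[1]):g$shape[1], (1 + by[2]):g$shape[2],
        (1 + by[3]):g$shape[3]] <-
      occ[1:(g$shape[1] - by[1]), 1:(g$shape[2] - by[2]),
          1:(g$shape[3] - by[3])]
    out
  }
  at <- binary_mask(g, tr(occ_a)); bt <- binary_mask(g, tr(occ_b))
  expect_equal(dice(at, bt), dice(a, b))
  expect_equal(surface_dice(at, bt), surface_dice(a, b))
  expect_equal(directed_percentile_hd(at, bt), directed_percentile_hd(a, b))
  expect_equal(mean_distance_to_agreement(at, bt),
               mean_distance_to_agreement(a, b))
})

test_that("per-case metrics use each observer's own group consensus", {
  case <- unanimous_case()
  recs <- compute_case_metrics(case)
  expect_equal(nrow(recs), 9)
  expect_true(all(recs$dsc == 1 & recs$sdsc == 1))
  expect_true(all(recs$hd98 == 0 & recs$mda_mean == 0))
  expect_setequal(unique(recs$group), c("RAD", "GTV-", "GTV+"))

  # single-observer group: median of one is itself
  g <- voxel_grid(c(10, 10, 6))
  m <- random_mask(g, p = 0.4, seed = 5)
  solo <- case_study("solo", list("GTV-" = observer_set(list(m), "o1", "GTV-")))
  rec1 <- compute_case_metrics(solo)
  expect_equal(rec1$dsc, 1)
  expect_equal(rec1$hd98, 0)
})

test_that("leave-one-out reference is available and differs when it should", {
  g <- voxel_grid(c(12, 12, 6))
  big <- array(FALSE, g$shape); big[3:9, 3:9, 2:5] <- TRUE
  masks <- list(binary_mask(g, big), binary_mask(g, big),
                binary_mask(g, big))
  off <- array(FALSE, g$shape); off[5:11, 5:11, 2:5] <- TRUE
  masks[[4]] <- binary_mask(g, off)
  cs <- case_study("c", list("GTV-" = observer_set(masks, paste0("o", 1:4),
                                                   "GTV-")))
  rin <- compute_case_metrics(cs, reference_rule = "majority")
  rout <- compute_case_metrics(cs, reference_rule = "majority_loo")
  # with 3/4 identical masks the majority equals `big` either way for them;
  # both rules must still give perfect agreement for the majority observers
  expect_true(all(rin$dsc[1:3] == 1))
  expect_true(all(rout$dsc[1:3] == 1))
})

test_that("metrics reject empty masks and incompatible grids", {
  g <- voxel_grid(c(6, 6, 6))
  m <- random_mask(g, p = 0.4, seed = 2)
  e <- binary_mask(g, array(FALSE, g$shape))
  expect_error(surface_dice(m, e), "non-empty")
  expect_error(directed_percentile_hd(e, m), "non-empty")
  expect_error(mean_distance_to_agreement(m, e), "non-empty")
  g2 <- voxel_grid(c(6, 6, 6), origin = c(1, 0, 0))
  expect_error(dice(m, binary_mask(g2, m$occupancy)), "incompatible")
})
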