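test_that("segmentation finds dark components within the area window", {
  expect_equal(segment_nuclei(matrix(200, 30, 30)), list())  # blank field

  f <- matrix(240, 60, 60)
  dm <- disk_mask(10)
  f[10 + seq_len(nrow(dm)), 10 + seq_len(ncol(dm))][dm] <- 40
  nuc <- segment_nuclei(f, min_area = 50)
  expect_length(nuc, 1)
  expect_lt(abs(nuc[[1]]$n_pixels - sum(dm)) / sum(dm), 0.02)

  # second disk below min_area is discarded
  f[2:4, 2:4] <- 40
  nuc2 <- segment_nuclei(f, min_area = 50)
  expect_length(nuc2, 1)

  # holes are filled before the area filter
  fh <- matrix(240, 40, 40)
  dm2 <- disk_mask(8)
  fh[5 + seq_len(nrow(dm2)), 5 + seq_len(ncol(dm2))][dm2] <- 40
  ctr <- 5 + ceiling(nrow(dm2) / 2)
  fh[ctr, ctr] <- 240
  nuch <- segment_nuclei(fh, min_area = 50)
  expect_length(nuch, 1)
  expect_equal(nuch[[1]]$n_pixels, sum(dm2))
})

test_that("roundness approaches the continuous form factor", {
  expect_lt(abs(compute_roundness(uniform_nucleus(disk_mask(50))) - 1), 0.05)
  ell <- uniform_nucleus(ellipse_mask(25, 50))
  expect_lt(abs(compute_roundness(ell) - ramanujan_ff(2)), 0.05)
  # error decays monotonically with resolution
  errs <- vapply(c(10, 25, 50), function(r)
    abs(compute_roundness(uniform_nucleus(disk_mask(r))) - 1), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("roundness is invariant under translation and 90-degree rotation", {
  m <- ellipse_mask(12, 21)
  base <- compute_roundness(uniform_nucleus(m))
  shifted <- matrix(FALSE, nrow(m) + 9, ncol(m) + 4)
  shifted[9 + seq_len(nrow(m)), 4 + seq_len(ncol(m))] <- m
  expect_equal(compute_roundness(uniform_nucleus(shifted)), base)
  expect_equal(compute_roundness(uniform_nucleus(t(m))), base)
})

test_that("degenerate masks are rejected", {
  px <- matrix(100, 4, 4)
  msk <- matrix(FALSE, 4, 4)
  msk[2, 2:3] <- TRUE
  expect_error(compute_roundness(nucleus_image(px, msk)), "degenerate mask")
})

test_that("run-length matrices match closed forms on canonical fixtures", {
  const <- nucleus_image(matrix(100, 4, 4), matrix(TRUE, 4, 4))
  m0 <- compute_glrlm(const, gray_bins = 16, directions = 0)
  expect_equal(m0$n_runs, 4)                       # 4 rows, one run each
  expect_equal(sum(m0$counts[, 4]), 4)
  s0 <- glrlm_stats(m0)
  expect_equal(s0$short_run_emphasis, 1 / 16)
  expect_equal(s0$long_run_emphasis, 16)
  expect_equal(s0$run_percentage, 0.25)
  expect_equal(s0$mean_run_length, 4)

  chk <- matrix(ifelse(outer(1:4, 1:4, `+`) %% 2 == 0, 30, 220), 4, 4)
  board <- nucleus_image(chk, matrix(TRUE, 4, 4))
  mc <- compute_glrlm(board, gray_bins = 16, directions = 0)
  expect_equal(mc$n_runs, 16)                      # all runs length 1
  sc <- glrlm_stats(mc)
  expect_equal(sc$short_run_emphasis, 1)
  expect_equal(sc$long_run_emphasis, 1)
  expect_equal(sc$run_percentage, 1)
})

test_that("run enumeration equals the naive scanner on random fixtures", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      side <- sample(6:8, 1)
      px <- matrix(sample(0:255, side^2, replace = TRUE), side, side)
      mask <- matrix(stats::runif(side^2) < 0.85, side, side)
      mask[sample(side^2, 1)] <- TRUE            # ensure nonempty
    })
    n <- nucleus_image(px, mask)
    G <- if (seed %% 2 == 0) 4 else 16
    q <- quantize_bins(px, mask, G)
    for (d in c(0, 45, 90, 135)) {
      got <- compute_glrlm(n, gray_bins = G, directions = d)
      want <- naive_glrlm(q, mask, d, G)
      expect_equal(unname(got$per_direction[[as.character(d)]]), want,
                   info = sprintf("seed %d dir %d", seed, d))
      # per-direction pixel conservation
      jw <- matrix(seq_len(ncol(want)), nrow(want), ncol(want), byrow = TRUE)
      expect_equal(sum(jw * want), sum(mask))
    }
    # stats agree with sums over enumerated runs
    all4 <- compute_glrlm(n, gray_bins = G, directions = c(0, 45, 90, 135))
    st <- glrlm_stats(all4)
    cnt <- Reduce(`+`, lapply(c(0, 45, 90, 135), function(d)
      naive_glrlm(q, mask, d, G)))
    j2 <- matrix(seq_len(ncol(cnt))^2, nrow(cnt), ncol(cnt), byrow = TRUE)
    expect_equal(st$run_count, sum(cnt))
    expect_equal(st$short_run_emphasis, sum(cnt / j2) / sum(cnt))
    expect_equal(st$long_run_emphasis, sum(cnt * j2) / sum(cnt))
  }
})

test_that("run-length statistics obey their structural identities", {
  for (seed in 7:10) {
    withr::with_seed(seed, {
      px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    })
    n <- nucleus_image(px, matrix(TRUE, 8, 8))
    st <- glrlm_stats(compute_glrlm(n, gray_bins = 4))
    expect_lte(st$short_run_emphasis, 1)
    expect_gte(st$long_run_emphasis, 1)
    expect_equal(st$run_percentage * st$mean_run_length, 1)
    all_unit <- st$run_count == n$n_pixels * 2    # two directions
    expect_equal(st$short_run_emphasis == 1 && st$long_run_emphasis == 1,
                 all_unit)
  }
})

test_that("light-pixel counting matches the histogram tail", {
  dark <- nucleus_image(matrix(0, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(count_light_pixels(dark), 0)
  light <- nucleus_image(matrix(255, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(count_light_pixels(light, 128), 25)

  withr::with_seed(1, {
    px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    mask <- matrix(stats::runif(100) < 0.7, 10, 10)
  })
  n <- nucleus_image(px, mask)
  for (thr in c(0, 100, 180, 255))
    expect_equal(count_light_pixels(n, thr), sum(px[mask] > thr))
  expect_error(count_light_pixels(n, 300), "light_threshold")
})

test_that("the feature vector is stable and component-wise consistent", {
  disk <- uniform_nucleus(disk_mask(12), intensity = 100)
  fv <- extract_features(disk)
  expect_named(fv, c("nuclear_roundness", "rlm_summary",
                     "short_run_emphasis", "long_run_emphasis",
                     "run_percentage", "n_light_pixels", "run_count",
                     "area", "perimeter", "mean_intensity", "sd_intensity"))
  expect_identical(names(fv), names(extract_features(disk)))
  expect_equal(unname(fv["nuclear_roundness"]), compute_roundness(disk))
  expect_equal(unname(fv["n_light_pixels"]), count_light_pixels(disk))
  st <- glrlm_stats(compute_glrlm(disk))
  expect_equal(unname(fv["short_run_emphasis"]), st$short_run_emphasis)
  expect_equal(unname(fv["rlm_summary"]), st$mean_run_length)
  expect_equal(unname(fv["area"]), sum(disk$mask))
  expect_equal(unname(fv["sd_intensity"]), 0)
})
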