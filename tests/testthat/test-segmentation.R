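test_that("thresholding is exact and monotone", {
  z <- phase_map(matrix(0, 8, 8), 0.16, background_subtracted = TRUE)
  expect_false(any(threshold_mask(z, 0.3)))
  f <- phase_map(matrix(seq(0, 2, length.out = 64), 8, 8),
                 0.16, background_subtracted = TRUE)
  m1 <- threshold_mask(f, 0.2)
  m2 <- threshold_mask(f, 0.8)
  expect_true(all(which(m2) %in% which(m1)))  # mask(tau2) subset of mask(tau1)
  expect_identical(threshold_mask(f, 0.5), f$values >= 0.5)
  w <- phase_map(matrix(0.5, 4, 4), 0.16, wrapped = TRUE)
  expect_error(threshold_mask(w), "unwrapped")
})

test_that("label equivalence handles canonical connectivity cases", {
  b <- matrix(FALSE, 5, 5); b[2:4, 2:4] <- TRUE
  lm <- label_components(b)
  expect_equal(lm$n_components, 1L)
  expect_true(all(lm$labels[b] == 1L))
  expect_true(all(lm$labels[!b] == 0L))
  # two pixels touching only diagonally
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(label_components(d, 8)$n_components, 1L)
  expect_equal(label_components(d, 4)$n_components, 2L)
  # empty mask
  expect_equal(label_components(matrix(FALSE, 3, 3))$n_components, 0L)
  # non-binary input
  expect_error(label_components(matrix(c(0, 2, 1, 0), 2, 2)), "binary")
  expect_error(label_components(matrix(0.5, 2, 2)), "binary")
})

test_that("label equivalence agrees with the flood-fill oracle", {
  for (s in 1:10) {
    mask <- withr::with_seed(s, matrix(runif(48 * 48) < 0.4, 48, 48))
    for (conn in c(4, 8)) {
      mine <- label_components(mask, conn)
      oracle <- flood_fill_labels(mask, conn)
      expect_true(same_partition(mine$labels, oracle),
                  info = sprintf("seed %d conn %d", s, conn))
      # labels are compact 1..K
      expect_identical(sort(unique(as.vector(mine$labels[mask]))),
                       seq_len(mine$n_components))
    }
  }
})

test_that("cell extraction applies volume, border and size filters", {
  p <- 0.5  # um/px -> pixel area 0.25 um^2
  n <- 40
  H <- matrix(0, n, n)
  L <- matrix(0L, n, n)
  # cell A: 20x20 block, h = 1 um -> 100 um^2 * 1 um = 100 fL
  L[5:24, 3:22] <- 1L; H[5:24, 3:22] <- 1
  # cell B: 6x6 block, h = 1 um -> 9 fL (platelet-sized)
  L[30:35, 5:10] <- 2L; H[30:35, 5:10] <- 1
  # cell C: touches the border, large
  L[1:12, 28:39] <- 3L; H[1:12, 28:39] <- 2
  hm <- height_map(H, p)
  cells <- extract_cells(L, hm, min_volume_fl = 20)
  expect_length(cells, 1)
  expect_equal(cells[[1]]$volume_fl, 100)
  expect_equal(cells[[1]]$n_px, 400L)
  # disabling both filters returns everything
  all3 <- extract_cells(L, hm, min_volume_fl = 0, exclude_border = FALSE)
  expect_length(all3, 3)
  # the speck filter
  expect_length(extract_cells(L, hm, min_volume_fl = 0,
                              exclude_border = FALSE, min_px = 50), 2)
  # negative heights are clamped and counted
  H2 <- H; H2[10, 10] <- -0.5
  c2 <- extract_cells(L, height_map(H2, p), min_volume_fl = 20)
  expect_equal(c2[[1]]$n_clamped, 1L)
  expect_equal(c2[[1]]$volume_fl, 100 - 0.25)
})

test_that("segment_phase records its threshold provenance", {
  f <- phase_map(matrix(c(rep(0, 40), rep(1, 24)), 8, 8), 0.16,
                 background_subtracted = TRUE)
  lm <- segment_phase(f, tau = 0.4)
  expect_equal(lm$tau, 0.4)
  expect_equal(lm$n_components, 1L)
})
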