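test_that("grid construction places positions every step_cm per chromosome", {
  map <- linear_map(100)
  expect_equal(nrow(build_grid(map, 0.02)), 5001L)
  g10 <- build_grid(linear_map(rep(100, 10)), 0.02)
  expect_equal(nrow(g10), 50010L)  # the usual '50,000 tests' layout, exactly
  expect_equal(nrow(build_grid(linear_map(1), 0.05)), 21L)
  # uniform spacing within chromosome
  for (ch in unique(g10$chrom)) {
    d <- diff(g10$cm[g10$chrom == ch])
    expect_true(all(abs(d - 0.02) < 1e-9))
  }
  # a chromosome shorter than the step still contributes one position
  tiny <- build_grid(linear_map(c(100, 0.01)), 0.05)
  expect_equal(sum(tiny$chrom == "2"), 1L)
})

test_that("ibd_rate matches hand-computed small cases", {
  map <- linear_map(10)
  grid <- build_grid(map, 1)
  # no segments -> all zero
  none <- ibd_segment_table(character(), integer(), character(), integer(),
                            character(), numeric(), numeric(), numeric())
  expect_equal(ibd_rate(none, grid, c("a", "b"))$rate, rep(0, nrow(grid)))
  # 2 diploid samples: 4 eligible pairs; one segment covering a position
  seg <- ibd_segment_table("a", 1, "b", 1, "1", 4e6, 6e6, 2)
  rs <- ibd_rate(seg, grid, c("a", "b"))
  expect_equal(rs$n_pairs, 4)
  expect_equal(rs$rate[grid$cm == 5], 0.25)
  # half-open interval: position at end_bp does not overlap
  expect_equal(rs$rate[grid$cm == 6], 0)
  expect_equal(rs$rate[grid$cm == 4], 0.25)
  expect_error(ibd_rate(seg, grid, "a"), "at least 2")
})

test_that("ibd_rate equals the brute-force pair-by-position oracle", {
  ids <- sprintf("s%02d", 1:20)
  for (seed in c(2, 9)) {
    segments <- random_segments(50, ids, c(50, 40), seed = seed)
    grid <- build_grid(linear_map(c(50, 40)), 0.5)
    fast <- ibd_rate(segments, grid, ids)
    slow <- brute_rate(segments, grid, ids)
    expect_equal(fast$n_pairs, slow$n_pairs)
    expect_equal(fast$rate, slow$rate)
  }
  # duplicated overlapping segments for one pair must not double count
  seg2 <- ibd_segment_table(c("a", "a"), c(1, 1), c("b", "b"), c(1, 1),
                            c("1", "1"), c(1e6, 2e6), c(5e6, 8e6), c(4, 6))
  grid <- build_grid(linear_map(20), 1)
  rs <- ibd_rate(seg2, grid, c("a", "b"))
  expect_equal(max(rs$rate), 0.25)
})

test_that("robust standardization masks outliers and normalizes the difference", {
  grid <- build_grid(linear_map(c(100, 100)), 0.1)
  M <- nrow(grid)
  set.seed(5)
  y1 <- 0.001 + 0.0001 * rnorm(M)
  y0 <- 0.001 + 0.0001 * rnorm(M)
  # spike one case position at median + 10 sd
  spike <- 500L
  y1[spike] <- median(y1) + 10 * sd(y1)
  base <- robust_standardize(list(rate = y1), list(rate = y0), grid)
  expect_true(base$excluded[spike])
  expect_false(is.na(base$z_diff[spike]))  # masked positions still reported
  stats <- attr(base, "standardization")
  # masked position does not move the revised moments
  y1_clean <- y1; y1_clean[spike] <- NA
  expect_equal(stats$case$mean, mean(y1_clean, na.rm = TRUE), tolerance = 1e-12)
  # mean 0, sd 1 over unmasked positions by construction
  expect_equal(mean(base$z_diff[!base$excluded]), 0, tolerance = 1e-9)
  expect_equal(sd(base$z_diff[!base$excluded]), 1, tolerance = 1e-9)
})

test_that("standardization is invariant to affine rescaling of the rates", {
  grid <- build_grid(linear_map(100), 0.1)
  M <- nrow(grid)
  set.seed(6)
  y1 <- 0.002 + 0.0002 * rnorm(M)
  y0 <- 0.002 + 0.0002 * rnorm(M)
  a <- robust_standardize(list(rate = y1), list(rate = y0), grid)
  b <- robust_standardize(list(rate = 3 * y1 + 0.01),
                          list(rate = 3 * y0 + 0.01), grid)
  expect_equal(a$z_diff, b$z_diff, tolerance = 1e-9)
  expect_equal(a$excluded, b$excluded)
})

test_that("degenerate standardization inputs error out", {
  grid <- build_grid(linear_map(10), 1)
  y <- list(rate = seq(0, 0.01, length.out = nrow(grid)))
  expect_error(robust_standardize(y, y, grid), "zero variance")
  flat <- list(rate = rep(0.001, nrow(grid)))
  expect_error(robust_standardize(flat, flat, grid), "standard deviation is zero")
  expect_error(selection_scan(
    ibd_segment_table(character(), integer(), character(), integer(),
                      character(), numeric(), numeric(), numeric()),
    c("a", "b"), grid), "standard deviation is zero")
})

test_that("pointwise p-values are upper-tail standard normal", {
  expect_equal(pointwise_pvalue(0), 0.5)
  expect_equal(signif(pointwise_pvalue(5.82), 3), 2.94e-9)
  expect_equal(signif(pointwise_pvalue(4.48), 3), 3.73e-6)
  expect_true(all(diff(pointwise_pvalue(seq(-3, 3, 0.5))) < 0))
})

test_that("region calling finds maximal runs and sizes them as k * step", {
  grid <- build_grid(linear_map(10), 0.05)
  z <- rep(0, nrow(grid))
  track <- data.table::data.table(chrom = grid$chrom, bp = grid$bp,
                                  cm = grid$cm, z_diff = z,
                                  excluded = rep(FALSE, nrow(grid)))
  data.table::setattr(track, "step_cm", 0.05)
  expect_equal(nrow(call_regions(track, 4)), 0L)

  # single position above threshold: size is one step (0.05 cM)
  track$z_diff[50] <- 5
  reg <- call_regions(track, 4)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$size_cm, 0.05)
  expect_equal(reg$start_cm, reg$end_cm)
  expect_equal(reg$argmax_cm, grid$cm[50])

  # two runs split by one sub-threshold position
  track$z_diff[60:62] <- c(4.5, 3.9, 4.5)
  reg <- call_regions(track, 4)
  expect_equal(nrow(reg), 3L)

  # masked positions cannot extend a region unless requested
  track$excluded[50] <- TRUE
  expect_equal(nrow(call_regions(track, 4)), 2L)
  expect_equal(nrow(call_regions(track, 4, test_excluded = TRUE)), 3L)
})

test_that("region calling is invariant to chromosome processing order", {
  grid <- build_grid(linear_map(c(30, 30)), 0.1)
  set.seed(8)
  track <- data.table::data.table(chrom = grid$chrom, bp = grid$bp,
                                  cm = grid$cm, z_diff = rnorm(nrow(grid)),
                                  excluded = rep(FALSE, nrow(grid)))
  data.table::setattr(track, "step_cm", 0.1)
  fwd <- call_regions(track, 2)
  rev_track <- track[rev(seq_len(nrow(track)))]
  data.table::setattr(rev_track, "step_cm", 0.1)
  # within-chromosome position order restored; chromosome order reversed
  rev_track <- rev_track[order(match(chrom, unique(chrom)), cm)]
  data.table::setattr(rev_track, "step_cm", 0.1)
  bwd <- call_regions(rev_track, 2)
  data.table::setorder(fwd, chrom, start_cm)
  data.table::setorder(bwd, chrom, start_cm)
  expect_equal(as.data.frame(fwd), as.data.frame(bwd))
})

test_that("selection scan is the one-sample path of the same machinery", {
  x <- generate_null(synthetic_spec(n_cases = 30, n_controls = 30,
                                    chrom_cm = c(80, 80)), seed = 21)
  grid <- build_grid(x$map, 0.1)
  controls <- x$phenotypes$id[x$phenotypes$status == 0L]
  one <- selection_scan(x$segments, controls, grid)
  cases <- x$phenotypes$id[x$phenotypes$status == 1L]
  two <- robust_standardize(ibd_rate(x$segments, grid, cases),
                            ibd_rate(x$segments, grid, controls), grid)
  # same standardized control track wherever the two-sample mask agrees
  ok <- !two$excluded & !one$excluded
  expect_equal(one$z_diff[ok], two$z_control[ok], tolerance = 1e-9)
})

test_that("selection scan detects uniformly shared loci that cancel in the difference", {
  x <- generate_null(synthetic_spec(n_cases = 60, n_controls = 60,
                                    chrom_cm = c(100, 100)), seed = 31)
  # carrier locus shared by cases and controls alike
  x <- inject_carrier_confounder(x, list(chrom = "1", cm = 50), f = 0.3,
                                 seed = 32)
  grid <- build_grid(x$map, 0.1)
  all_ids <- x$phenotypes$id
  sel <- selection_scan(x$segments, all_ids, grid)
  at_locus <- which(sel$chrom == "1" & abs(sel$cm - 50) < 0.2)
  expect_gt(max(sel$z_diff[at_locus]), 10)  # excess sharing is unmissable
  # whereas the case-control difference at the locus is modest
  cc <- scan_synthetic(x, step_cm = 0.1)
  expect_lt(max(cc$track$z_diff[at_locus]),
            max(sel$z_diff[at_locus]))
})

test_that("randomized phenotype labels preserve the sample set and reuse segments", {
  x <- generate_null(synthetic_spec(n_cases = 20, n_controls = 21,
                                    chrom_cm = c(60, 60)), seed = 41)
  grid <- build_grid(x$map, 0.1)
  track <- randomized_phenotype_scan(x$segments, x$phenotypes, grid, seed = 9)
  fake_cases <- attr(track, "permuted_cases")
  expect_equal(length(fake_cases), 20L)  # odd count: extra sample to controls
  expect_setequal(c(fake_cases, setdiff(x$phenotypes$id, fake_cases)),
                  x$phenotypes$id)
  again <- randomized_phenotype_scan(x$segments, x$phenotypes, grid, seed = 9)
  expect_identical(track$z_diff, again$z_diff)
  other <- randomized_phenotype_scan(x$segments, x$phenotypes, grid, seed = 10)
  expect_false(identical(attr(other, "permuted_cases"), fake_cases))
})
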