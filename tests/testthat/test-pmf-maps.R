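# Free-energy map loading, synthesis, feature extraction and sampling.

test_that("map files round-trip through both dialects, with normalization, unit and domain handling", {
  m <- make_twowell_map(gap = 2.4, grid = c(60, 60))

  for (dialect in c("xyz", "matrix")) {
    tf <- tempfile(fileext = ".map")
    write_map(m, tf, dialect = dialect)
    m2 <- load_map(tf, grid_spec = c(60, 60))
    expect_equal(m2$grid, m$grid, tolerance = 1e-8)
  }

  # constant map normalizes to all-zero
  tf <- tempfile()
  df <- expand.grid(phi = (0:19) * 2 * pi / 20, psi = (0:19) * 2 * pi / 20)
  writeLines(sprintf("%f %f 3.0", df$phi, df$psi), tf)
  flat <- load_map(tf, grid_spec = c(20, 20))
  expect_true(all(flat$grid == 0))
  expect_equal(flat$offset, 3.0)

  # one bin at -5, rest at 0: normalized grid is 0 there, +5 elsewhere
  g <- df
  g$G <- ifelse(seq_len(nrow(g)) == 7, -5, 0)
  writeLines(sprintf("%f %f %f", g$phi, g$psi, g$G), tf)
  m5 <- load_map(tf, grid_spec = c(20, 20))
  expect_equal(sort(unique(as.vector(m5$grid))), c(0, 5))
  expect_equal(sum(m5$grid == 0), 1)

  # kJ/mol header: energies divided by k_BT at 298 K
  writeLines(c("# energies in kJ/mol", sprintf("%f %f %f", df$phi, df$psi,
                                               rep(c(0, 2.479), length.out = nrow(df)))), tf)
  mkj <- load_map(tf, grid_spec = c(20, 20))
  expect_equal(max(mkj$grid), 1, tolerance = 1e-3)

  # [-pi, pi) domain is shifted onto [0, 2*pi)
  df2 <- expand.grid(phi = ((0:19) - 10) * 2 * pi / 20, psi = (0:19) * 2 * pi / 20)
  df2$G <- ifelse(abs(df2$phi - (-pi / 2)) < 1e-9 & abs(df2$psi - pi) < 1e-9, -1, 0)
  writeLines(sprintf("%f %f %f", df2$phi, df2$psi, df2$G), tf)
  ms <- load_map(tf, grid_spec = c(20, 20))
  mins <- find_minima(ms)
  expect_equal(mins$phi[1], 3 * pi / 2, tolerance = 0.02)
  expect_equal(mins$psi[1], pi, tolerance = 0.02)
})

test_that("loader rejects malformed rows and non-rectangular grids, naming the problem", {
  tf <- tempfile()
  df <- expand.grid(phi = (0:9) * 2 * pi / 10, psi = (0:9) * 2 * pi / 10)
  lines <- sprintf("%f %f 1.0", df$phi, df$psi)
  lines[42] <- "0.1 not-a-number 3"
  writeLines(lines, tf)
  expect_error(load_map(tf), "line 42")

  writeLines(lines[-c(42, 43)], tf)   # drop rows: grid incomplete
  expect_error(load_map(tf), "non-rectangular")

  writeLines(c("0.0 0.0", "0.1 0.1"), tf)  # dense dialect without header
  expect_error(load_map(tf), "header")

  expect_error(load_map(tempfile()), "not found")
})

test_that("interpolation is periodic across the seam and exact at the nodes", {
  m <- make_twowell_map(grid = c(64, 64))
  psi <- seq(0.1, 6.1, length.out = 23)
  expect_equal(map_interpolate(m, rep(0, 23), psi),
               map_interpolate(m, rep(2 * pi, 23), psi), tolerance = 1e-12)
  phi <- seq(0.1, 6.1, length.out = 23)
  expect_equal(map_interpolate(m, phi, rep(0, 23)),
               map_interpolate(m, phi, rep(2 * pi, 23)), tolerance = 1e-12)
  # node values are the grid values
  i <- c(0, 5, 31, 63); j <- c(0, 17, 2, 63)
  expect_equal(map_interpolate(m, i * 2 * pi / 64, j * 2 * pi / 64),
               m$grid[cbind(i + 1, j + 1)], tolerance = 1e-12)
})

test_that("feature extraction recovers the generator parameters of synthetic maps", {
  gap <- 4.0
  m <- make_twowell_map(gap = gap, grid = c(200, 200),
                        centers = list(c(4.997, 2.188), c(2.0, 5.0)))
  mins <- find_minima(m)
  bin <- 2 * pi / 200
  expect_equal(nrow(mins), 2)
  expect_lt(abs(mins$phi[1] - 4.997), bin)
  expect_lt(abs(mins$psi[1] - 2.188), bin)
  expect_lt(abs(mins$phi[2] - 2.0), bin)
  expect_equal(delta_g2(m), gap, tolerance = 0.02)

  # a 2.4 kT construction gap is recovered as well
  m24 <- make_twowell_map(gap = 2.4, grid = c(120, 120))
  expect_equal(delta_g2(m24), 2.4, tolerance = 0.02)

  # area fractions equal a brute-force count over the grid
  for (thr in c(1, 5, 12)) {
    expect_identical(accessible_area_fraction(m, thr),
                     sum(m$grid <= thr) / length(m$grid))
    expect_identical(accessible_area_fraction(m, thr, strict = TRUE),
                     sum(m$grid < thr) / length(m$grid))
  }
  expect_equal(accessible_area_fraction(m, Inf), 1)
})

test_that("single-well and flat maps are classified correctly", {
  m1 <- make_onewell_map()
  mins <- find_minima(m1)
  expect_equal(nrow(mins), 1)
  expect_true(is.na(delta_g2(m1)))

  flat <- new_dihedral_map(matrix(2, 30, 30))
  fm <- find_minima(flat)
  expect_equal(nrow(fm), 0)
  expect_true(attr(fm, "flat"))
  expect_equal(accessible_area_fraction(flat, 0.5), 1)  # normalized to zero

  # synthesize warns when wells merge into one minimum
  expect_warning(
    synthesize_map(data.frame(phi = c(1, 1.05), psi = c(1, 1.05), depth = c(10, 8),
                              width_phi = 0.4, width_psi = 0.4),
                   background = 10, grid_spec = c(60, 60)),
    "merged"
  )
})

test_that("restricted-region sampling is uniform over allowed bins and never leaves them", {
  m <- make_twowell_map(gap = 2.0, grid = c(40, 40))
  reg <- restrict_map(m, 7)
  expect_true(all(m$grid[reg$allowed] <= 7))
  expect_gte(reg$bin_count, 1)

  set.seed(42)
  n <- 40000
  s <- sample_region(reg, n)
  # nearest node of every sample is an allowed node
  ni <- (round(s[, 1] / (2 * pi / 40)) %% 40) + 1
  nj <- (round(s[, 2] / (2 * pi / 40)) %% 40) + 1
  cells <- (nj - 1) * 40 + ni
  expect_true(all(cells %in% reg$allowed))
  # uniform occupancy across allowed bins
  counts <- table(factor(cells, levels = reg$allowed))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
  # interpolated energy never exceeds cutoff by more than the within-bin
  # interpolation variation
  G <- map_interpolate(m, s[, 1], s[, 2])
  tol <- max(abs(diff(m$grid[, 1]))) + max(abs(diff(t(m$grid)[, 1])))
  expect_lt(max(G), 7 + tol)

  expect_equal(restrict_map(m, Inf)$bin_count, 40 * 40)
})

test_that("map library lookup follows monomer states and reports missing keys", {
  lib <- small_library()
  m <- map_for_link(lib, "GlcNH3+", "GlcNAc")
  expect_equal(m$link_key, "GlcNH3+-GlcNAc")

  # protonating the left monomer of a (GlcNH2, GlcNH2) link changes the key
  seqn <- build_sequence(2, 1)
  before <- monomer_state_labels(seqn, c(0L, 0L))
  after <- monomer_state_labels(seqn, c(1L, 0L))
  expect_equal(link_key(before[1], before[2]), "GlcNH2-GlcNH2")
  expect_equal(link_key(after[1], after[2]), "GlcNH3+-GlcNH2")

  incomplete <- map_library(lib$maps[1:3], cutoff = 7)
  expect_error(validate_library(incomplete), "GlcNH3\\+-GlcNH3\\+")
  expect_error(map_for_link(incomplete, "GlcNH3+", "GlcNH3+"), "missing link type")
  expect_error(map_for_link(lib, "GlcXX", "GlcNAc"), "unknown monomer state")

  tab <- analyze_map_library(lib)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$area_1kt <= tab$area_12kt))
  expect_true(all(tab$delta_g2 >= 0))
})
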