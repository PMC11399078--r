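test_that("CSV reader converts camera pixels to nm with the pixel size", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,photons,lpx,lpy", "0,1,2,500,0.05,0.08"), f)
  locs <- read_localizations(f, pixel_size_nm = 130)
  expect_equal(locs$x, 130)
  expect_equal(locs$y, 260)
  expect_equal(locs$lpx, 6.5)
  # nm-declared CSVs pass through unchanged
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: nm", "frame,x,y,photons,lpx,lpy", "0,130,260,500,6.5,10.4"), f2)
  expect_equal(read_localizations(f2, pixel_size_nm = 130)$x, 130)
})

test_that("reader validates inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,photons,lpx", "0,1,2,500,0.05"), f)
  expect_error(read_localizations(f), "lpy")
  expect_error(read_localizations(f, pixel_size_nm = 0), "pixel_size_nm")
  expect_error(read_localizations("/nonexistent/file.csv"), "not found")
})

test_that("empty tables round-trip without error", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(localization_table(), f)
  locs <- read_localizations(f)
  expect_s3_class(locs, "localization_table")
  expect_equal(nrow(locs), 0)
})

test_that("random tables round-trip losslessly through CSV and HDF5", {
  set.seed(11)
  orig <- locs_from_df(rand_locs(100))
  for (fmt in c("csv", "hdf5")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_localizations(orig, path, pixel_size_nm = 130)
    back <- read_localizations(path, pixel_size_nm = 130)
    expect_equal(as.data.frame(back), as.data.frame(orig), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # the HDF5 sidecar records the pixel size
  path <- withr::local_tempfile(fileext = ".hdf5")
  write_localizations(orig, path, pixel_size_nm = 108)
  meta <- yaml::read_yaml(paste0(tools::file_path_sans_ext(path), ".yaml"))
  expect_equal(meta$pixel_size_nm, 108)
})

test_that("constructor enforces invariants", {
  expect_error(localization_table(0L, 1, 2, 10, 0, 1), "strictly positive")
  expect_error(localization_table(0L, Inf, 2, 10, 1, 1), "finite")
})

test_that("weighted center matches the inverse-variance formula", {
  # two locs, x = (0, 10), lpx = (1, 2) -> (0*1 + 10*0.25)/1.25 = 2.0
  locs <- localization_table(frame = c(0L, 1L), x = c(0, 10), y = c(0, 0),
                             photons = c(1, 1), lpx = c(1, 2), lpy = c(1, 1))
  wc <- weighted_center(locs)
  expect_equal(unname(wc["xc"]), 2.0)
  # equal precisions reduce to the arithmetic mean
  set.seed(3)
  df <- rand_locs(50); df$lpx <- 5; df$lpy <- 5
  wc2 <- weighted_center(locs_from_df(df))
  expect_equal(unname(wc2["xc"]), mean(df$x))
  expect_equal(unname(wc2["yc"]), mean(df$y))
  expect_equal(unname(wc2["center_uncertainty"]), 5 / sqrt(50))
  # single localization is its own center
  one <- locs_from_df(df[1, ])
  expect_equal(unname(weighted_center(one)[c("xc", "yc")]), c(df$x[1], df$y[1]))
  bad <- locs_from_df(df)
  bad$lpx[1] <- -1
  expect_error(weighted_center(bad), "precision")
})

test_that("clustering separates well-spaced clouds and rejects sparse noise", {
  set.seed(7)
  df <- rbind(make_cloud(0, 0, 20, 5), make_cloud(200, 0, 20, 5))
  locs <- locs_from_df(df)
  a <- cluster_localizations(locs, radius = 50, min_locs = 10)
  expect_equal(length(unique(a[a >= 0])), 2)
  expect_true(all(a >= 0))
  # below min_locs everything is noise
  a2 <- cluster_localizations(locs_from_df(df[1:3, ]), radius = 50, min_locs = 5)
  expect_equal(a2, rep(-1L, 3))
  expect_equal(cluster_localizations(localization_table(), radius = 50), integer(0))
})

test_that("clustering is invariant to localization row order", {
  set.seed(8)
  df <- do.call(rbind, lapply(1:20, function(i) {
    make_cloud(runif(1, 0, 3000), runif(1, 0, 3000), rpois(1, 20) + 1, 4)
  }))
  locs <- locs_from_df(df)
  a <- cluster_localizations(locs, radius = 12, min_locs = 5)
  perm <- sample(nrow(df))
  a_perm <- cluster_localizations(locs_from_df(df[perm, ]), radius = 12, min_locs = 5)
  m1 <- molecules_from_clusters(locs, a)
  m2 <- molecules_from_clusters(locs_from_df(df[perm, ]), a_perm)
  expect_equal(nrow(m1), nrow(m2))
  o1 <- order(m1$xc, m1$yc); o2 <- order(m2$xc, m2$yc)
  expect_equal(m1$xc[o1], m2$xc[o2])
  expect_equal(m1$yc[o1], m2$yc[o2])
})

test_that("frame-spread filter removes temporally bursty clusters", {
  set.seed(9)
  steady <- make_cloud(0, 0, 30, 4)                      # frames across acquisition
  burst <- make_cloud(500, 500, 30, 4, frame_range = c(100L, 140L))
  locs <- locs_from_df(rbind(steady, burst))
  a_off <- cluster_localizations(locs, radius = 20, min_locs = 10)
  expect_equal(length(unique(a_off[a_off >= 0])), 2)
  a_on <- cluster_localizations(locs, radius = 20, min_locs = 10,
                                frame_spread_check = TRUE)
  expect_equal(length(unique(a_on[a_on >= 0])), 1)
  kept <- which(a_on >= 0)
  expect_true(all(kept <= 30))  # the steady cluster survives
})

test_that("molecules_from_clusters masks by ROI and renumbers densely", {
  set.seed(10)
  df <- rbind(make_cloud(100, 100, 20, 4), make_cloud(2000, 2000, 20, 4))
  locs <- locs_from_df(df)
  a <- cluster_localizations(locs, radius = 20, min_locs = 10)
  roi <- roi_rect(0, 0, 500, 500)
  mols <- molecules_from_clusters(locs, a, roi = roi)
  expect_equal(nrow(mols), 1)
  expect_equal(mols$molecule_id, 0L)
  expect_true(all(roi_contains(roi, mols$xc, mols$yc)))
  both <- molecules_from_clusters(locs, a, roi = roi_rect(0, 0, 3000, 3000))
  expect_equal(nrow(both), 2)
  expect_equal(both$molecule_id, c(0L, 1L))
  # count equals the number of unique non-noise ids inside the roi
  expect_equal(nrow(both), length(unique(a[a >= 0])))
})

test_that("binder density is count over ROI area", {
  set.seed(12)
  roi <- roi_rect(0, 0, 10000, 10000)   # 100 um^2
  mols <- molecule_set(xc = runif(100, 0, 10000), yc = runif(100, 0, 10000),
                       n_locs = rep(10L, 100), center_uncertainty = rep(1, 100),
                       roi = roi)
  expect_equal(binder_density(mols), 1.0)
  expect_equal(binder_density(molecule_set(roi = roi)), 0.0)
  # arithmetic oracle on a random fixture
  roi2 <- roi_rect(0, 0, 7000, 3000)
  n <- rpois(1, 57)
  m2 <- molecule_set(xc = runif(n, 0, 7000), yc = runif(n, 0, 3000),
                     n_locs = rep(1L, n), center_uncertainty = rep(1, n), roi = roi2)
  expect_equal(binder_density(m2), n / 21)
})

test_that("molecule sets round-trip through CSV", {
  set.seed(13)
  roi <- roi_rect(0, 0, 5000, 5000)
  mols <- molecule_set(xc = runif(20, 0, 5000), yc = runif(20, 0, 5000),
                       n_locs = rpois(20, 20), center_uncertainty = runif(20, 0.5, 2),
                       roi = roi)
  f <- withr::local_tempfile(fileext = ".csv")
  write_molecules(mols, f)
  back <- read_molecules(f, roi = roi)
  expect_equal(back$xc, mols$xc)
  expect_equal(back$n_locs, mols$n_locs)
  expect_error(read_molecules(f, roi = NULL), NA)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_molecules(bad), "missing required column")
})

test_that("the packaged synthetic example CSV loads and clusters", {
  f <- system.file("extdata", "synthetic_locs_px.csv", package = "paintquant")
  locs <- read_localizations(f, pixel_size_nm = 130)
  expect_gt(nrow(locs), 50)
  expect_true(all(locs$lpx > 1 & locs$lpx < 20))  # nm scale after conversion
  a <- cluster_localizations(locs, radius = 15, min_locs = 3)
  expect_gt(length(unique(a[a >= 0])), 5)
})
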