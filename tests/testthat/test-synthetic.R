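test_that("planted bands are contiguous, balanced and reproducible", {
  spec <- synthetic_spec(grid = c(30L, 30L), n_domains = 4L)
  pd <- plant_domains(spec)
  expect_equal(nrow(pd$coords), 900)
  expect_equal(sort(unique(pd$labels)), 0:3)
  expect_true(all(table(pd$labels) > 0))
  # bands: the label depends only on the row (y coordinate)
  rows <- floor(pd$coords[, 2] / spec$image_px_per_spot)
  expect_true(all(tapply(pd$labels, rows, function(x) length(unique(x))) == 1))
  # about 225 spots per band
  expect_true(all(abs(table(pd$labels) - 225) <= 60))
  expect_identical(plant_domains(spec)$labels, pd$labels)
  expect_equal(plant_domains(synthetic_spec(n_domains = 1L))$labels, rep(0L, 900))
  expect_error(plant_domains(synthetic_spec(grid = c(4L, 50L), n_domains = 5L)),
               "exceeds")
  # rings geometry produces concentric labels
  pr <- plant_domains(synthetic_spec(geometry = "rings"))
  ctr <- colMeans(pr$coords)
  d0 <- sqrt(rowSums((pr$coords[pr$labels == 0, ] -
                        matrix(ctr, sum(pr$labels == 0), 2, byrow = TRUE))^2))
  d3 <- sqrt(rowSums((pr$coords[pr$labels == 3, ] -
                        matrix(ctr, sum(pr$labels == 3), 2, byrow = TRUE))^2))
  expect_lt(max(d0), min(d3) + 1e-9)
})

test_that("simulated counts carry the planted fold change and dispersion", {
  spec <- synthetic_spec(grid = c(30L, 30L), n_domains = 2L, n_genes = 200L,
                         log_fc = 1.5, seed = 100L)
  pd <- plant_domains(spec)
  counts <- simulate_counts(pd$labels, spec)
  de <- attr(counts, "de_sets")
  mu <- attr(counts, "mean_matrix")
  # a DE gene unique to domain 1: sample mean ratio close to exp(log_fc)
  only1 <- setdiff(de[[2]], de[[1]])
  g <- only1[1]
  m_in <- mean(counts[pd$labels == 1, g])
  m_out <- mean(counts[pd$labels == 0, g])
  se <- sqrt(stats::var(counts[pd$labels == 1, g]) / sum(pd$labels == 1))
  expect_lt(abs(m_in - exp(spec$log_fc) * mu[1, g]), 3 * se + 3 * sqrt(stats::var(counts[pd$labels == 0, g]) / sum(pd$labels == 0)) * exp(spec$log_fc))
  expect_gt(m_in / m_out, exp(1.5) * 0.7)
  expect_lt(m_in / m_out, exp(1.5) / 0.7)
  # library sizes concentrate around the requested depth
  expect_lt(abs(mean(rowSums(counts)) - spec$depth) / spec$depth, 0.25)
  # determinism
  expect_identical(simulate_counts(pd$labels, spec), counts)
  # null model: no fold change -> domain means identical
  spec0 <- synthetic_spec(n_domains = 2L, log_fc = 0)
  c0 <- simulate_counts(plant_domains(spec0)$labels, spec0)
  mu0 <- attr(c0, "mean_matrix")
  expect_equal(mu0[1, ], mu0[2, ])
})

test_that("the NB dispersion parameter controls the variance-mean ratio", {
  # theta -> infinity approaches Poisson: variance/mean ratio -> 1
  spec_p <- synthetic_spec(grid = c(40L, 10L), n_domains = 1L, n_genes = 150L,
                           nb_dispersion = 1e5, seed = 4L)
  cp <- simulate_counts(plant_domains(spec_p)$labels, spec_p)
  mu <- attr(cp, "mean_matrix")[1, ]
  ratio <- apply(cp, 2, stats::var) / mu
  expect_lt(abs(mean(ratio) - 1), 0.15)
  # strongly overdispersed at theta = 2: var/mean = 1 + mu/theta on average
  spec_o <- synthetic_spec(grid = c(40L, 10L), n_domains = 1L, n_genes = 150L,
                           nb_dispersion = 2, seed = 4L)
  co <- simulate_counts(plant_domains(spec_o)$labels, spec_o)
  muo <- attr(co, "mean_matrix")[1, ]
  expected <- 1 + muo / 2
  observed <- apply(co, 2, stats::var) / muo
  expect_lt(abs(mean(observed / expected) - 1), 0.25)
})

test_that("the rendered image carries domain signal scaled by texture contrast", {
  spec0 <- synthetic_spec(grid = c(10L, 10L), texture_contrast = 0)
  pd <- plant_domains(spec0)
  img0 <- render_histology(pd$labels, pd$coords, spec0)
  expect_equal(max(img0) - min(img0), 0)    # perfectly uniform
  spec1 <- synthetic_spec(grid = c(10L, 10L), texture_contrast = 1)
  img1 <- render_histology(pd$labels, pd$coords, spec1)
  expect_identical(render_histology(pd$labels, pd$coords, spec1), img1)
  # within-domain patch features correlate more than between-domain
  ps <- standardize_patches(extract_patches(img1, pd$coords, crop = 10L, out_size = 16L))
  raw <- embed_patches(ps, stub_extractor(bins = 8L, pool = 4L))
  S <- suppressWarnings(pearson_similarity(raw))
  same <- outer(pd$labels, pd$labels, `==`)
  diag(same) <- NA
  expect_gt(mean(S[which(same)]), mean(S[which(!same)]))
})

test_that("make_dataset composes a loadable, round-trippable fixture", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "SpatialDataset")
  expect_equal(dim(ds$counts), c(100, 60))
  expect_equal(dim(ds$image), c(60, 60, 3))
  expect_equal(length(ds$meta$domain), 100)
  ds2 <- tiny_dataset(seed = 101L)
  expect_false(identical(ds$counts, ds2$counts))
  expect_identical(dim(ds2$counts), dim(ds$counts))
  # round trip through the MTX loader is lossless
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  back <- load_dataset(dir, image_path = file.path(dir, "image.png"))
  expect_identical(unname(back$counts), unname(ds$counts))
  expect_equal(back$coords, ds$coords)
  expect_identical(back$meta$domain, ds$meta$domain)
  expect_equal(dim(back$image), dim(ds$image))
})
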