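# Synthetic-data generators: determinism, noise calibration, genome
# tiling, contact-map structure.

test_that("noiseless profiles equal the model curve with zero SEM", {
  s <- seq(5, 100, 5)
  pr <- simulate_3c_profile(s, K = 1.07e3, L = 9.70, S = 2.7, D = 255,
                            P = 201)
  expect_equal(pr$frequency,
               model_curve(s, K = 1.07e3, L = 9.70, S = 2.7,
                           D = 255, P = 201))
  expect_true(all(pr$sem == 0))
})

test_that("profile simulation is seed-deterministic and seed-sensitive", {
  s <- seq(5, 100, 5)
  a <- simulate_3c_profile(s, K = 1, L = 10, S = 3,
                           noise = noise_spec(0.2), seed = 4)
  b <- simulate_3c_profile(s, K = 1, L = 10, S = 3,
                           noise = noise_spec(0.2), seed = 4)
  c <- simulate_3c_profile(s, K = 1, L = 10, S = 3,
                           noise = noise_spec(0.2), seed = 5)
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$sem, b$sem)
  expect_false(identical(a$frequency, c$frequency))
})

test_that("seeded generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_3c_profile(c(5, 10), K = 1, L = 10, S = 3,
                                noise = noise_spec(0.1), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("log-normal noise has the documented first moment", {
  # mean of X*exp(eps) is X*exp(sigma^2/2) for eps ~ N(0, sigma^2)
  sigma <- 0.1
  pr <- simulate_3c_profile(
    rep(20, 1), K = 1, L = 10, S = 3,
    noise = noise_spec(sigma, n_assays = 2500, n_tech = 4), seed = 8
  )
  mu <- model_curve(20, K = 1, L = 10, S = 3)
  expect_equal(pr$frequency, mu * exp(sigma^2 / 2), tolerance = 0.01)
})

test_that("empirical noise scale matches sigma_log", {
  s <- rep(30, 1)
  draws <- replicate(3000, simulate_3c_profile(
    s, K = 1, L = 10, S = 3, noise = noise_spec(0.2, 1, 1)
  )$frequency)
  expect_equal(stats::sd(log(draws)), 0.2, tolerance = 0.05)
})

test_that("simulated genomes tile chromosomes with class-labelled TADs", {
  sp <- genome_spec(chromosome_length_bp = 2e6, tad_median_kb = 70)
  g1 <- simulate_genome(sp, seed = 10)
  g2 <- simulate_genome(sp, seed = 10)
  expect_identical(as.data.frame(g1$tads), as.data.frame(g2$tads))
  # gap-free tiling of whole bins, min 2 bins each
  st <- GenomicRanges::start(g1$tads)
  en <- GenomicRanges::end(g1$tads)
  expect_equal(st[1], 1)
  expect_equal(en[length(en)], 2e6)
  expect_true(all(st[-1] == en[-length(en)] + 1))
  expect_true(all(GenomicRanges::width(g1$tads) %% 5000 == 0))
  expect_true(all(GenomicRanges::width(g1$tads) >= 10000))
  expect_true(all(S4Vectors::mcols(g1$domains)$name %in%
                    paste0("D", 1:4)))
})

test_that("TAD sizes follow the requested log-normal median", {
  sp <- genome_spec(chromosome_length_bp = 50e6, tad_median_kb = 70,
                    tad_sdlog = 0.5)
  g <- simulate_genome(sp, seed = 11)
  sizes_kb <- GenomicRanges::width(g$tads) / 1000
  expect_gt(length(sizes_kb), 500)
  expect_equal(stats::median(sizes_kb), 70, tolerance = 0.05)
})

test_that("degenerate class proportions label every TAD identically", {
  sp <- genome_spec(chromosome_length_bp = 1e6,
                    class_proportions = c(D1 = 1, D2 = 0, D3 = 0, D4 = 0))
  g <- simulate_genome(sp, seed = 3)
  expect_true(all(S4Vectors::mcols(g$domains)$name == "D1"))
})

test_that("contact maps respect structure, attenuation and determinism", {
  sp <- genome_spec(chromosome_length_bp = 1e6, tad_median_kb = 100,
                    tad_sdlog = 0.2,
                    class_proportions = c(D2 = 1),
                    class_params = list(D2 = c(K = 1.5e-9, L = 10.6,
                                               S = 4.9)))
  g <- simulate_genome(sp, seed = 6)
  m0 <- simulate_contact_map(g, sigma_log = 0, attenuation = 1, seed = 6)
  # attenuation 1, single class: value depends only on separation
  for (db in c(1, 5, 20)) {
    i <- seq_len(m0$n_bins - db)
    vals <- map_value(m0, i - 1, i - 1 + db)
    expect_equal(max(vals) - min(vals), 0)
    expect_equal(vals[1],
                 model_curve(db * 5, K = 1.5e-9, L = 10.6, S = 4.9))
  }
  # attenuation 0: all across-border values are zero
  mz <- simulate_contact_map(g, sigma_log = 0, attenuation = 0, seed = 6)
  truth <- attr(mz, "truth")
  idx <- which(truth$bin_tad[-1] != truth$bin_tad[-length(truth$bin_tad)])[1]
  expect_equal(map_value(mz, idx - 1, idx), 0)
  # determinism
  m1 <- simulate_contact_map(g, sigma_log = 0.1, seed = 9)
  m2 <- simulate_contact_map(g, sigma_log = 0.1, seed = 9)
  expect_identical(m1$mat, m2$mat)
  # stored triangle is upper, finite, non-negative
  expect_true(all(m1$mat@x >= 0))
  expect_true(all(is.finite(m1$mat@x)))
  tm <- methods::as(m1$mat, "TsparseMatrix")
  expect_true(all(tm@j >= tm@i))
})

test_that("poisson count mode produces depth-scaled counts", {
  sp <- genome_spec(chromosome_length_bp = 5e5, tad_median_kb = 100,
                    class_proportions = c(D2 = 1),
                    class_params = list(D2 = c(K = 1, L = 10.6, S = 4.9)))
  g <- simulate_genome(sp, seed = 2)
  m <- simulate_contact_map(g, mode = "poisson", depth = 1e4, seed = 2)
  expect_true(all(m$mat@x * 1e4 == round(m$mat@x * 1e4)))
})

test_that("simulation manifests serialize truth parameters", {
  pr <- simulate_3c_profile(c(5, 10), K = 2, L = 10, S = 3,
                            noise = noise_spec(0.1), seed = 12)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_simulation_manifest(pr, f)
  manifest <- jsonlite::read_json(f)
  expect_equal(manifest$K, 2)
  expect_equal(manifest$seed, 12)
  expect_equal(manifest$noise$sigma_log, 0.1)
})
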