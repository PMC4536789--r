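# Virtual-3C extraction from binned maps, TAD filtering, epigenetic
# classification, batch fitting and per-domain summaries.

make_uniform_map <- function(n_bins, value = 2, bin_kb = 5) {
  idx <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  contact_map(
    data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L, value = value),
    chrom = "chrU", bin_size_kb = bin_kb, n_bins = n_bins
  )
}

test_that("profile count follows the bin-arithmetic formula", {
  m <- make_uniform_map(200)
  vp <- build_virtual_profiles(m, anchor_width_kb = 25, span_kb = 400)
  expect_equal(length(unique(vp$anchor_bin)), 121) # 200 - 80 + 1
  expect_equal(sort(unique(vp$anchor_bin)), 0:120)
  # exactly one full window fits on an 80-bin chromosome
  m80 <- make_uniform_map(80)
  vp80 <- build_virtual_profiles(m80)
  expect_equal(unique(vp80$anchor_bin), 0)
  # and none on a shorter one
  vp79 <- build_virtual_profiles(make_uniform_map(79))
  expect_equal(nrow(vp79), 0)
})

test_that("profiles from a uniform map are flat at the uniform value", {
  vp <- build_virtual_profiles(make_uniform_map(100, value = 3.5))
  expect_true(all(vp$frequency == 3.5))
  # separations are positive bin multiples, bounded by span - anchor
  expect_equal(sort(unique(vp$separation_kb)), seq(5, 375, 5))
})

test_that("profile values are constant-separation means of bin pairs", {
  n <- 90
  set.seed(14)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vals <- stats::runif(nrow(idx))
  m <- contact_map(data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                              value = vals), chrom = "c", n_bins = n)
  vp <- build_virtual_profiles(m)
  for (a in c(0, 4, 10)) {
    for (d in c(5, 40, 200)) {
      got <- vp$frequency[vp$anchor_bin == a & vp$separation_kb == d]
      manual <- mean(map_value(m, a + 0:4, a + 0:4 + d / 5))
      expect_equal(got, manual)
    }
  }
})

test_that("bin/bp coordinate conversions round-trip", {
  m <- make_uniform_map(100)
  vp <- build_virtual_profiles(m)
  bs_bp <- attr(vp, "bin_size_kb") * 1000
  anchors <- unique(vp$anchor_bin)
  expect_equal((anchors * bs_bp) / bs_bp, anchors)
})

test_that("TAD filtering keeps only anchors with enough in-TAD span", {
  m <- make_uniform_map(200)
  vp <- build_virtual_profiles(m)
  # one 300-kb TAD at 0-300 kb, next at 300-600, then 600-1000
  tads <- GenomicRanges::GRanges(
    "chrU", IRanges::IRanges(start = c(1, 300001, 600001),
                             end = c(300000, 600000, 1000000))
  )
  S4Vectors::mcols(tads)$name <- c("T1", "T2", "T3")
  kept <- filter_within_tad(vp, tads, min_span_kb = 65)
  keep_anchors <- unique(kept$anchor_bin)
  # anchor needs [a, a+90kb) within one TAD: a <= 210kb -> bins 0..42,
  # 300..510 -> bins 60..102, 600..910 capped by span: bins 120
  brute <- Filter(function(a) {
    lo <- a * 5000
    hi <- lo + (25 + 65) * 1000
    any(lo >= c(0, 300000, 600000) & hi <= c(300000, 600000, 1000000))
  }, unique(vp$anchor_bin))
  expect_equal(keep_anchors, unlist(brute))
  # a window ending 10 kb before a border is excluded
  expect_false(43 %in% keep_anchors) # [215, 305) kb crosses 300-kb border
  expect_true(42 %in% keep_anchors)
})

test_that("epigenetic classification uses majority overlap with tie-drop", {
  m <- make_uniform_map(100)
  vp <- build_virtual_profiles(m)
  doms <- GenomicRanges::GRanges(
    "chrU",
    IRanges::IRanges(start = c(1, 15001, 62501), end = c(15000, 62500, 5e5))
  )
  S4Vectors::mcols(doms)$name <- c("D1", "D2", "D3")
  cl <- classify_profiles(vp, doms)
  lab <- function(a) unique(cl$domain[cl$anchor_bin == a])
  expect_equal(lab(0), "D1")  # [0, 25) kb: 15 kb D1 + 10 kb D2 -> D1
  expect_equal(lab(4), "D2")  # [20, 45) kb lies wholly in D2
  expect_true(is.na(lab(10))) # [50, 75) kb: 12.5 kb D2 + 12.5 kb D3 tie
  expect_equal(lab(20), "D3") # fully inside D3
})

test_that("batch fits recover truth from noiseless model profiles", {
  pipe <- two_class_pipeline(chrom_len = 1.5e6, sigma_log = 0)
  vp <- build_virtual_profiles(pipe$map)
  vf <- filter_within_tad(vp, pipe$genome$tads, min_span_kb = 70)
  vc <- classify_profiles(vf, pipe$genome$domains)
  fits <- fit_virtual_profiles(vc)
  expect_true(all(fits$converged))
  truth <- pipe$spec$class_params
  for (d in c("D1", "D4")) {
    sub <- fits[fits$domain == d & !is.na(fits$domain), ]
    expect_gt(nrow(sub), 0)
    expect_equal(stats::median(sub$S), truth[[d]][["S"]], tolerance = 1e-2)
    amp_hat <- stats::median(sub$K * (sub$L * sub$S)^-3)
    amp_true <- truth[[d]][["K"]] *
      (truth[[d]][["L"]] * truth[[d]][["S"]])^-3
    expect_equal(amp_hat, amp_true, tolerance = 1e-2)
  }
})

test_that("degenerate profiles are flagged, not fitted", {
  m <- make_uniform_map(85, value = 1) # flat: zero variance within fit span
  vp <- build_virtual_profiles(m)
  fits <- fit_virtual_profiles(vp)
  expect_true(all(!fits$converged))
  expect_true(all(is.na(fits$K)))
})

test_that("quality filtering applies the open (0,1) R-squared rule", {
  tbl <- structure(
    data.frame(
      anchor_bin = 0:3, domain = "D1",
      K = 1, L = 10, S = 5, se_K = NA, se_L = NA, se_S = NA,
      r_squared = c(0.6, 0.4, -0.2, 1.0), ssr = 1, n_obs = 14,
      converged = TRUE
    ),
    chrom = "c", fit_span_kb = 70, anchor_width_kb = 25,
    class = c("virtual_fit_table", "data.frame")
  )
  out <- filter_fit_quality(tbl)
  expect_equal(out$retained$r_squared, c(0.6, 0.4))
  expect_equal(out$fraction_r2_above_half, 0.5)
  all_good <- tbl
  all_good$r_squared <- rep(0.9, 4)
  expect_equal(filter_fit_quality(all_good)$fraction_r2_above_half, 1)
  none <- tbl
  none$converged <- FALSE
  expect_warning(out0 <- filter_fit_quality(none), "undefined")
  expect_true(is.na(out0$fraction_r2_above_half))
})

test_that("domain summaries report medians and pairwise rank tests", {
  tbl <- structure(
    data.frame(
      anchor_bin = 0:399,
      domain = rep(c("D1", "D4"), each = 200),
      K = 1, L = 10,
      S = c(stats::rnorm(200, 4.15, 0.2), stats::rnorm(200, 5.30, 0.2)),
      se_K = NA, se_L = NA, se_S = NA,
      r_squared = 0.8, ssr = 1, n_obs = 14, converged = TRUE
    ),
    chrom = "c", fit_span_kb = 70, anchor_width_kb = 25,
    class = c("virtual_fit_table", "data.frame")
  )
  set.seed(20)
  tbl$S <- c(stats::rnorm(200, 4.15, 0.2), stats::rnorm(200, 5.30, 0.2))
  sm <- domain_parameter_summary(tbl)
  expect_equal(sm$medians$domain, c("D1", "D4"))
  expect_equal(sm$medians$median_S, c(4.15, 5.30), tolerance = 0.05)
  s_test <- sm$tests[sm$tests$parameter == "S", ]
  expect_lt(s_test$p_value, 1e-3)
  # single record per domain: median reported, test skipped
  tiny <- tbl[c(1, 201), ]
  class(tiny) <- class(tbl)
  attr(tiny, "chrom") <- "c"
  sm2 <- domain_parameter_summary(tiny)
  expect_equal(sm2$medians$n, c(1, 1))
  expect_true(all(is.na(sm2$tests$p_value)))
})
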