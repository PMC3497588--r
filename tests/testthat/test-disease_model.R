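test_that("the tri-modal curve evaluates exactly as written", {
  p <- trimodal_params(c(0, 1, 0), c(-0.5, 0, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(trimodal_density(0, p), 1.0)
  p2 <- trimodal_params(c(1, 1, 1), c(-0.5, 0, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(trimodal_density(0, p2), 1.0 + 2 * exp(-25), tolerance = 1e-8)
  # unit offset from a single peak
  p3 <- trimodal_params(c(1, 0, 0), c(-0.5, 0, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(trimodal_density(-0.5 + 0.1, p3), exp(-1), tolerance = 1e-12)
  # non-negative everywhere, vanishing in the tails
  xs <- seq(-1, 1, length.out = 201)
  expect_true(all(trimodal_density(xs, p2) >= 0))
  expect_lt(trimodal_density(50, p2), 1e-12)
  # components are relabeled so mu ascends
  p4 <- trimodal_params(c(3, 2, 1), c(0.5, -0.5, 0), c(0.3, 0.1, 0.2))
  expect_equal(p4$mu, c(-0.5, 0, 0.5))
  expect_equal(p4$alpha, c(2, 1, 3))
  expect_error(trimodal_params(c(-1, 1, 1), c(0, 0, 0), c(1, 1, 1)), class = "hgf_invalid_input")
})

test_that("score histograms span [-1, 1] with exact counts", {
  h <- score_histogram(c(-0.5, 0.5), n_bins = 2)
  expect_equal(h$heights, c(1L, 1L))
  expect_equal(h$edges, c(-1, 0, 1))
  withr::with_seed(8, scores <- runif(96, -1, 1))
  h2 <- score_histogram(scores, n_bins = 20)
  expect_equal(sum(h2$heights), 96L)
  # naive binning loop oracle (left-closed bins, last bin closed at +1)
  oracle <- vapply(seq_len(20), function(b) {
    lo <- h2$edges[b]
    hi <- h2$edges[b + 1]
    sum(if (b == 20) scores >= lo & scores <= hi else scores >= lo & scores < hi)
  }, numeric(1))
  expect_equal(h2$heights, as.integer(oracle))
  expect_equal(score_histogram(1, n_bins = 4)$heights, c(0L, 0L, 0L, 1L))
  expect_error(score_histogram(1.2, 10), class = "hgf_invalid_input")
  expect_error(score_histogram(0.5, 1), class = "hgf_invalid_input")
})

test_that("R-square follows its definition and invariances", {
  expect_equal(r_square(c(1, 2, 3), c(1, 2, 3)), 1.0)
  obs <- c(4, 1, 7, 2)
  expect_equal(r_square(obs, rep(mean(obs), 4)), 0.0)
  expect_equal(r_square(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(r_square(obs + 10, c(3, 2, 6, 1) + 10), r_square(obs, c(3, 2, 6, 1)))
  expect_lte(r_square(obs, c(100, -50, 3, 7)), 1)
  expect_error(r_square(c(2, 2, 2), c(1, 2, 3)), class = "hgf_undefined")
  expect_error(r_square(1, 1), class = "hgf_invalid_input")
})

test_that("noiseless tri-modal curves are recovered to 1e-4", {
  truth <- trimodal_params(c(6, 12, 5), c(-0.45, 0.05, 0.5), c(0.12, 0.15, 0.1))
  edges <- seq(-1, 1, length.out = 31)
  centers <- (edges[-1] + edges[-31]) / 2
  h <- list(edges = edges, centers = centers, heights = trimodal_density(centers, truth))
  fit <- fit_trimodal(h, seed = 2)
  expect_gte(fit$r_square, 0.9999)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-4)
  expect_equal(fit$params$mu, truth$mu, tolerance = 1e-4)
  expect_equal(fit$params$sigma, truth$sigma, tolerance = 1e-4)
})

test_that("degenerate and undersized histograms are rejected", {
  edges <- seq(-1, 1, length.out = 21)
  centers <- (edges[-1] + edges[-21]) / 2
  expect_error(
    fit_trimodal(list(edges = edges, centers = centers, heights = rep(0, 20))),
    class = "hgf_degenerate"
  )
  expect_error(
    fit_trimodal(list(centers = centers[1:5], heights = rep(1:5))),
    class = "hgf_invalid_input"
  )
})

test_that("sampled scores let the fit recover the planted peak centers", {
  truth <- well_separated_params()
  s <- sample_trimodal(truth, 500, seed = 31)
  fit <- fit_trimodal(score_histogram(s, 20), seed = 31)
  expect_true(all(abs(fit$params$mu - truth$mu) < 0.05))
})

test_that("thresholds sit at component intersections", {
  # equal amplitude and width: exact midpoint between peaks 2 and 3
  p <- trimodal_params(c(2, 1, 1), c(-0.5, 0.0, 0.6), c(0.15, 0.1, 0.1))
  thr <- derive_thresholds(p)
  expect_equal(thr$cutoffs[[2]], 0.3, tolerance = 1e-10)
  expect_identical(thr$source, "fitted")
  # asymmetric case against a fine grid-intersection oracle
  p2 <- trimodal_params(c(1, 1, 1), c(-0.4, 0, 0.4), c(0.1, 0.2, 0.1))
  thr2 <- derive_thresholds(p2)
  grid_cut <- function(i, j) {
    xs <- seq(p2$mu[i] + 1e-5, p2$mu[j] - 1e-5, by = 1e-5)
    gi <- p2$alpha[i] * exp(-((xs - p2$mu[i]) / p2$sigma[i])^2)
    gj <- p2$alpha[j] * exp(-((xs - p2$mu[j]) / p2$sigma[j])^2)
    xs[which.min(abs(gi - gj))]
  }
  expect_equal(thr2$cutoffs[[1]], grid_cut(1, 2), tolerance = 1e-4)
  expect_equal(thr2$cutoffs[[2]], grid_cut(2, 3), tolerance = 1e-4)
  expect_true(all(thr2$cutoffs > p2$mu[1:2] & thr2$cutoffs < p2$mu[2:3]))
  # vanished middle amplitude: no crossing, fallback recommended
  p3 <- trimodal_params(c(1, 0, 1), c(-0.4, 0, 0.4), c(0.1, 0.1, 0.1))
  expect_error(derive_thresholds(p3), class = "hgf_threshold_fallback")
})

test_that("manual thresholds validate their cutoffs", {
  thr <- manual_thresholds(c(0.1, 0.3))
  expect_identical(thr$source, "manual")
  expect_length(manual_thresholds(c(0.05, 0.1, 0.2))$cutoffs, 3L)
  expect_error(manual_thresholds(c(0.3, 0.1)), class = "hgf_invalid_input")
  expect_error(manual_thresholds(c(0.1, 1.0)), class = "hgf_invalid_input")
  expect_error(manual_thresholds(0.5), class = "hgf_invalid_input")
})

test_that("categorization reproduces the worked ischemic-stroke and parkinson bands", {
  is_scores <- c(
    "morning cortisol level" = 0.48, "calcium/minerals" = 0.13,
    "mood" = 0.18, "stress" = 0.12, "vitamin E" = 0.12, "head trauma" = 0.02
  )
  bands <- categorize(is_scores, manual_thresholds(c(0.1, 0.3)))
  expect_identical(bands$established, "morning cortisol level")
  expect_true(all(c("calcium/minerals", "mood", "stress", "vitamin E") %in% bands$potential))
  expect_identical(bands$unknown, "head trauma")

  pd_scores <- c("immunological disorders" = 0.29, "hyperthyroidism" = 0.10, "noise" = 0.01)
  pd <- categorize(pd_scores, manual_thresholds(c(0.05, 0.1, 0.2)))
  expect_identical(pd$established, "immunological disorders")
  # left-closed bands: a score exactly at a cutoff joins the band above it
  expect_identical(pd$potential, "hyperthyroidism")
  expect_identical(pd$unknown, "noise")
  expect_identical(sort(unlist(pd[c("established", "potential", "low", "unknown")], use.names = FALSE)), sort(names(pd_scores)))
})

test_that("categorization always partitions the factor set", {
  eps <- 1e-9
  wide <- manual_thresholds(c(-1 + eps, 1 - eps))
  scores <- c(a = -1, b = -0.2, c = 0.5, d = 1)
  bands <- categorize(scores, wide)
  expect_identical(bands$unknown, "a")
  expect_identical(bands$established, "d")
  expect_setequal(bands$potential, c("b", "c"))
})
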