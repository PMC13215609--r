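# Network construction, entropy computation, and trace behavior.

small_config <- function(...) {
  network_config(n_layers = 4L, channels_per_layer = rep(8L, 4L),
                 input_size = c(16L, 16L, 1L), n_classes = 10L, ...)
}

test_that("network_config validates its invariants", {
  expect_s3_class(network_config(), "network_config")
  expect_error(network_config(n_layers = 0), "n_layers")
  expect_error(network_config(n_timesteps = 1), "n_timesteps")
  expect_error(network_config(n_classes = 1), "n_classes")
  expect_error(network_config(kernel_size = 4), "odd")
  expect_error(network_config(channels_per_layer = c(8, 8)), "channels")
  expect_error(network_config(input_size = c(32, 32)), "input_size")
  expect_error(network_config(weight_init_scale = 0), "weight_init_scale")
})

test_that("weights are reproducible from the seed and differ across seeds", {
  n1 <- build_network(small_config(seed = 1L))
  n2 <- build_network(small_config(seed = 1L))
  n3 <- build_network(small_config(seed = 2L))
  expect_identical(serialize(n1$layers, NULL), serialize(n2$layers, NULL))
  expect_identical(n1$readout, n2$readout)
  expect_false(identical(serialize(n1$layers, NULL),
                         serialize(n3$layers, NULL)))
  # default geometry: 8 conv layers
  expect_length(build_network(network_config(seed = 1L))$layers, 8L)
})

test_that("shannon_entropy matches closed forms and rejects bad input", {
  expect_identical(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  # direct-summation oracle on a random distribution
  set.seed(3)
  p <- runif(10); p <- p / sum(p)
  direct <- 0
  for (i in seq_along(p)) direct <- direct - p[i] * log(p[i])
  expect_equal(shannon_entropy(p), direct, tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sums to")
})

test_that("run_image produces a full-length trace and validates channels", {
  net <- build_network(small_config(seed = 5L))
  img <- matrix(runif(16 * 16), 16, 16)
  tr <- run_image(net, img, "x")
  expect_s3_class(tr, "entropy_trace")
  expect_length(as.numeric(tr), 8L)
  expect_error(run_image(net, array(0.5, c(16, 16, 3))), "channels")
})

test_that("zeroed readout forces uniform softmax at every timestep", {
  net <- build_network(small_config(seed = 5L))
  net$readout$W[] <- 0
  tr <- run_image(net, matrix(0.7, 16, 16))
  expect_equal(as.numeric(tr), rep(log(10), 8L), tolerance = 1e-12)
})

test_that("hand-set logits via the readout bias reproduce direct entropies", {
  cfg <- network_config(n_layers = 2L, channels_per_layer = c(4L, 4L),
                        input_size = c(8L, 8L, 1L), n_classes = 4L,
                        seed = 9L)
  net <- build_network(cfg)
  net$readout$W[] <- 0                  # stub: logits = bias only
  logits <- c(2, 1, 0, -1)
  net$readout$b <- logits
  p <- exp(logits) / sum(exp(logits))
  expect_equal(as.numeric(run_image(net, matrix(0.5, 8, 8))),
               rep(-sum(p * log(p)), 8L), tolerance = 1e-9)
})

test_that("state resets between images: repeated scoring is identical", {
  net <- build_network(small_config(seed = 11L))
  img <- matrix(runif(256), 16, 16)
  expect_identical(as.numeric(run_image(net, img)),
                   as.numeric(run_image(net, img)))
})

test_that("entropy bounds hold and entropy declines on average (100 images)", {
  net <- build_network(network_config(seed = 21L))
  imgs <- make_fixture_images(100, seed = 22L)
  traces <- vapply(imgs, function(im) as.numeric(run_image(net, im)),
                   numeric(8L))
  expect_true(all(traces >= 0))
  expect_true(all(traces <= log(100) + 1e-9))
  expect_gt(mean(traces[1L, ]), mean(traces[8L, ]))
})

test_that("score_image_set matches one-at-a-time scoring and survives errors", {
  net <- build_network(small_config(seed = 31L))
  imgs <- make_fixture_images(3, size = c(16L, 16L), channels = 1L,
                              seed = 32L)
  tab <- score_image_set(net, imgs)
  expect_equal(nrow(tab), 3L)
  # loop oracle
  for (i in seq_len(3L)) {
    tr <- run_image(net, imgs[[i]], names(imgs)[i])
    fit <- fit_power_curve(tr)
    expect_equal(tab$A[i], fit$A, tolerance = 1e-12)
    expect_equal(unlist(tab[i, paste0("entropy_t", 1:8)], use.names = FALSE),
                 as.numeric(tr), tolerance = 1e-12)
  }
  # identical image twice gives identical rows
  tab2 <- score_image_set(net, list(a = imgs[[1L]], b = imgs[[1L]]))
  expect_equal(tab2$A[1L], tab2$A[2L])
  # unreadable file yields an NA row plus warning; run continues
  expect_warning(
    tab3 <- score_image_set(net, c(no = tempfile(fileext = ".png"))),
    "failed")
  expect_true(is.na(tab3$A[1L]))
})

test_that("netpbm images round-trip through write_pnm/read_pnm", {
  img <- make_fixture_images(1, size = c(12L, 10L), channels = 3L,
                             seed = 1L)[[1L]]
  path <- tempfile(fileext = ".ppm")
  write_pnm(img, path)
  back <- read_pnm(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)   # quantization only
  grey <- matrix(seq(0, 1, length.out = 20), 4, 5)
  pg <- tempfile(fileext = ".pgm")
  write_pnm(grey, pg)
  expect_equal(dim(read_pnm(pg)), c(4L, 5L, 1L))
  expect_error(read_image(tempfile(fileext = ".bmp")), "no such file")
})
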