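test_that("a straight ridge is traced to sub-pixel accuracy", {
  img <- draw_ridge(512, function(x) rep(300, length(x)))
  trs <- trace_filaments(image2d(img, 4), template_width = 70,
                         polarity = "bright")
  expect_length(trs, 1)
  expect_lt(max(abs(trs[[1]]$polyline[, 2] - 300)), 1)
})

test_that("a sine-curved ridge's arc length is recovered within 2%", {
  amp <- 40; per <- 400
  img <- draw_ridge(512, function(x) 256 + amp * sin(2 * pi * x / per))
  trs <- trace_filaments(image2d(img, 4), template_width = 70,
                         polarity = "bright")
  expect_length(trs, 1)
  xr <- range(trs[[1]]$polyline[, 1])
  f <- function(x) sqrt(1 + (amp * 2 * pi / per * cos(2 * pi * x / per))^2)
  arc_true <- stats::integrate(f, xr[1], xr[2])$value * 4
  expect_lt(abs(trace_arc_length(trs[[1]], 4) - arc_true) / arc_true, 0.02)
})

test_that("a blank noise micrograph yields no traces", {
  img <- withr::with_seed(4, matrix(rnorm(512^2), 512, 512))
  expect_length(trace_filaments(image2d(img, 4)), 0)
})

test_that("truth passthrough returns the simulated polylines", {
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 256,
                           filaments_per_micrograph = 2, seed = 3)
  ds <- simulate_dataset(mini_lattice(), mini_unit(), cfg,
                         n_micrographs = 1, n_units = 10)
  sim <- ds$micrographs[[1]]
  trs <- trace_filaments(sim$micrograph, truth = sim$truth)
  expect_length(trs, 2)
  expect_true(all(vapply(trs, function(t) nrow(t$polyline) == 10, logical(1))))
})

test_that("segment count follows the arc-length formula", {
  img <- draw_ridge(512, function(x) rep(256, length(x)))
  mic <- image2d(img, 4)
  tr <- trace_filaments(mic, template_width = 70, polarity = "bright")[[1]]
  L <- trace_arc_length(tr, 4)
  for (params in list(c(32, 40), c(48, 64), c(32, 100))) {
    box <- params[1]; step <- params[2]
    segs <- extract_segments(mic, tr, box = box, step = step,
                             filament_radius = 40)
    expect_length(segs, floor((L - box * 4) / step) + 1) # combinatorial oracle
  }
})

test_that("a trace shorter than one box yields no segments", {
  mic <- image2d(matrix(0, 128, 128), 4)
  tr <- structure(list(micrograph_id = "m", filament_id = "f",
                       polyline = rbind(c(60, 64), c(70, 64)),
                       estimated_width = 10), class = "filament_trace")
  expect_length(extract_segments(mic, tr, box = 64), 0)
})

test_that("segment backgrounds are normalized to mean 0 sd 1", {
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 512, snr = 1,
                           filaments_per_micrograph = 3, seed = 6)
  ds <- simulate_dataset(demo_lattice(), demo_asym_unit(), cfg,
                         n_micrographs = 2, n_units = 60)
  count <- 0
  for (m in 1:2) {
    sim <- ds$micrographs[[m]]
    for (tr in trace_filaments(sim$micrograph, truth = sim$truth)) {
      for (sg in extract_segments(sim$micrograph, tr, box = 64)) {
        count <- count + 1
        b <- 64
        x <- (seq_len(b) - 33) * 4
        a <- sg$psi_prior * pi / 180
        perp <- abs(-sin(a) * matrix(x, b, b) + cos(a) * t(matrix(x, b, b)))
        bg <- perp > 115
        expect_lt(abs(mean(sg$image$values[bg])), 0.01)
        expect_lt(abs(stats::sd(sg$image$values[bg]) - 1), 0.02)
      }
    }
  }
  expect_gt(count, 50)
})

test_that("segments are unique per (filament, arc position) and carry priors", {
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 512, snr = Inf,
                           ctf = NULL, filaments_per_micrograph = 2, seed = 7)
  ds <- simulate_dataset(demo_lattice(), demo_asym_unit(), cfg,
                         n_micrographs = 1, n_units = 60)
  sim <- ds$micrographs[[1]]
  segs <- list()
  for (tr in trace_filaments(sim$micrograph, truth = sim$truth))
    segs <- c(segs, extract_segments(sim$micrograph, tr, box = 64))
  keys <- vapply(segs, function(s) paste(s$filament_id, s$arc_position),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(vapply(segs, function(s) is.finite(s$psi_prior), logical(1))))
})
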