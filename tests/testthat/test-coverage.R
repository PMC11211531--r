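# Coverage fractions, inter-area variance, NMAE.

test_that("film coverage is the area ratio", {
  expect_equal(film_coverage(0, 1), 0)
  expect_equal(film_coverage(1, 1), 1)
  expect_equal(film_coverage(0.2, 0.5), 0.4)
  expect_error(film_coverage(2, 1), class = "leafspray_domain_error")
})

test_that("pixel coverage counts stained pixels in a window", {
  px <- matrix(FALSE, 4, 4)
  px[1:2, 1:2] <- TRUE # 4 of 16
  lay <- tibble::tibble(area = "frame", xmin = 0, xmax = 4e-3,
                        ymin = 0, ymax = 4e-3)
  img <- stain_image(px, 1e-3, lay)
  expect_equal(pixel_coverage(img, lay), 0.25)
  expect_equal(pixel_coverage(stain_image(matrix(FALSE, 4, 4), 1e-3, lay),
                              lay), 0)
  expect_error(
    pixel_coverage(img, c(xmin = 0.01, xmax = 0.02, ymin = 0.01, ymax = 0.02)),
    class = "leafspray_domain_error")
})

test_that("coverage variance is the population variance of the triple", {
  expect_equal(coverage_variance(0.3, 0.3, 0.3), 0)
  expect_equal(coverage_variance(0, 1, 1), 2 / 9)
  # the worked simulation coverages: 16%, 72%, 68%
  expect_equal(coverage_variance(0.16, 0.72, 0.68), 0.06506666666666666,
               tolerance = 1e-12)
  set.seed(31)
  for (k in 1:50) {
    e <- runif(3)
    s <- coverage_variance(e[1], e[2], e[3])
    p <- sample(3)
    expect_equal(coverage_variance(e[p[1]], e[p[2]], e[p[3]]), s) # permutation
    expect_gte(s, 0)
    if (s == 0) expect_true(all(e == e[1]))
  }
  expect_equal(coverage_variance(0.4, 0.4, 0.4), 0) # zero iff equal
})

test_that("NMAE normalizes by the simulated value", {
  expect_equal(nmae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmae(c(1, 3), c(2, 2)), 0.5)
  set.seed(17)
  for (k in 1:25) {
    yt <- runif(5); ys <- runif(5, 0.1, 1)
    v <- nmae(yt, ys)
    expect_gte(v, 0)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(nmae(c_scale * yt, c_scale * ys), v) # scale invariance
  }
  expect_error(nmae(c(1, 2), c(1, 0)), class = "leafspray_domain_error")
  expect_error(nmae(c(1, 2), c(1, 2, 3)), class = "leafspray_domain_error")
})

test_that("predictive adequacy thresholds at 30%", {
  expect_true(nmae_adequate(0.15))
  expect_true(nmae_adequate(0.299))
  expect_false(nmae_adequate(0.30))
  expect_false(nmae_adequate(0.5))
})

test_that("coverage report assembles mean, variance and NMAE", {
  rep <- coverage_report(0.16, 0.72, 0.68)
  expect_equal(rep$eta_mean, 0.52)
  expect_equal(rep$sigma, coverage_variance(0.16, 0.72, 0.68))
  rep2 <- coverage_report(0.18, 0.70, 0.66,
                          reference = c(0.16, 0.72, 0.68))
  expect_true(rep2$adequate)
  expect_gt(rep2$nmae, 0)
})

test_that("rendered stain images recover their target coverages", {
  set.seed(23)
  for (k in 1:50) {
    targets <- c(test = runif(1, 0.02, 0.5), control_left = runif(1, 0.3, 0.9),
                 control_right = runif(1, 0.3, 0.9))
    img <- render_paper(targets = targets, seed = k)
    gt <- attr(img, "ground_truth")
    expect_true(all(abs(gt$achieved - gt$target) <= 0.01))
    rep <- measure_coverage(img)
    expect_equal(rep$eta_t, gt$achieved[gt$area == "test"])
  }
  expect_error(render_paper(targets = c(0.5, 1.2, 0.3)),
               class = "leafspray_domain_error")
})

test_that("deposit-driven rendering stains disks at ground positions", {
  dep <- tibble::tibble(x = 0, y = 0) # centre of the test area
  img <- render_paper(deposits = dep, droplet_radius = 1e-3)
  rep <- measure_coverage(img)
  expect_gt(rep$eta_t, 0)
  expect_equal(rep$eta_cl, 0)
  expect_equal(rep$eta_cr, 0)
  # empty deposits: blank paper
  img0 <- render_paper(deposits = tibble::tibble(x = double(), y = double()))
  expect_equal(mean(img0$pixels), 0)
})

test_that("stain images survive the PBM round trip", {
  img <- render_paper(targets = c(test = 0.16, control_left = 0.72,
                                  control_right = 0.68), seed = 9)
  f <- withr::local_tempfile(fileext = ".pbm")
  write_stain_pbm(img, f)
  img2 <- read_stain_pbm(f, layout = area_layout())
  expect_identical(img2$pixels, img$pixels)
  expect_equal(img2$resolution, img$resolution)
})
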