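test_that("retinex enhancement removes flat illumination, keeps dimensions", {
  flat <- matrix(120, 20, 30)
  out <- enhance_ssr(flat)
  expect_equal(dim(out), c(20, 30))
  expect_equal(max(out) - min(out), 0)  # constant in, constant out

  set.seed(201)
  img <- matrix(runif(20 * 30, 0, 255), 20, 30)
  expect_equal(dim(enhance_ssr(img)), dim(img))
  expect_message(enhance_ssr(cbind(img, 0)), "epsilon")
})

test_that("retinex matches a direct log-difference oracle on a step edge", {
  # step edge on a slow ramp: the transform must keep the step and
  # flatten the ramp
  W <- 40; H <- 24; sigma <- 300; eps <- 1
  ramp <- matrix(rep(seq(40, 120, length.out = W), each = H), H, W)
  step <- ramp; step[, (W / 2):W] <- step[, (W / 2):W] + 100
  out <- enhance_ssr(step, scale = sigma, eps = eps)

  # oracle: independent dense-Gaussian surround and log difference
  g <- function(n) {
    k <- exp(-outer(1:n, 1:n, "-")^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  surround <- g(H) %*% step %*% t(g(W))
  oracle <- log(step + eps) - log(surround + eps)
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle)) * 255
  expect_equal(unclass(out), oracle, tolerance = 1e-10)

  # the step stays the dominant contrast: the largest horizontal jump
  # in the output sits at the planted edge
  jumps <- abs(diff(out[1, ]))
  expect_equal(which.max(jumps), W / 2 - 1)
  expect_gt(max(jumps), 5 * max(jumps[-(W / 2 - 1)]))
})

test_that("magnification dimensions and identity behave as specified", {
  img <- matrix(runif(100), 10, 10)
  expect_equal(magnify(img, 1), img)
  expect_equal(dim(magnify(img, 3)), c(30, 30))
  expect_error(magnify(img, 0.5), "config")
})

test_that("cubic beats bilinear on a smooth (quadratic) ramp", {
  # analytic field quadratic in x: cubic convolution reproduces
  # quadratics up to boundary effects, bilinear does not
  f <- function(x) (x / 10)^2
  src <- matrix(rep(f(0:19 + 0.5), each = 8), 8, 20)
  fac <- 4
  xs_out <- ((0:(20 * fac - 1)) + 0.5) / fac  # original-scale coordinate
  truth <- matrix(rep(f(xs_out), each = 8 * fac), 8 * fac, 20 * fac)
  interior <- 9:(20 * fac - 8)
  err_cubic <- max(abs(magnify(src, fac)[1, interior] - truth[1, interior]))
  err_bilinear <- max(abs(magnify(src, fac, "bilinear")[1, interior] -
                            truth[1, interior]))
  expect_lt(err_cubic, err_bilinear)
  expect_lt(err_cubic, 1e-10)
})

test_that("binarization polarity and bounds are fixed", {
  expect_false(any(binarize(matrix(128, 5, 5))))
  expect_true(all(binarize(matrix(128, 5, 5), threshold = 0)))
  expect_true(all(binarize(matrix(139, 5, 5))))  # >= is foreground
  spec <- synthetic_spec()
  r <- render_eye_images(1, spec)
  bin <- binarize(unclass(r$images[[1]]), 139)
  # planted sclera (bright opening) is foreground, skin/iris are not
  expect_true(bin[20, 32])                     # inside the opening
  expect_false(bin[5, 5])                      # skin corner
})

test_that("contour extraction finds boundary, apex and corner of shapes", {
  # filled ellipse
  H <- 41; W <- 61
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)
  ell <- ((gx - 30) / 25)^2 + ((gy - 20) / 12)^2 <= 1
  ct <- extract_contour(ell)
  expect_equal(unname(ct$upper_mid), c(30, 8))   # topmost at centre column
  expect_equal(unname(ct$corner[1]), 55)         # extreme x
  expect_equal(unname(ct$corner[2]), 20, tolerance = 1)
  # boundary points all lie on the mask edge
  expect_true(all(ell[cbind(ct$boundary[, "y"] + 1, ct$boundary[, "x"] + 1)]))

  # two components: larger one wins
  two <- ell
  two[2:4, 2:4] <- TRUE
  ct2 <- extract_contour(two)
  expect_equal(unname(ct2$upper_mid), c(30, 8))

  # left corner on request
  ctl <- extract_contour(ell, corner = "left")
  expect_equal(unname(ctl$corner[1]), 5)

  expect_error(extract_contour(matrix(FALSE, 10, 10)), "no-contour")
  expect_warning(extract_contour(matrix(TRUE, 10, 10)), "unreliable")
})

test_that("D_uc sign convention: descending lid increases D_uc", {
  ct <- structure(list(boundary = cbind(x = 0, y = 0),
                       upper_mid = c(x = 10, y = 5),
                       corner = c(x = 20, y = 5), area = 1),
                  class = "eye_contour")
  expect_equal(compute_duc(ct), 0)
  ct$upper_mid["y"] <- -5  # 10 rows above the corner
  expect_equal(compute_duc(ct), -10)
})

test_that("the imaging chain tracks planted lid descent monotonically", {
  spec <- synthetic_spec()
  ramp <- seq(1.0, 0.55, length.out = 8)
  r <- render_eye_images(ramp, spec)
  duc <- vapply(r$images, duc_from_image, numeric(1))
  expect_true(all(diff(duc) > 0))  # lid descends as aperture falls
  # pipeline apex within 2 original-scale pixels of the rendered apex
  truth_duc <- r$truth$apex_y - r$truth$corner_y
  expect_lt(max(abs(duc / 33 - truth_duc)), 2)
})

test_that("per-blink maxima handle gaps and boundaries", {
  ev <- blink_events(c(0L, 10L), c(5L, 1L))
  duc <- c(-5, 0, 2, 0, -5, rep(-9, 5), 7)
  out <- max_duc_per_blink(ev, duc)
  expect_equal(out$max_duc, c(2, 7))  # incl. single-frame event

  # missing frames: computed over what exists, flagged
  out2 <- suppressMessages(
    max_duc_per_blink(ev, duc[1:3], duc_frames = 0:2))
  expect_equal(out2$max_duc[1], 2)
  expect_true(is.na(out2$max_duc[2]))
  expect_true(all(attr(out2, "duc_partial")))
})
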