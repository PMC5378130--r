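test_that("terminal points sit at the major-axis ends", {
  tp <- terminal_points(0, 0, 2, 0)
  expect_equal(unlist(tp), c(tx1 = 2, ty1 = 0, tx2 = -2, ty2 = 0))
  tp <- terminal_points(0, 0, 2, 90)
  expect_equal(unlist(tp), c(tx1 = 0, ty1 = 2, tx2 = 0, ty2 = -2))
  # 3-4-5 triangle: cos = 0.8, sin = 0.6
  tp <- terminal_points(3, 4, 5, 36.86989765)
  expect_equal(unlist(tp), c(tx1 = 7, ty1 = 7, tx2 = -1, ty2 = 1),
               tolerance = 1e-6)
})

test_that("terminal points satisfy the ellipse geometry identities", {
  set.seed(42)
  n <- 200
  xc <- runif(n, -50, 50); yc <- runif(n, -50, 50)
  a <- runif(n, 0.5, 30); th <- runif(n, -720, 720)
  tp <- terminal_points(xc, yc, a, th)
  d1 <- sqrt((tp$tx1 - xc)^2 + (tp$ty1 - yc)^2)
  d2 <- sqrt((tp$tx2 - xc)^2 + (tp$ty2 - yc)^2)
  expect_equal(d1, a, tolerance = 1e-9)
  expect_equal(d2, a, tolerance = 1e-9)
  expect_equal((tp$tx1 + tp$tx2) / 2, xc, tolerance = 1e-9)
  expect_equal((tp$ty1 + tp$ty2) / 2, yc, tolerance = 1e-9)
})

test_that("swapped terminal labels are restored from the previous frame", {
  prev <- list(tx1 = 10, ty1 = 0, tx2 = -10, ty2 = 0)
  raw <- list(tx1 = -10.2, ty1 = 0.1, tx2 = 10.1, ty2 = -0.1)
  fixed <- resolve_tp_identity(raw, prev)
  expect_equal(fixed$tx1, 10.1)
  expect_equal(fixed$tx2, -10.2)
  # already consistent labelling is left alone
  same <- resolve_tp_identity(list(tx1 = 9.9, ty1 = 0, tx2 = -9.9, ty2 = 0), prev)
  expect_equal(same$tx1, 9.9)
})

test_that("a slowly rotating body never flips its terminal labels", {
  # 2 deg/frame across the 90-degree mark, where the raw mod-180 fit jumps
  true_dir <- seq(0, 178, by = 2)
  raw <- true_dir %% 180
  lifted <- continuous_direction(raw)
  expect_equal(lifted, true_dir)
  tp <- terminal_points(0, 0, 5, lifted)
  jumps <- sqrt(diff(tp$tx1)^2 + diff(tp$ty1)^2)
  expect_true(all(jumps < 0.5))  # no 2a-sized label flip
})

test_that("a stationary body keeps constant labelling", {
  lifted <- continuous_direction(rep(37, 100))
  expect_equal(lifted, rep(37, 100))
})

test_that("node extraction collapses a stationary dwell into one node", {
  nd <- extract_nodes(rep(5, 20), rep(5, 20), dis_th = 1.7, mn_th = 14)
  expect_equal(nrow(nd), 1)
  expect_equal(c(nd$x, nd$y), c(5, 5))
  expect_equal(nd$mn, 20L)
})

test_that("fast regular motion yields no nodes", {
  x <- seq(0, 95, by = 5)
  nd <- extract_nodes(x, rep(0, length(x)), dis_th = 1.7, mn_th = 14)
  expect_equal(nrow(nd), 0)
})

test_that("dwell-travel-dwell yields two nodes at the dwell sites", {
  set.seed(9)
  jitter <- function(n, p) cbind(p[1] + rnorm(n, 0, 0.2), p[2] + rnorm(n, 0, 0.2))
  path <- rbind(jitter(18, c(10, 10)),
                cbind(seq(12, 30, by = 2), seq(12, 30, by = 2)),
                jitter(16, c(32, 33)))
  nd <- extract_nodes(path[, 1], path[, 2], dis_th = 1.7, mn_th = 14)
  expect_equal(nrow(nd), 2)
  expect_lt(sqrt((nd$x[1] - 10)^2 + (nd$y[1] - 10)^2), 0.5)
  expect_lt(sqrt((nd$x[2] - 32)^2 + (nd$y[2] - 33)^2), 0.5)
  expect_equal(nd$mn, c(18L, 16L))
})

test_that("node members are temporally consecutive runs", {
  set.seed(11)
  x <- cumsum(sample(c(0, 0, 0, 4), 400, replace = TRUE))
  y <- cumsum(sample(c(0, 0, 0, 4), 400, replace = TRUE))
  nd <- extract_nodes(x, y, dis_th = 1.7, mn_th = 5)
  expect_true(all(nd$last_index - nd$first_index + 1L == nd$mn))
  expect_true(all(diff(nd$first_index) > 0))
})

test_that("node count never increases with a stricter membership bound", {
  set.seed(13)
  x <- cumsum(rnorm(500, 0, 1.2)); y <- cumsum(rnorm(500, 0, 1.2))
  counts <- vapply(c(2, 5, 9, 14, 20), function(mn) {
    nrow(extract_nodes(x, y, dis_th = 1.7, mn_th = mn))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the strictness switch admits nodes with exactly mn_th members", {
  x <- c(rep(0, 14), 10, 20, 30)
  strict <- extract_nodes(x, rep(0, 17), dis_th = 1.7, mn_th = 14, strict = TRUE)
  loose <- extract_nodes(x, rep(0, 17), dis_th = 1.7, mn_th = 14, strict = FALSE)
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(loose), 1)
})

test_that("an empty path yields an empty node table", {
  nd <- extract_nodes(numeric(0), numeric(0))
  expect_equal(nrow(nd), 0)
})
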