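rand_joint <- function(seed, nvar = 3L, n = 60L) {
  # random empirical joint over binary variables, for property loops
  rng <- rng_stream(seed)
  cols <- lapply(seq_len(nvar), function(i)
    as.character(as.integer(rng_unif(rng, n) < rng_unif(rng, 1))))
  names(cols) <- c("x", "y", "z")[seq_len(nvar)]
  sup <- stats::setNames(rep(list(c("0", "1")), nvar), names(cols))
  empirical_dist(cols, support = sup)
}

test_that("empirical distributions are frequency estimates with bookkeeping", {
  p <- empirical_dist(c("L", "L", "R", "R"))
  expect_equal(as.numeric(p$probs), c(0.5, 0.5))
  expect_identical(p$n_samples, 4L)
  expect_equal(sum(p$counts), 4)

  point <- empirical_dist(rep("L", 9), support = list(x = c("L", "R")))
  expect_equal(as.numeric(point$probs), c(1, 0))  # declared symbol kept at 0
  expect_error(empirical_dist(character(0)), "empty")
  expect_error(empirical_dist(c("L", "Q"), support = list(x = c("L", "R"))),
               "support")
})

test_that("entropy matches direct evaluation with the 0 log 0 convention", {
  expect_identical(entropy(c(0.5, 0.5)), 1)
  expect_identical(entropy(c(1, 0)), 0)
  expect_equal(entropy(c(0.25, 0.75)), 0.811278124459, tolerance = 1e-10)
  p <- rand_joint(1)
  expect_equal(entropy(p), entropy(as.numeric(p$probs)))
})

test_that("mutual information matches a term-by-term enumeration oracle", {
  x <- c(rep("0", 3), "0", "1", rep("1", 3))
  y <- c(rep("0", 3), "1", "0", rep("1", 3))  # counts 3/1/1/3
  p <- empirical_dist(list(x = x, y = y))
  expect_equal(mutual_information(p), mi_oracle(x, y), tolerance = 1e-12)

  indep <- prob_table(array(c(0.06, 0.24, 0.14, 0.56), c(2, 2),
                           dimnames = list(x = c("0", "1"), y = c("0", "1"))))
  expect_equal(mutual_information(indep), 0, tolerance = 1e-12)

  copy <- empirical_dist(list(x = c("L", "R"), y = c("L", "R")))
  expect_identical(mutual_information(copy), 1)
  expect_error(mutual_information(rand_joint(2, nvar = 3L)), "2 variables")
})

test_that("MI is symmetric and non-negative on random empirical joints", {
  for (seed in 1:20) {
    p <- rand_joint(seed, nvar = 2L)
    q <- prob_table(aperm(p$probs, c(2, 1)))
    expect_equal(mutual_information(p), mutual_information(q), tolerance = 1e-12)
    expect_gte(mutual_information(p), -1e-12)
    expect_gte(entropy(p), 0)
  }
})

test_that("conditional MI handles independence, XOR and explaining away", {
  # z independent of (x, y): CMI equals MI
  xy <- rand_joint(5, nvar = 2L)
  arr <- array(0, c(2, 2, 2), dimnames = c(dimnames(xy$probs), list(z = c("0", "1"))))
  arr[, , 1] <- xy$probs / 2
  arr[, , 2] <- xy$probs / 2
  p3 <- prob_table(arr)
  expect_equal(conditional_mutual_information(p3), mutual_information(xy),
               tolerance = 1e-12)

  g <- expand.grid(x = c("0", "1"), z = c("0", "1"), stringsAsFactors = FALSE)
  y <- as.character(as.integer(g$x != g$z))      # y = XOR(x, z)
  pxor <- empirical_dist(list(x = g$x, y = y, z = g$z))
  expect_identical(conditional_mutual_information(pxor), 1)

  ycopy <- empirical_dist(list(x = g$x, y = g$z, z = g$z))  # y from z alone
  expect_equal(conditional_mutual_information(ycopy), 0, tolerance = 1e-12)
})

test_that("the chain rule I((y,z):x) = I(y:x) + I(z:x|y) holds exactly", {
  for (seed in 1:20) {
    p <- rand_joint(seed + 100)
    lhs <- mutual_information(collapse_vars(p, c("y", "z"), "yz"))
    # I(z:x|y): reorder to (z, x, y) so y is the conditioning variable
    pzxy <- prob_table(aperm(p$probs, c(3, 1, 2)))
    rhs <- mutual_information(marginal(p, c("y", "x"))) +
      conditional_mutual_information(pzxy)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("transfer entropy equals the CMI of the explicit lag embedding", {
  src <- c("L", "R", "R", "L", "R", "L", "L", "R", "R", "L")
  tgt <- c("R", "L", "R", "R", "L", "L", "R", "L", "R", "R")
  te <- transfer_entropy(src, tgt)
  expect_equal(te, cmi_oracle(tgt[2:10], src[1:9], tgt[1:9]), tolerance = 1e-12)

  # history = 2: condition on the pasted 2-step target past
  te2 <- transfer_entropy(src, tgt, history = 2)
  z2 <- paste(tgt[1:8], tgt[2:9], sep = "|")
  expect_equal(te2, cmi_oracle(tgt[3:10], src[2:9], z2), tolerance = 1e-12)
  expect_error(transfer_entropy(src, tgt[1:5]), "equal length")
  expect_error(transfer_entropy(src[1:2], tgt[1:2], history = 2), "too short")
})

test_that("transfer entropy reaches its analytic limits on long series", {
  rng <- rng_stream(8)
  src <- bit_action(as.integer(rng_unif(rng, 10000) < 0.5))
  tgt <- c("L", src[-10000])               # copies source with lag 1
  expect_lt(abs(transfer_entropy(src, tgt) - 1), 0.02)

  other <- bit_action(as.integer(rng_unif(rng, 10000) < 0.5))
  expect_lt(transfer_entropy(src, other), 0.005)  # no coupling
})

test_that("plug-in MI bias for independent binary pairs stays below 0.01 bits", {
  rng <- rng_stream(12)
  vals <- vapply(1:100, function(i) {
    x <- as.integer(rng_unif(rng, 500) < 0.5)
    y <- as.integer(rng_unif(rng, 500) < 0.5)
    mutual_information(empirical_dist(list(x = x, y = y)))
  }, 0)
  expect_gt(mean(vals), 0)       # plug-in bias is positive
  expect_lt(mean(vals), 0.01)
})
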