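test_that("principal strains match the eigen-decomposition", {
  expect_equal(principal_strains(diag(c(0.01, -0.003, -0.003))),
               c(0.01, -0.003))
  # pure engineering shear gamma_12 = 0.02 in Voigt form
  pr <- principal_strains(c(0, 0, 0, 0.02, 0, 0))
  expect_equal(pr, c(0.01, -0.01), tolerance = 1e-12)
  expect_equal(principal_strains(matrix(0, 3, 3)), c(0, 0))
  # random symmetric tensors against eigen() directly
  set.seed(21)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3); S <- (A + t(A)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(principal_strains(S), c(max(ev), min(ev)),
                 tolerance = 1e-12)
  }
  expect_error(principal_strains(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
})

test_that("dominant strain keeps the larger magnitude with its sign", {
  expect_equal(dominant_strain(0.01, -0.04), -0.04)
  expect_equal(dominant_strain(0.02, -0.01), 0.02)
  expect_equal(dominant_strain(0.01, -0.01), 0.01)  # tie -> tensile
  expect_error(dominant_strain(-0.01, 0.01), "eps_max")
})

test_that("von Mises closed forms are exact", {
  expect_equal(von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises(diag(c(50, 50, 50))), 0)
  expect_equal(von_mises(c(0, 0, 0, 10, 0, 0)), sqrt(3) * 10,
               tolerance = 1e-12)
})

test_that("peak device stress follows the exclusion-then-average rule", {
  vals <- as.numeric(1:10000)
  pk <- peak_device_stress(vals, yield_strength = 20000)
  # brute-force oracle: drop ceil(0.001 N), average the next 10
  srt <- sort(vals, decreasing = TRUE)
  oracle <- mean(srt[(10 + 1):(10 + 10)])
  expect_equal(pk$peak, oracle)
  expect_equal(pk$peak, 9985.5)
  expect_equal(pk$yield_ratio, 9985.5 / 20000)
  expect_true(pk$elastic)
  # permutation invariance
  set.seed(31)
  pk2 <- peak_device_stress(sample(vals), 20000)
  expect_equal(pk2$peak, pk$peak)
  # constant field
  expect_equal(peak_device_stress(rep(7, 100), 10)$peak, 7)
  # yield flag flips with the threshold
  expect_false(peak_device_stress(rep(7, 100), 5)$elastic)
  expect_error(peak_device_stress(1:10, 100), "at least 20")
  # random sets against the oracle
  for (i in 1:5) {
    v <- stats::rlnorm(2000, 3, 1)
    s <- sort(v, decreasing = TRUE)
    dr <- ceiling(0.001 * length(v))
    expect_equal(peak_device_stress(v, 1)$peak, mean(s[(dr + 1):(dr + 10)]))
  }
})

fake_solution <- function(strain_rows, elems = seq_len(nrow(strain_rows))) {
  structure(list(strain = strain_rows,
                 stress = strain_rows,
                 weight = rep(1, nrow(strain_rows)),
                 element = elems,
                 region = rep("granulation", nrow(strain_rows))),
            class = "fe_solution")
}

fake_mesh <- function(healing) {
  structure(list(elem_sets = list(healing_region = healing)),
            class = "labeled_mesh")
}

test_that("healing summary splits tensile/compressive and applies the 15% rule", {
  n <- 40
  eps <- matrix(0, n, 6); eps[, 1] <- 0.01   # uniaxial 1% tension
  hs <- summarize_healing(fake_solution(eps), fake_mesh(seq_len(n)))
  expect_true(all(is.na(hs$compressive)))
  expect_equal(unname(hs$tensile[["median"]]), 1)
  expect_equal(hs$fraction_below_15, 1)
  eps2 <- matrix(0, n, 6); eps2[, 1] <- -0.20  # uniform 20% compression
  hs2 <- summarize_healing(fake_solution(eps2), fake_mesh(seq_len(n)))
  expect_equal(hs2$fraction_below_15, 0)
  expect_equal(unname(hs2$compressive[["median"]]), 20)
  expect_error(summarize_healing(fake_solution(eps), fake_mesh(integer(0))),
               "empty")
})

test_that("healing quartiles match order-statistics on crafted data", {
  vals <- seq(0.001, 0.101, length.out = 101)  # exact type-7 order stats
  eps <- matrix(0, 101, 6); eps[, 1] <- vals
  hs <- summarize_healing(fake_solution(eps), fake_mesh(1:101))
  expect_equal(unname(hs$tensile[["q1"]]), 100 * vals[26])
  expect_equal(unname(hs$tensile[["median"]]), 100 * vals[51])
  expect_equal(unname(hs$tensile[["q3"]]), 100 * vals[76])
  expect_equal(unname(hs$tensile[["min"]]), 100 * vals[1])
  expect_equal(unname(hs$tensile[["max"]]), 100 * vals[101])
  expect_true(hs$tensile[["q1"]] <= hs$tensile[["median"]] &&
                hs$tensile[["median"]] <= hs$tensile[["q3"]])
})
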