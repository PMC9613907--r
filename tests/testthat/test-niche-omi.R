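test_that("standardize_env centres and scales under the site weights", {
  et <- env_table(matrix(c(0, 2), 2, 1, dimnames = list(NULL, "bio1")))
  z <- standardize_env(et)
  expect_equal(unname(z$env[, 1]), c(-1, 1))   # mean 1, population SD 1

  # idempotence
  z2 <- standardize_env(z)
  expect_equal(z2$env, z$env, tolerance = 1e-12)

  # weighted version: mean and variance are weighted moments
  et3 <- env_table(matrix(c(0, 1, 3), 3, 1, dimnames = list(NULL, "v")),
                   site_weights = c(2, 1, 1))
  z3 <- standardize_env(et3)
  expect_equal(sum(z3$weights * z3$env[, 1]), 0, tolerance = 1e-12)
  expect_equal(sum(z3$weights * z3$env[, 1]^2), 1, tolerance = 1e-12)

  const <- env_table(cbind(bio1 = c(1, 2, 3), flat = c(5, 5, 5)))
  expect_error(standardize_env(const), "flat")
})

test_that("drop_redundant removes exactly duplicated variables", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 1, 2))
  et <- drop_redundant(env_table(m))
  expect_equal(colnames(et$env), c("a", "c"))  # b is a scaled copy of a
})

test_that("OMI matches its defining geometry on small cases", {
  # a species distributed like the site weights sits at the origin
  Z <- matrix(c(-1, 1, -1, 1, -1, 1), 3, 2,
              dimnames = list(NULL, c("v1", "v2")))
  et <- standardize_env(env_table(Z))
  occ <- occurrence_table(rbind(ubiquitous = c(1, 1, 1),
                                partial = c(2, 1, 0)))
  res <- omi_analysis(et, occ, n_axes = 1)
  expect_equal(res$species$omi[1], 0, tolerance = 1e-12)

  # 2 sites, 1 standardized variable, species only at site 2 -> OMI 1
  et2 <- standardize_env(env_table(matrix(c(0, 2), 2, 1,
                                          dimnames = list(NULL, "v"))))
  occ2 <- occurrence_table(rbind(spec = c(0, 3), other = c(1, 1)))
  res2 <- omi_analysis(et2, occ2, n_axes = 1)
  expect_equal(res2$species$omi[1], 1, tolerance = 1e-12)
  expect_equal(res2$axis_pct[1], 100)

  # mirrored centroids: axis 1 carries all variability, symmetric scores
  Z3 <- matrix(c(-1, 1, 0, 0, 0, 0, -1, 1), 4, 2,
               dimnames = list(NULL, c("v1", "v2")))
  et3 <- env_table(Z3)
  occ3 <- occurrence_table(rbind(plus = c(0, 1, 0, 0),
                                 minus = c(1, 0, 0, 0)))
  res3 <- omi_analysis(et3, occ3, n_axes = 2)
  expect_equal(res3$axis_pct_all[1], 100, tolerance = 1e-9)
  expect_equal(res3$species_scores[1, 1], -res3$species_scores[2, 1],
               tolerance = 1e-12)
})

test_that("per-species inertia decomposes as OMI + Tol + Rtol", {
  set.seed(31)
  for (k in 1:5) {
    Z <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    et <- standardize_env(env_table(Z))
    occ <- occurrence_table(matrix(rpois(3 * 20, 2) + c(1, 0, 0), 3, 20))
    res <- omi_analysis(et, occ, n_axes = 2)
    expect_equal(res$species$inertia,
                 res$species$omi + res$species$tol + res$species$rtol,
                 tolerance = 1e-9)
    expect_true(all(res$species$omi >= 0))
    expect_true(all(res$species$tol >= -1e-12))
    expect_true(all(res$species$rtol >= -1e-12))
    expect_equal(sum(res$axis_pct_all), 100, tolerance = 1e-9)
  }
})

test_that("omi_analysis agrees with the loop-and-eigen oracle", {
  set.seed(17)
  for (k in 1:4) {
    n_sites <- sample(8:20, 1); p <- sample(2:5, 1)
    Z <- matrix(rnorm(n_sites * p), n_sites,
                dimnames = list(NULL, paste0("v", 1:p)))
    et <- standardize_env(env_table(Z))
    occ <- matrix(rpois(4 * n_sites, 1.5), 4, n_sites) + 1
    res <- omi_analysis(et, occurrence_table(occ), n_axes = 2)
    orc <- oracle_omi(et$env, et$weights, occ)
    expect_equal(res$species$omi, orc$omi, tolerance = 1e-9)
    expect_equal(res$species$tol, orc$tol, tolerance = 1e-9)
    expect_equal(res$species$rtol, orc$rtol, tolerance = 1e-9)
    expect_equal(res$axis_pct_all, orc$axis_pct, tolerance = 1e-9)
  }
})

test_that("OMI is invariant under orthogonal rotation of the space", {
  set.seed(23)
  Z <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("v", 1:3)))
  occ <- occurrence_table(matrix(rpois(2 * 15, 2) + 1, 2, 15))
  et <- env_table(Z)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))       # random orthogonal matrix
  etR <- env_table(Z %*% Q)
  a <- omi_analysis(et, occ, n_axes = 2)
  b <- omi_analysis(etR, occ, n_axes = 2)
  expect_equal(a$species$omi, b$species$omi, tolerance = 1e-9)
  expect_equal(a$axis_pct_all, b$axis_pct_all, tolerance = 1e-9)
})

test_that("a pure-noise variable leaves OMI essentially unchanged", {
  nd <- simulate_niche(n_sites = 80, n_vars = 4, offset = c(2, 0, 0, 0),
                       records = c(specialist = 60, generalist = 120),
                       seed = 5)
  et <- standardize_env(nd$env)
  base <- omi_analysis(et, nd$occ, n_axes = 1)$species$omi
  # resampling-based spread of the baseline OMI
  set.seed(6)
  boot <- replicate(60, {
    idx <- sample(nrow(nd$occ["specialist", , drop = FALSE]))
    occ_b <- nd$occ
    occ_b["specialist", ] <- as.vector(
      tabulate(sample(seq_len(ncol(occ_b)), sum(occ_b["specialist", ]),
                      replace = TRUE,
                      prob = occ_b["specialist", ] / sum(occ_b["specialist", ])),
               ncol(occ_b)))
    omi_analysis(et, occurrence_table(occ_b), n_axes = 1)$species$omi[1]
  })
  se <- sd(boot)
  set.seed(7)
  noise <- matrix(rnorm(nrow(nd$env$env)), ncol = 1,
                  dimnames = list(NULL, "noise"))
  et2 <- standardize_env(env_table(cbind(nd$env$env, noise)))
  withnoise <- omi_analysis(et2, nd$occ, n_axes = 1)$species$omi
  expect_lt(abs(withnoise[1] - base[1]), 3 * se + 0.05)
})

test_that("permutation test flags a planted specialist, spares a generalist", {
  nd <- simulate_niche(n_sites = 50, n_vars = 3, offset = c(3, 0, 0),
                       records = c(specialist = 50, generalist = 100),
                       seed = 9)
  et <- standardize_env(nd$env)
  pt <- omi_permutation_test(et, nd$occ, n_perm = 99, seed = 2)
  expect_lt(pt$p_value[pt$species == "specialist"], 0.05)
  expect_gt(pt$p_value[pt$species == "generalist"], 0.05)
})
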