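test_that("degenerate marginal concentrates all mass at zero", {
  cfg <- sim_config(200, marginals = c(1, 0, 0, 0), seed = 3)
  tab <- simulate_responses(cfg)
  expect_true(all(as.matrix(tab[paste0("item", 1:9)]) == 0L))
})

test_that("identical configurations give bit-identical output and do not touch global RNG state", {
  cfg <- sim_config(500, seed = 42)
  set.seed(99); before <- .Random.seed
  t1 <- simulate_responses(cfg)
  expect_identical(before, .Random.seed)
  t2 <- simulate_responses(cfg)
  expect_identical(t1, t2)
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(t1, simulate_responses(cfg2)))
})

test_that("empirical item frequencies reproduce configured marginals at large n", {
  m <- c(0.6, 0.2, 0.1, 0.1)
  cfg <- sim_config(100000, marginals = m, latent_correlation = diag(9),
                    seed = 7)
  tab <- simulate_responses(cfg)
  for (j in 1:9) {
    freq <- tabulate(tab[[paste0("item", j)]] + 1L, 4L) / 100000
    expect_lt(max(abs(freq - m)), 0.01)
  }
})

test_that("pairwise dependence matches the bivariate-normal quadrature oracle", {
  R <- matrix(0.6, 9, 9); diag(R) <- 1
  m <- default_marginals()
  cfg <- sim_config(100000, marginals = m, latent_correlation = R, seed = 11)
  tab <- simulate_responses(cfg)
  for (pair in list(c(1L, 2L), c(3L, 9L))) {
    pmf <- oracle_joint_pmf(m[pair[1], ], m[pair[2], ], 0.6)
    emp <- table(factor(tab[[paste0("item", pair[1])]], levels = 0:3),
                 factor(tab[[paste0("item", pair[2])]], levels = 0:3)) / 100000
    expect_lt(max(abs(emp - pmf)), 0.01)
    rho_emp <- cor(tab[[paste0("item", pair[1])]],
                   tab[[paste0("item", pair[2])]], method = "spearman")
    expect_lt(abs(rho_emp - oracle_spearman(pmf)), 0.05)
  }
})

test_that("invalid configurations are rejected with explanatory errors", {
  expect_error(sim_config(10, marginals = c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_error(sim_config(10, marginals = c(0.7, 0.4, -0.1, 0)), "nonnegative")
  bad <- matrix(0.99, 9, 9); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(sim_config(10, latent_correlation = bad), "positive definite")
  asym <- diag(9); asym[1, 2] <- 0.3
  expect_error(sim_config(10, latent_correlation = asym), "symmetric")
  expect_error(sim_config(10, missing_rate = 1.2), "missing_rate")
})

test_that("prevalence calibration is a fixed point at the current prevalence", {
  cfg <- sim_config(1000, seed = 5)
  current <- phqpairs:::estimate_prevalence(cfg, n_mc = 100000)
  out <- calibrate_prevalence(cfg, current, tolerance = 0.02, n_mc = 100000)
  expect_lt(abs(attr(out, "offset")), 0.05)
  expect_lt(max(abs(out$marginals - cfg$marginals)), 0.02)
})

test_that("unreachable prevalence targets fail with an explanation", {
  cfg <- sim_config(100, seed = 5)
  expect_error(
    calibrate_prevalence(cfg, 1e-6, tolerance = 1e-7, n_mc = 20000,
                         max_offset = 0.5),
    "unreachable")
})

test_that("missingness injection is a no-op at rate 0, total at rate 1, binomial in between", {
  cfg <- sim_config(1000, seed = 9)
  tab <- simulate_responses(cfg)
  expect_identical(inject_missing(tab, 0, seed = 1), tab)
  all_na <- inject_missing(tab, 1, seed = 1)
  expect_true(all(is.na(as.matrix(all_na[paste0("item", 1:9)]))))
  holed <- inject_missing(tab, 0.1, seed = 2)
  n_miss <- sum(is.na(as.matrix(holed[paste0("item", 1:9)])))
  expect_lt(abs(n_miss - 900), 3 * sqrt(9000 * 0.1 * 0.9))
  observed <- !is.na(as.matrix(holed[paste0("item", 1:9)]))
  expect_identical(as.matrix(holed[paste0("item", 1:9)])[observed],
                   as.matrix(tab[paste0("item", 1:9)])[observed])
  expect_identical(inject_missing(tab, 0.1, seed = 2), holed)
})

test_that("planting with boost 1 leaves a one-factor correlation unchanged", {
  cfg <- sim_config(100, latent_correlation = onefactor_correlation(default_loadings()),
                    seed = 1)
  out <- plant_informative_pair(cfg, c(2, 4), 1)
  expect_lt(max(abs(out$latent_correlation - cfg$latent_correlation)), 1e-12)
})

test_that("planted items acquire the largest item-restscore correlations", {
  cfg <- plant_informative_pair(recovery_config(100000, seed = 21), c(2, 4), 1.5)
  tab <- simulate_responses(cfg)
  items <- as.matrix(tab[paste0("item", 1:9)])
  total <- rowSums(items)
  rest_cor <- vapply(1:9, function(j) cor(items[, j], total - items[, j]),
                     numeric(1))
  expect_setequal(order(rest_cor, decreasing = TRUE)[1:2], c(2L, 4L))
})

test_that("a boost pushing loadings past 1 is rejected", {
  cfg <- recovery_config(100, seed = 1)
  expect_error(plant_informative_pair(cfg, c(2, 4), 2), "positive definite|loading")
  expect_error(plant_informative_pair(cfg, c(2, 2), 1.2), "distinct")
  expect_error(plant_informative_pair(cfg, c(2, 4), 0.8), ">= 1")
})

test_that("response tables and configurations round-trip through disk", {
  cfg <- plant_informative_pair(recovery_config(50, seed = 13), c(1, 9), 1.2)
  tab <- inject_missing(simulate_responses(cfg), 0.15, seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_responses(tab, csv)
  expect_identical(readLines(csv, n = 1),
                   paste(c("id", paste0("item", 1:9)), collapse = ","))
  back <- read_responses(csv)
  expect_equal(back$item3, tab$item3)
  expect_equal(sum(is.na(back)), sum(is.na(tab)))

  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_sim_config(cfg, path)
    cfg2 <- read_sim_config(path)
    expect_equal(cfg2$marginals, cfg$marginals, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(cfg2$latent_correlation, cfg$latent_correlation,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(cfg2$planted_pair$pair, c(1, 9))
    expect_identical(simulate_responses(cfg2)$item1,
                     simulate_responses(cfg)$item1)
  }
})

test_that("renamed columns are mapped through col_map on read", {
  tab <- simulate_responses(sim_config(20, seed = 3))
  names(tab) <- c("id", paste0("phq", 1:9))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  back <- read_responses(csv, col_map = setNames(paste0("phq", 1:9),
                                                 paste0("item", 1:9)))
  expect_named(back, c("id", paste0("item", 1:9)))
  expect_error(read_responses(csv), "col_map")
})
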