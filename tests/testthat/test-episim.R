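test_that("zero heritability gives the constant-penetrance table", {
  m <- generate_penetrance_model(2, 0.3, 0, prevalence_target = 0.2)
  expect_equal(m$table, rep(0.2, 9))
  expect_equal(m$h2, 0)
  expect_equal(m$prevalence, 0.2)
})

test_that("generated models are strict and hit the target heritability", {
  cases <- list(c(2, 0.05, 0.05), c(2, 0.4, 0.2), c(3, 0.05, 0.005),
                c(3, 0.2, 0.05), c(4, 0.05, 0.001))
  for (i in seq_along(cases)) {
    cc <- cases[[i]]
    m <- generate_penetrance_model(cc[1], cc[2], cc[3], seed = 400 + i)
    mm <- oracle_model_moments(m)
    expect_lt(mm$worst_subset_marginal_dev, 1e-6,
              label = sprintf("strictness (k=%g maf=%g)", cc[1], cc[2]))
    expect_lt(abs(mm$h2 - cc[3]) / cc[3], 0.01)
    expect_equal(mm$K, m$prevalence, tolerance = 1e-9)
    expect_true(all(m$table >= 0 & m$table <= 1))
    expect_gt(m$prevalence, 0)
    expect_lt(m$prevalence, 1)
  }
})

test_that("model generation is reproducible under a seed", {
  a <- generate_penetrance_model(3, 0.2, 0.05, seed = 5)
  b <- generate_penetrance_model(3, 0.2, 0.05, seed = 5)
  expect_identical(a, b)
})

test_that("unattainable heritability fails loudly, naming the pair", {
  # strictness caps achievable h2 well below 0.1 for 3 loci at MAF 0.1
  expect_error(generate_penetrance_model(3, 0.1, 0.1, max_tries = 10L),
               "h2 = 0.1 at MAF = 0.1")
})

test_that("sampled joint genotypes follow the conditional closed forms", {
  m <- generate_penetrance_model(2, 0.2, 0.1, seed = 21)
  cfg <- sim_config(2, 0.2, 0.1, n_snps = 2, n_cases = 1e5, n_controls = 1e5,
                    seed = 22)
  ds <- sample_dataset(m, cfg)
  probs <- conditional_genotype_probs(m)
  gid <- ds$genotypes[, ds$truth[1]] * 3L + ds$genotypes[, ds$truth[2]] + 1L
  # map dataset truth columns back to model locus order: truth preserves it
  for (grp in list(list(sel = ds$phenotype == 1L, p = probs$case),
                   list(sel = ds$phenotype == 0L, p = probs$control))) {
    obs <- tabulate(gid[grp$sel], nbins = 9)
    pid <- probs$G[, 1] * 3 + probs$G[, 2] + 1
    p <- numeric(9)
    p[pid] <- grp$p
    keep <- p * sum(obs) >= 5        # merge sparse cells into one bin
    x <- c(obs[keep], sum(obs[!keep]))
    pr <- c(p[keep], sum(p[!keep]))
    gof <- suppressWarnings(chisq.test(x[pr > 0], p = pr[pr > 0] / sum(pr)))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("with h2 = 0 the case and control genotype laws coincide", {
  m <- generate_penetrance_model(2, 0.25, 0)
  probs <- conditional_genotype_probs(m)
  expect_equal(probs$case, probs$control)
})

test_that("noise SNPs are independent of phenotype", {
  m <- generate_penetrance_model(2, 0.1, 0.05, seed = 31)
  cfg <- sim_config(2, 0.1, 0.05, n_snps = 60, n_cases = 4000,
                    n_controls = 4000, seed = 32)
  ds <- sample_dataset(m, cfg)
  noise <- setdiff(seq_len(60), ds$truth)
  af_case <- colMeans(ds$genotypes[ds$phenotype == 1L, noise]) / 2
  af_ctrl <- colMeans(ds$genotypes[ds$phenotype == 0L, noise]) / 2
  # each |diff| is O(1/sqrt(n)); the average over 58 SNPs must be tiny
  expect_lt(mean(abs(af_case - af_ctrl)), 0.015)
})

test_that("dataset shape, truth bookkeeping and config validation", {
  m <- generate_penetrance_model(3, 0.2, 0.05, seed = 41)
  cfg <- sim_config(3, 0.2, 0.05, n_snps = 15, n_cases = 50, n_controls = 40,
                    seed = 42)
  ds <- sample_dataset(m, cfg)
  expect_equal(dim(ds), c(90L, 15L))
  expect_equal(ds$phenotype, rep(c(1L, 0L), c(50L, 40L)))
  expect_length(ds$truth, 3L)
  expect_identical(ds, sample_dataset(m, cfg))  # seeded determinism
  expect_error(sim_config(2, 0.6, 0.1, n_snps = 5), "maf")
  expect_error(sim_config(2, 0.2, 0.1, n_snps = 1), "n_snps")
})

test_that("simulation_grid writes datasets plus a deterministic manifest", {
  dir1 <- tempfile(); dir2 <- tempfile()
  grid <- list(sim_config(2, 0.2, 0.05, n_snps = 10, n_cases = 30,
                          n_controls = 30),
               sim_config(2, 0.4, 0.05, n_snps = 10, n_cases = 30,
                          n_controls = 30))
  man1 <- simulation_grid(grid, replicates = 2, seed = 99, dir = dir1)
  man2 <- simulation_grid(grid, replicates = 2, seed = 99, dir = dir2)
  expect_equal(nrow(man1), 4L)
  expect_identical(readLines(file.path(dir1, "manifest.tsv")),
                   readLines(file.path(dir2, "manifest.tsv")))
  ds <- read_dataset(file.path(dir1, man1$file[1]), "csv")
  expect_equal(dim(ds), c(60L, 10L))
  # truth columns recorded in the manifest round-trip as indices
  truth <- as.integer(strsplit(man1$truth[1], ",")[[1]])
  expect_length(truth, 2L)
  # empty grid / zero replicates still produce a valid manifest
  man0 <- simulation_grid(grid, replicates = 0, seed = 1, dir = tempfile())
  expect_equal(nrow(man0), 0L)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("infeasible grid cells are reported and skipped", {
  grid <- list(sim_config(3, 0.1, 0.1, n_snps = 8, n_cases = 20,
                          n_controls = 20),
               sim_config(2, 0.3, 0.05, n_snps = 8, n_cases = 20,
                          n_controls = 20))
  d <- tempfile()
  man <- simulation_grid(grid, replicates = 1, seed = 3, dir = d)
  expect_equal(nrow(man), 1L)
  expect_match(attr(man, "skipped"), "infeasible")
  expect_true(file.exists(file.path(d, "skipped.tsv")))
  unlink(d, recursive = TRUE)
})
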