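test_that("survey round-trips through the CSV dialect unchanged", {
  obs <- tiny_obs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(obs, path)
  back <- read_survey(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$colony_id, obs$colony_id)
  expect_equal(back$size_t, obs$size_t)
  expect_equal(back$survived, obs$survived)
  expect_equal(back$remnant_sizes, obs$remnant_sizes)

  # a 500-row synthetic table survives the same round trip
  sim <- simulate_survey(generative_params(n_colonies = 500, n_years = 2),
                         seed = 11)
  write_survey(sim$survey, path)
  back <- read_survey(path)
  expect_equal(nrow(back), nrow(sim$survey))
  expect_equal(back$size_t, sim$survey$size_t, tolerance = 1e-9)
  expect_equal(back$size_t1, sim$survey$size_t1, tolerance = 1e-9)
  expect_equal(back$fragmented, sim$survey$fragmented)
  expect_equal(unlist(back$remnant_sizes), unlist(sim$survey$remnant_sizes),
               tolerance = 1e-9)
})

test_that("row-level invariants are rejected with row numbers", {
  obs <- tiny_obs()
  obs$size_t1[3] <- 50  # dead colony with a size at t+1
  expect_error(validate_survey(obs), "non-survivor.*3")

  obs2 <- tiny_obs()
  obs2$remnant_sizes[[2]] <- numeric(0)
  expect_error(validate_survey(obs2), "no remnant sizes")

  obs3 <- tiny_obs()
  obs3$size_t[1] <- -2
  expect_error(validate_survey(obs3), "non-positive size_t")
})

test_that("a missing required column is a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(colony_id = "A", size_t = 3), path,
                   row.names = FALSE)
  expect_error(read_survey(path), "missing column")
})

test_that("strategy assignment is deterministic for single-strategy genera
           and proportional for multi-strategy genera", {
  catalog <- data.frame(
    taxon = c("Porites", "Acropora", "Acropora"),
    strategy = c("weedy", "competitive", "weedy"),
    n_species = c(1L, 3L, 1L))
  obs <- data.frame(
    colony_id = sprintf("C%04d", 1:4000),
    taxon = rep(c("Porites", "Acropora"), each = 2000),
    strategy = NA_character_, stringsAsFactors = FALSE)

  out <- assign_strategies(obs, catalog, seed = 5)
  expect_true(all(out$strategy[out$taxon == "Porites"] == "weedy"))
  frac <- mean(out$strategy[out$taxon == "Acropora"] == "competitive")
  expect_gt(frac, 0.70)  # binomial expectation 0.75 at n = 2000
  expect_lt(frac, 0.80)

  # determinism and per-colony constancy across repeated rows
  out2 <- assign_strategies(obs, catalog, seed = 5)
  expect_identical(out$strategy, out2$strategy)
  dup <- rbind(obs, obs)
  outd <- assign_strategies(dup, catalog, seed = 5)
  per_colony <- tapply(outd$strategy, outd$colony_id,
                       function(s) length(unique(s)))
  expect_true(all(per_colony == 1))

  expect_error(assign_strategies(
    data.frame(colony_id = "X", taxon = "Unknownia", strategy = NA),
    catalog, seed = 1), "Unknownia")
})

test_that("assignment frequencies match catalog proportions", {
  catalog <- data.frame(taxon = "G", strategy = c("competitive", "weedy",
                                                  "stress_tolerant"),
                        n_species = c(5L, 3L, 2L))
  probs <- c(competitive = 0.5, weedy = 0.3, stress_tolerant = 0.2)
  obs <- data.frame(colony_id = sprintf("C%05d", 1:10000), taxon = "G",
                    strategy = NA_character_)
  pvals <- vapply(1:20, function(seed) {
    out <- assign_strategies(obs, catalog, seed = seed)
    counts <- table(factor(out$strategy, levels = names(probs)))
    stats::chisq.test(counts, p = probs)$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("assemblage filtering drops generalists and warns on empty sets", {
  obs <- tiny_obs()
  obs$strategy <- c("competitive", "generalist", "competitive")
  out <- filter_assemblage(obs, strategy = "competitive", region = "AT")
  expect_false(any(out$strategy == "generalist"))
  expect_equal(nrow(out), 2)

  expect_warning(empty <- filter_assemblage(obs, region = "ZZ"),
                 "no observations")
  expect_equal(nrow(empty), 0)

  # retained counts equal a brute-force per-row scan
  sim <- simulate_survey(generative_params(n_colonies = 300, n_years = 3,
                                           strategy = "weedy",
                                           region = "JS"), seed = 3)$survey
  sim$strategy[seq(1, nrow(sim), by = 7)] <- "generalist"
  got <- nrow(filter_assemblage(sim, strategy = "weedy", region = "JS"))
  manual <- sum(vapply(seq_len(nrow(sim)), function(i) {
    sim$strategy[i] == "weedy" && sim$region[i] == "JS"
  }, logical(1)))
  expect_equal(got, manual)
})
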