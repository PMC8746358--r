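test_that("noise-free construction is exactly linear in the planted column", {
  d <- generate_matrix(synthetic_spec(n_compounds = 30, n_descriptors = 4,
                                      planted = 1, beta = 2,
                                      noise_sd_frac = 0, seed = 5))
  expect_equal(d$matrix$y, unname(25 + 2 * d$matrix$x[, 1]))
})

test_that("generation is seed-reproducible and seed-sensitive", {
  sp <- synthetic_spec(seed = 77)
  expect_identical(generate_matrix(sp), generate_matrix(sp))
  d2 <- generate_matrix(synthetic_spec(seed = 78))
  expect_false(identical(generate_matrix(sp)$matrix$x, d2$matrix$x))
})

test_that("an OLS oracle on the planted columns explains the variance", {
  d <- generate_matrix(synthetic_spec(n_compounds = 200, n_descriptors = 40,
                                      planted = 5, noise_sd_frac = 0.1,
                                      seed = 13))
  df <- data.frame(y = d$matrix$y, d$matrix$x[, d$planted])
  r2 <- summary(stats::lm(y ~ ., data = df))$r.squared
  expect_gte(r2, 0.9)
})

test_that("column count frequencies match the binomial model", {
  d <- generate_matrix(synthetic_spec(n_compounds = 10000, n_descriptors = 3,
                                      planted = 1, seed = 21))
  expected <- stats::dbinom(0:3, 3, 0.4)
  for (j in 1:3) {
    obs <- tabulate(d$matrix$x[, j] + 1L, nbins = 4)
    p <- stats::chisq.test(obs, p = expected)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("degenerate specs are rejected", {
  expect_error(synthetic_spec(beta = 0, noise_sd_frac = 0), "degenerate")
  expect_error(synthetic_spec(n_compounds = 5), "at least 7")
  expect_error(synthetic_spec(planted = c(1, 99)), "out of range")
})

test_that("molecule generator yields parseable, descriptor-rich sets", {
  set <- generate_molecule_set(10, seed = 3)
  expect_length(set, 10)
  counts <- suppressMessages(lapply(set, function(cp)
    enumerate_ql_descriptors(cp$structure)))
  expect_gte(length(unique(unlist(lapply(counts, names)))), 5)
  expect_length(generate_molecule_set(0), 0)
  # different seeds give different structure multisets (checked loosely)
  hash <- function(s) paste(sort(vapply(s, function(cp)
    molgraph_formula(cp$structure), "")), collapse = "|")
  diffs <- vapply(1:10, function(i)
    hash(generate_molecule_set(6, seed = i)) !=
    hash(generate_molecule_set(6, seed = i + 100)), logical(1))
  expect_gte(sum(diffs), 5)
})

test_that("recovery metrics compute precision and recall arithmetic", {
  f1 <- list(matrix = list(x = matrix(0, 1, 5,
               dimnames = list(NULL, paste0("D", 1:5)))),
             pharmacophore = list(descriptors = data.frame(
               label = paste0("D", 1:5), sens = 1.2)))
  m1 <- recovery_metrics(f1, paste0("D", 1:5))
  expect_equal(m1["retained", "precision"], 1)
  expect_equal(m1["significant", "recall"], 1)

  f2 <- list(matrix = list(x = matrix(0, 1, 2,
               dimnames = list(NULL, c("D9", "D10")))),
             pharmacophore = list(descriptors = data.frame(
               label = "D9", sens = 1.2)))
  m2 <- recovery_metrics(f2, paste0("D", 1:5))
  expect_equal(m2["retained", "precision"], 0)
  expect_equal(m2["significant", "recall"], 0)

  f3 <- list(matrix = list(x = matrix(0, 1, 8,
               dimnames = list(NULL, paste0("D", 1:8)))),
             pharmacophore = list(descriptors = data.frame(
               label = paste0("D", c(1:4, 6:9)), sens = 1.2)))
  m3 <- recovery_metrics(f3, paste0("D", 1:5))
  expect_equal(m3["significant", "precision"], 0.5)
  expect_equal(m3["significant", "recall"], 0.8)
})
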