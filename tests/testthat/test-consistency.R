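fake_maps <- function(n, nv = 60, seed = 1, method = "m") {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    structure(list(values = rnorm(nv, 50, 8), valid = rep(TRUE, nv),
                   method = method, id = sprintf("s%03d", i)),
              class = "surface_map"))
}

test_that("pairwise CC hits the exact combinatorial pair counts", {
  for (spec in list(c(50, 1225), c(21, 210), c(14, 91))) {
    ccs <- pairwise_cc(fake_maps(spec[1], seed = spec[1]), group = "g",
                       method = "m")
    expect_identical(ccs$n_pairs, as.integer(spec[2]))
    expect_identical(nrow(unique(ccs$pairs[c("id_a", "id_b")])),
                     as.integer(spec[2]))
  }
})

test_that("combining the patient groups concatenates without cross-group pairs", {
  cc_tau <- pairwise_cc(fake_maps(21, seed = 1), group = "tau", method = "m")
  cc_tdp <- pairwise_cc(fake_maps(14, seed = 2), group = "tdp", method = "m")
  both <- combine_patient_groups(cc_tau, cc_tdp)
  expect_identical(both$n_pairs, 301L)
  # no pair mixes an id from each source set
  tau_ids <- unique(c(cc_tau$pairs$id_a, cc_tau$pairs$id_b))
  in_tau_a <- both$pairs$id_a %in% tau_ids
  in_tau_b <- both$pairs$id_b %in% tau_ids
  expect_true(all(in_tau_a == in_tau_b))
  cc_other <- pairwise_cc(fake_maps(5, seed = 3), group = "x", method = "other")
  expect_error(combine_patient_groups(cc_tau, cc_other), "method")
})

test_that("correlations match identity cases and a brute-force formula", {
  m <- fake_maps(2, seed = 7)
  m[[2]]$values <- m[[1]]$values
  expect_equal(pairwise_cc(m)$pairs$cc, 1, tolerance = 1e-12)
  m[[2]]$values <- -m[[1]]$values
  expect_equal(pairwise_cc(m)$pairs$cc, -1, tolerance = 1e-12)

  # brute-force sum-formula Pearson on a random pair with partial validity
  m <- fake_maps(2, seed = 8)
  m[[1]]$valid[1:7] <- FALSE
  m[[2]]$valid[5:11] <- FALSE
  ok <- m[[1]]$valid & m[[2]]$valid
  x <- m[[1]]$values[ok]; y <- m[[2]]$values[ok]; n <- length(x)
  brute <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pairwise_cc(m)$pairs$cc, brute, tolerance = 1e-12)

  # under 3 common vertices: undefined and logged
  m[[1]]$valid[] <- FALSE; m[[1]]$valid[1:2] <- TRUE
  res <- pairwise_cc(m)
  expect_true(is.na(res$pairs$cc))
  expect_match(res$log, "undefined")
})

test_that("mean participant CC matches hand enumeration and combinatorics", {
  maps <- fake_maps(4, seed = 9)
  ccs <- pairwise_cc(maps, group = "g", method = "m")
  expect_identical(ccs$n_pairs, 6L)
  pcc <- mean_participant_cc(ccs)
  expect_identical(pcc$n_pairs, rep(3L, 4))  # n - 1 pairs each
  p <- ccs$pairs
  for (id in pcc$id) {
    hand <- mean(p$cc[p$id_a == id | p$id_b == id])
    expect_equal(pcc$mean_cc[pcc$id == id], hand, tolerance = 1e-12)
  }
  # mean of participant means equals mean of all pairwise CCs exactly
  expect_equal(mean(pcc$mean_cc), mean(p$cc), tolerance = 1e-12)
})

test_that("method comparisons match closed-form t statistics", {
  a <- pairwise_cc(fake_maps(5, seed = 10), group = "g", method = "A")
  b <- a
  b$method <- "B"
  same <- compare_methods(a, b, "paired")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$cohens_d, 0)

  # hand-computed paired t on the 10 pair differences
  b$pairs$cc <- a$pairs$cc + c(0.02, -0.01, 0.03, 0.01, 0, 0.02, -0.02,
                               0.01, 0.04, 0.02)
  cmp <- compare_methods(a, b, "paired")
  d <- a$pairs$cc - b$pairs$cc
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-10)
  expect_identical(cmp$df, length(d) - 1)
  # two-sample pooled variant has df = 2 n_pairs - 2
  cmp2 <- compare_methods(a, b, "two_sample_pooled")
  expect_identical(cmp2$df, 2 * nrow(a$pairs) - 2)
  sp <- sqrt(((10 - 1) * var(a$pairs$cc) + (10 - 1) * var(b$pairs$cc)) / 18)
  t2_hand <- (mean(a$pairs$cc) - mean(b$pairs$cc)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(cmp2$t_statistic, t2_hand, tolerance = 1e-10)
  # paired mode requires matching pair sets
  c_other <- pairwise_cc(fake_maps(4, seed = 11), group = "g", method = "C")
  expect_error(compare_methods(a, c_other, "paired"), "pair sets")
})

test_that("group comparison of mean participant CC uses the pooled-t convention", {
  a <- fake_maps(50, seed = 12)
  b <- fake_maps(14, seed = 13)
  pa <- mean_participant_cc(pairwise_cc(a, group = "ctl", method = "m"))
  pb <- mean_participant_cc(pairwise_cc(b, group = "pat", method = "m"))
  cmp <- compare_groups_mean_cc(pa, pb)
  expect_identical(cmp$df, 62)  # 50 + 14 - 2

  # closed form on a 3 vs 3 toy
  x <- c(0.5, 0.6, 0.55); y <- c(0.48, 0.52, 0.5)
  toy <- compare_groups_mean_cc(x, y)
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  expect_equal(toy$t_statistic, (mean(x) - mean(y)) / (sp * sqrt(2 / 3)),
               tolerance = 1e-10)
  expect_identical(toy$df, 4)
})

test_that("enumeration order does not change pairwise results", {
  maps <- fake_maps(6, seed = 14)
  ccs1 <- pairwise_cc(maps)
  ccs2 <- pairwise_cc(rev(maps))
  key <- function(p) {
    k <- apply(p[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
    p$cc[order(k)]
  }
  expect_equal(key(ccs1$pairs), key(ccs2$pairs), tolerance = 1e-12)
})
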