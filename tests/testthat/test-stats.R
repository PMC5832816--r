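test_that("one_sample_t matches the closed form and stats::t.test", {
  r <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- one_sample_t(c(2, 4, 6), 0)
  expect_equal(r2$statistic, 4 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$df, 2L)

  set.seed(14)
  for (k in 1:10) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    ref <- runif(1, -5, 5)
    mine <- one_sample_t(x, ref)
    oracle <- stats::t.test(x, mu = ref)
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("one_sample_t is translation invariant and guards degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  a <- one_sample_t(x, 2)
  b <- one_sample_t(x + 7, 9)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(one_sample_t(c(1), 0), class = "invermass_degenerate_test_error")
  expect_error(one_sample_t(c(2, 2, 2), 0), class = "invermass_degenerate_test_error")
})

test_that("bonferroni compares each p against alpha over m", {
  res <- bonferroni(c(0.01, 0.2, 0.001, 0.5))
  expect_equal(res$alpha_adjusted, rep(0.05 / 4, 4))
  expect_equal(res$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(res$significant,
                   unname(stats::p.adjust(res$p_value, "bonferroni") < 0.05))
  expect_equal(bonferroni(0.04)$significant, TRUE)
  expect_true(all(bonferroni(rep(0, 5))$significant))
  expect_error(bonferroni(c(0.5, 1.2)), class = "invermass_domain_error")
})

test_that("mixed model recovers a constant method offset", {
  # a whisper of noise keeps the residual variance identifiable
  eps <- c(1, -1, 2, -2, 1, -1) * 1e-6
  tab <- data.frame(individual_id = rep(c("a", "b", "c"), 2),
                    method = rep(c("direct", "m2"), each = 3),
                    mass_mg = c(1, 2, 3, 2, 3, 4) + eps)
  fit <- suppressWarnings(method_mixed_model(tab))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "intercept"], 2, tolerance = 1e-4)
  expect_equal(cf$estimate[cf$term == "m2"], 1, tolerance = 1e-4)
  expect_equal(fit$reference_level, "direct")
})

test_that("balanced-design estimates equal column-mean differences exactly", {
  set.seed(31)
  inds <- sprintf("i%02d", 1:8)
  methods <- c("direct", "m1", "m2", "m3")
  offs <- c(direct = 0, m1 = 0.4, m2 = -0.2, m3 = 3)
  tab <- expand.grid(individual_id = inds, method = methods,
                     stringsAsFactors = FALSE)
  ind_eff <- setNames(rnorm(8, 0, 1), inds)
  tab$mass_mg <- 10 + ind_eff[tab$individual_id] + offs[tab$method] +
    rnorm(nrow(tab), 0, 0.1)
  fit <- method_mixed_model(tab)
  cf <- fit$coefficients
  colmeans <- tapply(tab$mass_mg, tab$method, mean)
  expect_equal(cf$estimate[cf$term == "intercept"],
               unname(colmeans["direct"]), tolerance = 1e-8)
  for (m in c("m1", "m2", "m3")) {
    expect_equal(cf$estimate[cf$term == m],
                 unname(colmeans[m] - colmeans["direct"]), tolerance = 1e-8)
  }
})

test_that("mixed model recovers simulated offsets within 3 standard errors", {
  set.seed(77)
  inds <- sprintf("i%02d", 1:20)
  offs <- c(direct = 0, m1 = -0.5, m2 = -0.3, m3 = 10.5)
  tab <- expand.grid(individual_id = inds, method = names(offs),
                     stringsAsFactors = FALSE)
  ind_eff <- setNames(rnorm(20, 0, 1), inds)
  tab$mass_mg <- 20 + ind_eff[tab$individual_id] + offs[tab$method] +
    rnorm(nrow(tab), 0, 0.1)
  fit <- method_mixed_model(tab)
  cf <- fit$coefficients
  for (m in c("m1", "m2", "m3")) {
    row <- cf[cf$term == m, ]
    expect_lt(abs(row$estimate - offs[[m]]) / row$std_error, 3)
  }
  expect_true(all(cf$p_value_approx >= 0 & cf$p_value_approx <= 1))
})

test_that("mixed model input contracts are enforced", {
  tab <- data.frame(individual_id = rep(c("a", "b", "c"), 2),
                    method = rep(c("direct", "m2"), each = 3),
                    mass_mg = c(1, 2, 3, 2.2, 3.1, 4.4))
  expect_error(method_mixed_model(tab[tab$method == "direct", ]),
               class = "invermass_domain_error")
  expect_error(method_mixed_model(tab, reference = "m9"),
               class = "invermass_domain_error")
  tab3 <- rbind(tab,
                data.frame(individual_id = c("a", "b", "c"), method = "m3",
                           mass_mg = c(5, 6, 7)))
  expect_warning(method_mixed_model(tab3[-c(1, 8), ]), "unbalanced")
})

test_that("overestimation_ratio is a scale-free mean ratio", {
  tab <- data.frame(individual_id = rep(c("a", "b"), 2),
                    method = rep(c("direct", "m3"), each = 2),
                    mass_mg = c(1, 2, 2, 4))
  expect_equal(overestimation_ratio(tab, "m3"), 2)
  expect_equal(overestimation_ratio(tab, "direct"), 1)
  tab2 <- tab; tab2$mass_mg <- tab2$mass_mg * 13.7
  expect_equal(overestimation_ratio(tab2, "m3"), 2, tolerance = 1e-12)
  expect_error(overestimation_ratio(tab, "m9"), class = "invermass_domain_error")
})

test_that("mass_table validation catches malformed input", {
  expect_error(mass_table(data.frame(x = 1)), class = "invermass_format_error")
  dup <- data.frame(individual_id = c("a", "a"), method = c("m1", "m1"),
                    mass_mg = c(1, 2))
  expect_error(mass_table(dup), class = "invermass_format_error")
  neg <- data.frame(individual_id = "a", method = "m1", mass_mg = -1)
  expect_error(mass_table(neg), class = "invermass_domain_error")
})
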