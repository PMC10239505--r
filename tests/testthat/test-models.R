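test_that("differential analysis reports the expected terms per region", {
  sim <- make_sim(seed = 1)
  prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
  res <- run_differential(prep)
  cx <- res[res$region == "cortex" & res$analyte_id == "Hcy", ]
  expect_setequal(cx$term, c("grp_pd_cn", "grp_pd_mci", "grp_pd_d",
                             "ldopa_pd_nd", "ldopa_pd_d"))
  # putamen has no dementia rows and no dementia levodopa term
  pu <- res[res$region == "putamen" & res$analyte_id == "Hcy", ]
  expect_setequal(pu$term, c("grp_pd_cn", "grp_pd_mci", "ldopa_pd_nd"))
  expect_true(all(res$n_effective > 0))
  # convergence flags are reported honestly; the overwhelming majority of
  # fits converge within the iteration cap
  expect_gte(mean(res$converged), 0.9)
  # all-PD mode collapses the cognitive groups
  res2 <- run_differential(prep, mode = "all_pd", regions = "cortex")
  expect_setequal(unique(res2$term), c("grp_pd", "ldopa_pd_nd",
                                       "ldopa_pd_d"))
})

test_that("null cohorts yield essentially no discoveries on average", {
  # DOPA is excluded: it is genuinely associated with the levodopa terms
  # (it defines them), so it is not a null analyte
  fracs <- vapply(1:4, function(s) {
    sim <- simulate_cohort(sim_config(n_analytes_lc = 15,
                                      n_analytes_fia = 45), seed = 22 + s)
    prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
    res <- run_differential(prep, regions = "cortex")
    res <- res[res$analyte_id != "DOPA", ]
    mean(res$q <= 0.05, na.rm = TRUE)
  }, 0)
  expect_lte(mean(fracs), 0.01)
})

test_that("a planted levodopa-dementia effect is detected and estimated", {
  cfg <- sim_config(n_analytes_lc = 6, n_analytes_fia = 10,
                    levodopa_effects = data.frame(analyte = "Hcy",
                                                  pd_class = "PD-D",
                                                  effect = 2))
  sim <- simulate_cohort(cfg, seed = 31)
  prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
  res <- run_differential(prep, regions = "cortex")
  hit <- res[res$analyte_id == "Hcy" & res$term == "ldopa_pd_d", ]
  expect_lte(hit$q, 0.05)
  expect_gt(hit$beta, 1)
  # q-values are stratified: every (term, method, type) stratum is a
  # self-contained FDR run
  expect_true(all(!is.na(res$q)))
})

test_that("progression coefficients are two-way standardized and invariant", {
  cfg <- sim_config(n_analytes_lc = 4, n_analytes_fia = 4,
                    score_effects = data.frame(analyte = "Hcy",
                                               score = "updrs_m",
                                               slope = 0.5))
  sim <- simulate_cohort(cfg, seed = 47)
  prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
  res <- run_progression(prep, "updrs_m", regions = "cortex")
  b <- res$beta[res$analyte_id == "Hcy"]
  expect_lt(abs(b - 0.5), 0.3)
  # affine rescaling of the raw score leaves the coefficient unchanged
  prep2 <- prep
  prep2$meta$updrs_m <- 3 * prep2$meta$updrs_m + 7
  res2 <- run_progression(prep2, "updrs_m", regions = "cortex")
  expect_equal(res2$beta, res$beta, tolerance = 1e-6)
  # shifting control analyte values is absorbed by the PD indicator
  prep3 <- prep
  ids <- rownames(prep3$regions$cortex$values)
  ctrl <- prep3$meta$group[match(ids, prep3$meta$sample_id)] == "CTRL"
  prep3$regions$cortex$values[ctrl, ] <-
    prep3$regions$cortex$values[ctrl, ] + 10
  res3 <- run_progression(prep3, "updrs_m", regions = "cortex")
  expect_equal(res3$beta, res$beta, tolerance = 1e-6)
})

test_that("planted progression slopes are recovered on average", {
  cfg <- sim_config(n_analytes_lc = 3, n_analytes_fia = 3,
                    n_per_group = list(
                      cortex = c(CTRL = 36, `PD-CN` = 14, `PD-MCI` = 19,
                                 `PD-D` = 32)),
                    n_plates = c(cortex = 2),
                    score_effects = data.frame(analyte = "Hcy",
                                               score = "updrs_m",
                                               slope = 0.5))
  betas <- vapply(1:40, function(s) {
    sim <- simulate_cohort(cfg, seed = 100 + s)
    prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
    res <- run_progression(prep, "updrs_m")
    res$beta[res$analyte_id == "Hcy"]
  }, 0)
  expect_lt(abs(mean(betas) - 0.5), 0.15)
})

test_that("missing scores drop PD subjects from that model only", {
  sim <- make_sim(seed = 53)
  prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
  pd_cx <- prep$meta$group %in% c("PD-CN", "PD-MCI", "PD-D") &
    prep$meta$region == "cortex"
  drop_ids <- prep$meta$sample_id[pd_cx][1:10]
  prep$meta$updrs_m[prep$meta$sample_id %in% drop_ids] <- NA
  res <- run_progression(prep, "updrs_m", regions = "cortex")
  full <- run_differential(prep, regions = "cortex")
  expect_equal(unique(res$n_effective),
               unique(full$n_effective) - 10)
  # a score constant among PD is a hard error
  prep$meta$updrs_m[pd_cx] <- 5
  expect_error(run_progression(prep, "updrs_m", regions = "cortex"),
               "constant")
})

test_that("collinearity metrics match their closed forms", {
  set.seed(61)
  # orthogonal design (columns centered so Pearson r is exactly zero)
  X <- qr.Q(qr(scale(matrix(rnorm(300), 100, 3), scale = FALSE)))
  colnames(X) <- c("a", "b", "c")
  rep_ok <- collinearity_check(X)
  expect_true(all(abs(rep_ok$correlations$r) < 1e-10))
  expect_true(all(abs(rep_ok$gvif$adjusted_gvif - 1) < 1e-10))
  expect_false(rep_ok$flagged)
  # two regressors with r = 0.5: adjusted GVIF = (1/(1-0.25))^(1/2)
  z1 <- rnorm(5000)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(5000)
  # construct exact correlation by orthogonalization
  z2 <- 0.5 * scale(z1)[, 1] +
    sqrt(0.75) * scale(resid(lm(z2 ~ z1)))[, 1]
  X2 <- cbind(a = scale(z1)[, 1], b = z2)
  rep2 <- collinearity_check(X2)
  expect_equal(rep2$correlations$r, 0.5, tolerance = 1e-10)
  expect_equal(rep2$gvif$adjusted_gvif,
               rep(sqrt(1 / 0.75), 2), tolerance = 1e-10)
  expect_false(rep2$flagged)
  # duplicated column: GVIF diverges and is flagged
  X3 <- cbind(a = z1, b = z1)
  rep3 <- collinearity_check(X3)
  expect_true(rep3$flagged)
  expect_true(any(!is.finite(rep3$gvif$gvif) | rep3$gvif$gvif > 1e6))
})

test_that("cohort table tests match exact oracles", {
  # Fisher 2x2 with perfect separation: p = 2 / C(20,10)
  ids <- sprintf("S%02d", 1:20)
  meta <- make_small_meta(ids, rep(c("CTRL", "PD-D"), each = 10))
  meta$sex <- rep(c("M", "F"), each = 10)
  tab <- cohort_table(meta, continuous = character(0), binary = "sexM")
  expect_equal(tab$p_all_groups, 2 / choose(20, 10), tolerance = 1e-10)
  # identical balanced groups: Fisher p = 1
  meta$sex <- rep(c("M", "F"), 10)
  tab2 <- cohort_table(meta, continuous = character(0), binary = "sexM")
  expect_equal(tab2$p_all_groups, 1)
  # entirely missing characteristic is omitted with a note
  meta$mmse <- NA_real_
  tab3 <- cohort_table(meta, continuous = c("age", "mmse"),
                       binary = character(0))
  expect_false("mmse" %in% tab3$characteristic)
  expect_true("mmse" %in% attr(tab3, "omitted"))
})

test_that("heteroscedastic ANOVA in the cohort table has power", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    ids <- sprintf("S%02d", 1:40)
    meta <- make_small_meta(ids, rep(c("CTRL", "PD-D"), each = 20))
    meta$age <- rnorm(40) + 2 * (meta$group == "PD-D")
    tab <- cohort_table(meta, continuous = "age", binary = character(0))
    tab$p_all_groups < 0.001
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("Welch tests find no score-levodopa association when none exists", {
  sim <- make_sim(seed = 71)
  prep <- preprocess(sim$analytes, sim$meta, sim$blanks)
  w <- welch_by_levodopa(prep$meta, prep$levodopa)
  expect_true(all(w$p > 0 & w$p <= 1))
  # L+ assignment is independent of scores by construction: no tiny q
  expect_gt(min(w$q), 0.05)
  expect_true(all(c("PD-D", "PD-ND") %in% w$pd_class))
})
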