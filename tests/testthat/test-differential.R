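# small paired two-group layout reused across tests: 3 subjects x MB/EV
ctl_sheet <- toy_sheet(3, treatments = "CTL")

test_that("paired design has intercept, subject blocks and one group column", {
  d <- build_design(ctl_sheet, "within_treatment_between_population",
                    treatment = "CTL")
  expect_equal(dim(d$design), c(6, 4))
  expect_equal(d$coef, "MB")
  expect_equal(qr(d$design)$rank, ncol(d$design))
  # single subject: rank-deficient pairing is refused
  one <- ctl_sheet[ctl_sheet$subject == "S1", ]
  expect_error(build_design(one, "within_treatment_between_population",
                            treatment = "CTL"), "2 subjects")
  # between-treatment design within a compartment
  sheet <- toy_sheet(3)
  d2 <- build_design(sheet, "between_treatment_within_population",
                     compartment = "MB", treatments = c("CTL", "CLFS"))
  expect_equal(dim(d2$design), c(6, 4))
  expect_equal(d2$coef, "CLFS")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  n_mirs <- 400
  d <- build_design(ctl_sheet, "within_treatment_between_population",
                    treatment = "CTL")
  offs <- rep(log(2e5), 6)
  # Poisson data: estimate collapses to the lower end of the grid
  cfgp <- sim_config(seed = 41, n_mirs = n_mirs, treatments = "CTL",
                     frac_de = 0, frac_mb_exclusive = 0,
                     frac_ev_exclusive = 0, dispersion = 0,
                     subject_sd = 0, planted_corr = 0,
                     lib_size_range = c(2e5, 2e5))
  simp <- simulate_counts(cfgp)
  cnt <- simp$counts$counts[rowSums(simp$counts$counts) > 0, ]
  dispp <- estimate_dispersions(cnt, d$design, offs)
  expect_lte(dispp$common, 0.01)
  # NB truth 0.2 recovered within (0.1, 0.3)
  cfgn <- cfgp; cfgn$dispersion <- 0.2; cfgn$seed <- 42L
  class(cfgn) <- "sim_config"
  simn <- simulate_counts(cfgn)
  cntn <- simn$counts$counts[rowSums(simn$counts$counts) > 0, ]
  dispn <- estimate_dispersions(cntn, d$design, offs)
  expect_gt(dispn$common, 0.1)
  expect_lt(dispn$common, 0.3)
  # infinite prior collapses tagwise onto common
  disp_inf <- estimate_dispersions(cntn[1:50, ], d$design, offs,
                                   prior_df = 1e9)
  expect_equal(unname(disp_inf$tagwise), rep(disp_inf$common, 50),
               tolerance = 1e-6)
  # all-zero rows are refused
  cnt0 <- rbind(cntn[1:5, ], zero = 0)
  expect_error(estimate_dispersions(cnt0, d$design, offs), "all-zero")
})

test_that("NB GLM fits match closed forms and a generic GLM oracle", {
  d <- build_design(ctl_sheet, "within_treatment_between_population",
                    treatment = "CTL")
  offs <- rep(0, 6)
  # saturated group-means case: dispersion 0, equal offsets
  grp <- d$design[, "MB"]
  y <- ifelse(grp == 1, 20, 10)
  simple_design <- cbind(`(Intercept)` = 1, MB = grp)
  fit <- fit_nb_glm(matrix(y, 1, dimnames = list("m", rownames(d$design))),
                    simple_design, offs, dispersion = 0)
  expect_equal(unname(fit$coefficients[1, "MB"]) / log(2), 1, tolerance = 1e-6)
  # intercept-only: fitted mean is the offset-weighted mean
  offs2 <- log(c(1, 1, 2, 2, 4, 4) * 1e3)
  y2 <- c(10, 12, 25, 19, 41, 38)
  fit2 <- fit_nb_glm(matrix(y2, 1, dimnames = list("m", rownames(d$design))),
                     matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)")),
                     offs2, dispersion = 0)
  expect_equal(unname(fit2$fitted[1, ]),
               exp(offs2) * sum(y2) / sum(exp(offs2)), tolerance = 1e-6)
  # oracle: MASS negative-binomial GLM with fixed theta on random miRs
  skip_if_not_installed("MASS")
  set.seed(13)
  phi <- 0.15
  for (g in 1:20) {
    mu <- exp(rnorm(6, 5, 0.3))
    yv <- rnbinom(6, size = 1 / phi, mu = mu)
    if (all(yv == 0)) yv[1] <- 1
    fitp <- fit_nb_glm(matrix(yv, 1, dimnames = list("m", NULL)),
                       d$design, offs, dispersion = phi)
    ref <- suppressWarnings(glm(
      yv ~ 0 + d$design + offset(offs),
      family = MASS::negative.binomial(theta = 1 / phi),
      control = glm.control(epsilon = 1e-12, maxit = 100)))
    expect_equal(unname(fitp$coefficients[1, ]), unname(coef(ref)),
                 tolerance = 1e-6)
  }
})

test_that("QL F-test output is deterministic with monotone p in F", {
  cfg <- sim_config(seed = 51, n_mirs = 150, treatments = "CTL",
                    frac_de = 0.2, de_target = "compartment",
                    dispersion = 0.1, lib_size_range = c(3e5, 4e5),
                    subject_sd = 0, planted_corr = 0)
  sim <- simulate_counts(cfg)
  flt <- filter_low_expressors(sim$counts)
  nf <- tmm_factors(flt$kept)
  d <- build_design(flt$kept$samples, "within_treatment_between_population",
                    treatment = "CTL")
  offs <- norm_offsets(nf)[d$sample_ids]
  fit <- fit_nb_glm(flt$kept$counts[, d$sample_ids], d$design, offs, 0.1)
  t1 <- ql_f_test(fit, d$coef)
  t2 <- ql_f_test(fit, d$coef)
  expect_identical(t1, t2)
  ok <- !is.na(t1$f_stat)
  expect_true(all(t1$p_value[ok] > 0 & t1$p_value[ok] <= 1))
  o <- order(t1$f_stat[ok])
  expect_true(all(diff(t1$p_value[ok][o]) <= 1e-12))
  # fdr column behind the flag
  expect_true("fdr" %in% names(ql_f_test(fit, d$coef, add_fdr = TRUE)))
  # saturated design is refused
  sat <- cbind(d$design, extra1 = c(1, 0, 0, 0, 0, 0),
               extra2 = c(0, 1, 0, 0, 0, 0))
  fit_sat <- suppressWarnings(
    fit_nb_glm(flt$kept$counts[1:5, d$sample_ids], sat, offs, 0.1))
  expect_error(ql_f_test(fit_sat, "MB"), "residual df")
})

test_that("run_all_contrasts has the dual-normalization structure", {
  cfg <- sim_config(seed = 61, n_mirs = 250, frac_de = 0.08,
                    de_target = "compartment", de_compartment = "MB",
                    planted_log2fc = 3, dispersion = 0.1,
                    frac_mb_exclusive = 0, frac_ev_exclusive = 0,
                    lib_size_range = c(4e5, 6e5))
  sim <- simulate_counts(cfg)
  res <- run_all_contrasts(sim$counts)
  expect_named(res$within_treatment, c("CTL", "CLFS", "IHFS"))
  expect_named(res$between_treatment, c("MB", "EV"))
  # exactly 6 pairwise between-treatment tables
  expect_equal(sum(lengths(res$between_treatment)), 6)
  expect_named(res$between_treatment$MB,
               c("CLFSvsCTL", "IHFSvsCTL", "IHFSvsCLFS"))
  expect_named(res$filtered_ids, c("joint", "MB", "EV"))
  # planted MB-enriched miRs carry positive MB-side logFC in every
  # within-treatment table
  planted <- sim$truth$mir_id[sim$truth$de_flag]
  for (trt in names(res$within_treatment)) {
    tab <- res$within_treatment[[trt]]
    hit <- tab[tab$mir_id %in% planted & !is.na(tab$p_value), ]
    expect_gt(nrow(hit), 0)
    expect_true(all(hit$log2_fc > 0))
  }
})

test_that("balanced null data shows no systematic logFC sign bias", {
  cfg <- sim_config(seed = 71, n_mirs = 300, frac_de = 0,
                    frac_mb_exclusive = 0, frac_ev_exclusive = 0,
                    dispersion = 0.1, lib_size_range = c(4e5, 6e5))
  sim <- simulate_counts(cfg)
  res <- run_all_contrasts(sim$counts)
  meds <- vapply(res$within_treatment, function(tab) {
    stats::median(tab$log2_fc[!is.na(tab$p_value)])
  }, numeric(1))
  expect_lt(mean(abs(meds)), 0.1)
})
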