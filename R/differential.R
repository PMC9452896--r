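#' Build a paired design matrix for one contrast family
#'
#' Encodes the within-subject pairing as subject fixed effects (blocking)
#' plus group indicator(s): intercept, subject blocks, then either a
#' compartment term (MB vs EV within one treatment) or treatment term(s)
#' within one compartment. The returned coefficient name(s) extract the
#' group effect.
#'
#' @param samples sample sheet (data.frame).
#' @param analysis `"within_treatment_between_population"` (MB vs EV inside
#'   one treatment) or `"between_treatment_within_population"` (treatment
#'   effects inside one compartment).
#' @param treatment treatment selector for the between-population analysis.
#' @param compartment compartment selector (`"MB"`/`"EV"`) for the
#'   between-treatment analysis.
#' @param treatments treatments to include in the between-treatment
#'   analysis; the first is the reference level. Default: all present.
#' @return list with `design` (full-column-rank model matrix), `coef`
#'   (names of the group coefficient column(s)), and `sample_ids` (samples
#'   used, design row order).
#' @export
build_design <- function(samples,
                         analysis = c("within_treatment_between_population",
                                      "between_treatment_within_population"),
                         treatment = NULL, compartment = NULL,
                         treatments = NULL) {
  analysis <- match.arg(analysis)
  samples <- validate_sample_sheet(samples)
  if (analysis == "within_treatment_between_population") {
    if (is.null(treatment)) stop("`treatment` selector required")
    sub <- samples[samples$treatment == treatment, , drop = FALSE]
    if (length(unique(sub$compartment)) < 2) {
      stop("need both MB and EV samples within treatment ", treatment)
    }
    # MB effect relative to EV: positive log2FC = myobundle-enriched
    grp <- factor(sub$compartment, levels = c("EV", "MB"))
  } else {
    if (is.null(compartment)) stop("`compartment` selector required")
    sub <- samples[samples$compartment == compartment, , drop = FALSE]
    if (!is.null(treatments)) {
      sub <- sub[sub$treatment %in% treatments, , drop = FALSE]
      grp <- factor(sub$treatment, levels = treatments)
    } else {
      grp <- factor(sub$treatment, levels = treatment_levels(sub$treatment))
    }
    if (nlevels(droplevels(grp)) < 2) {
      stop("need at least two treatment groups within compartment ",
           compartment)
    }
  }
  if (length(unique(sub$subject)) < 2) {
    stop("paired design needs at least 2 subjects (got ",
         length(unique(sub$subject)), ")")
  }
  subj <- factor(sub$subject)
  df <- data.frame(subject = subj, group = grp)
  design <- stats::model.matrix(~ subject + group, data = df)
  rownames(design) <- sub$sample_id
  grp_cols <- grep("^group", colnames(design), value = TRUE)
  colnames(design) <- sub("^group", "", colnames(design))
  coef <- sub("^group", "", grp_cols)
  if (qr(design)$rank < ncol(design)) {
    stop("design is confounded (group aliased with subject blocks)")
  }
  list(design = design, coef = coef, sample_ids = sub$sample_id)
}

# --- NB GLM via IRLS -------------------------------------------------------

# Fit one negative-binomial log-link GLM by iteratively reweighted least
# squares. Working weights mu/(1+phi*mu); convergence when the max relative
# coefficient change drops below `tol`. Zero-count protection: fitted means
# are initialized at (y + mean(y))/2, strictly positive for any non-zero
# row, and the linear predictor is clamped to +-30.
nb_fit_one <- function(y, X, offset, phi, tol = 1e-8, maxit = 50) {
  if (all(y == 0)) {
    return(list(coefficients = rep(NA_real_, ncol(X)), fitted = rep(0, length(y)),
                deviance = 0, converged = TRUE, all_zero = TRUE))
  }
  mu <- (y + mean(y)) / 2
  eta <- log(mu) - offset
  beta <- qr.solve(X, eta)
  converged <- FALSE
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    new_beta <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    delta <- max(abs(new_beta - beta) / (abs(beta) + 1))
    beta <- new_beta
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # secondary deviance criterion: catches boundary fits (a group with
    # all-zero counts) whose coefficients drift toward -Inf while the
    # fitted likelihood has plateaued
    mu_new <- exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30))
    dev <- nb_deviance(y, mu_new, phi)
    if (delta > 1e-3 && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-10) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(coefficients = beta, fitted = mu, deviance = nb_deviance(y, mu, phi),
       converged = converged, all_zero = FALSE)
}

# NB residual deviance (Poisson limit at phi = 0).
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi <= 0) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

# Cox-Reid adjusted profile log-likelihood of one gene at dispersion phi.
nb_apl_one <- function(y, X, offset, phi) {
  fit <- nb_fit_one(y, X, offset, phi)
  if (fit$all_zero) return(NA_real_)
  mu <- pmax(fit$fitted, 1e-300)
  ll <- if (phi <= 0) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * w)
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  ll - 0.5 * as.numeric(ld)
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the summed Cox-Reid adjusted profile
#' likelihood (APL) over a log-spaced grid with golden-section refinement.
#' Tagwise estimates are the per-miR APL grid maximizers, shrunk toward the
#' common value on the log scale with weight `prior_df` against the
#' residual degrees of freedom (so `prior_df -> Inf` recovers the common
#' value for every miR).
#'
#' @param counts count matrix (filtered: no all-zero rows).
#' @param design model matrix (full rank).
#' @param offsets numeric vector of log effective library sizes (from
#'   [norm_offsets()]), one per sample.
#' @param prior_df shrinkage weight toward the common dispersion
#'   (default 10).
#' @param phi_grid dispersion grid searched before refinement.
#' @return list with `common`, `tagwise` (named per miR), `prior_df`.
#' @export
estimate_dispersions <- function(counts, design, offsets, prior_df = 10,
                                 phi_grid = exp(seq(log(1e-4), log(4),
                                                    length.out = 11))) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0)) {
    stop("all-zero miR rows must be filtered out before dispersion estimation")
  }
  G <- nrow(counts)
  apl <- matrix(NA_real_, G, length(phi_grid))
  for (k in seq_along(phi_grid)) {
    for (g in seq_len(G)) {
      apl[g, k] <- nb_apl_one(counts[g, ], design, offsets, phi_grid[k])
    }
  }
  total <- colSums(apl)
  best <- which.max(total)
  lo <- phi_grid[max(1, best - 1)]
  hi <- phi_grid[min(length(phi_grid), best + 1)]
  fsum <- function(phi) {
    sum(vapply(seq_len(G),
               function(g) nb_apl_one(counts[g, ], design, offsets, phi),
               numeric(1)))
  }
  common <- golden_max(fsum, lo, hi, tol = 1e-3)
  df_res <- length(offsets) - ncol(design)
  tag_grid <- phi_grid[apply(apl, 1, which.max)]
  w <- df_res / (df_res + prior_df)
  tagwise <- exp(w * log(tag_grid) + (1 - w) * log(common))
  names(tagwise) <- rownames(counts)
  list(common = common, tagwise = tagwise, prior_df = prior_df)
}

# Golden-section maximization on [lo, hi] (log scale).
golden_max <- function(f, lo, hi, tol = 1e-3) {
  a <- log(lo); b <- log(hi)
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    }
  }
  exp((a + b) / 2)
}

#' Fit per-miR negative-binomial GLMs
#'
#' One NB log-link GLM per miR via IRLS, with sample offsets (log effective
#' library sizes) and a fixed dispersion. All-zero rows get zero fitted
#' values and NA coefficients; non-converged fits are flagged and excluded
#' from testing with a warning.
#'
#' @inheritParams estimate_dispersions
#' @param dispersion scalar or per-miR numeric dispersion.
#' @return `nb_fit` object: coefficients (miR x coefficient), fitted means,
#'   residual deviances, residual df, convergence flags, plus the inputs
#'   needed to refit reduced models for testing.
#' @export
fit_nb_glm <- function(counts, design, offsets, dispersion) {
  counts <- as.matrix(counts)
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  G <- nrow(counts)
  phi <- rep_len(dispersion, G)
  coefs <- matrix(NA_real_, G, ncol(design),
                  dimnames = list(rownames(counts), colnames(design)))
  fitted <- matrix(0, G, ncol(counts),
                   dimnames = dimnames(counts))
  dev <- numeric(G)
  conv <- logical(G)
  zero <- logical(G)
  for (g in seq_len(G)) {
    fit <- nb_fit_one(counts[g, ], design, offsets, phi[g])
    coefs[g, ] <- fit$coefficients
    fitted[g, ] <- fit$fitted
    dev[g] <- fit$deviance
    conv[g] <- fit$converged
    zero[g] <- fit$all_zero
  }
  if (any(!conv)) {
    warning(sum(!conv), " miR fit(s) did not converge; excluded from testing")
  }
  structure(list(
    coefficients = coefs, fitted = fitted, deviance = dev,
    df_residual = ncol(counts) - ncol(design), converged = conv,
    all_zero = zero, counts = counts, design = design, offsets = offsets,
    dispersion = phi
  ), class = "nb_fit")
}

#' Quasi-likelihood F-test for one contrast
#'
#' Per-miR quasi-dispersion = residual deviance / residual df, squeezed
#' toward the mean quasi-dispersion with prior weight `prior_df`
#' (empirical-Bayes moderation). The F statistic is the deviance drop of
#' the contrast per contrast df over the squeezed quasi-dispersion, referred
#' to an F distribution with (contrast df, residual df + prior df).
#' Unadjusted p-values are reported (small-sample discovery stance); a
#' Benjamini-Hochberg column is available behind `add_fdr`.
#'
#' @param fit `nb_fit` object from [fit_nb_glm()].
#' @param coef coefficient name(s) (or indices) in the design to drop for
#'   the reduced model; a single coefficient gives its log2 fold change.
#' @param prior_df prior weight for quasi-dispersion squeezing (default 10).
#' @param add_fdr append a Benjamini-Hochberg `fdr` column.
#' @return data.frame (one row per tested miR): `mir_id`, `log2_fc`,
#'   `ave_log2_cpm`, `f_stat`, `p_value`.
#' @export
ql_f_test <- function(fit, coef, prior_df = 10, add_fdr = FALSE) {
  stopifnot(inherits(fit, "nb_fit"))
  if (fit$df_residual <= 0) {
    stop("residual df <= 0: design saturates the data, QL test undefined")
  }
  if (is.character(coef)) {
    idx <- match(coef, colnames(fit$design))
    if (anyNA(idx)) stop("unknown coefficient(s): ",
                         paste(coef[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(coef)
  }
  X0 <- fit$design[, -idx, drop = FALSE]
  G <- nrow(fit$counts)
  dev0 <- numeric(G)
  for (g in seq_len(G)) {
    f0 <- nb_fit_one(fit$counts[g, ], X0, fit$offsets, fit$dispersion[g])
    dev0[g] <- f0$deviance
  }
  testable <- fit$converged & !fit$all_zero
  df_test <- length(idx)
  df_res <- fit$df_residual
  s2 <- fit$deviance / df_res
  s2_mean <- mean(s2[testable])
  s2_post <- (prior_df * s2_mean + df_res * s2) / (prior_df + df_res)
  drop_dev <- pmax(dev0 - fit$deviance, 0)
  f_stat <- (drop_dev / df_test) / pmax(s2_post, 1e-10)
  p <- stats::pf(f_stat, df_test, df_res + prior_df, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  lib_eff <- exp(fit$offsets)
  avecpm <- log2(rowMeans(sweep(fit$counts, 2, 1e6 / lib_eff, `*`)) + 0.5)
  log2_fc <- if (df_test == 1) {
    fit$coefficients[, idx] / log(2)
  } else {
    rep(NA_real_, G)
  }
  out <- data.frame(
    mir_id = rownames(fit$counts),
    log2_fc = unname(log2_fc),
    ave_log2_cpm = unname(avecpm),
    f_stat = unname(f_stat),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
  out$f_stat[!testable] <- NA_real_
  out$p_value[!testable] <- NA_real_
  out$p_value[fit$all_zero] <- 1
  out$log2_fc[fit$all_zero] <- 0
  if (add_fdr) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# One complete DE run on a subset of samples: design, dispersion, fit, test.
# `dispersion` may be precomputed (common value from the full normalization
# context); NULL estimates it on the subset.
run_one_contrast <- function(x, factors, analysis, treatment = NULL,
                             compartment = NULL, treatments = NULL,
                             prior_df = 10, dispersion = NULL) {
  d <- build_design(x$samples, analysis = analysis, treatment = treatment,
                    compartment = compartment, treatments = treatments)
  counts <- x$counts[, d$sample_ids, drop = FALSE]
  offs <- norm_offsets(factors)[d$sample_ids]
  nz <- rowSums(counts) > 0
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersions(counts[nz, , drop = FALSE], d$design,
                                       offs, prior_df = prior_df)$common
  }
  fit <- fit_nb_glm(counts[nz, , drop = FALSE], d$design, offs,
                    dispersion = dispersion)
  tab <- ql_f_test(fit, d$coef, prior_df = prior_df)
  if (any(!nz)) {
    zero_tab <- data.frame(mir_id = rownames(counts)[!nz], log2_fc = 0,
                           ave_log2_cpm = -Inf, f_stat = NA_real_,
                           p_value = 1, stringsAsFactors = FALSE)
    tab <- rbind(tab, zero_tab)
    tab <- tab[match(rownames(counts), tab$mir_id), ]
    rownames(tab) <- NULL
  }
  tab
}

# Common dispersion for one normalization context (joint, MB-only or
# EV-only matrix), estimated under the saturated group-means design
# (subject blocks + one indicator per compartment:treatment cell).
context_dispersion <- function(x, factors, prior_df = 10) {
  grp <- droplevels(interaction(x$samples$compartment,
                                x$samples$treatment, drop = TRUE))
  subj <- factor(x$samples$subject)
  if (nlevels(grp) < 2) {
    design <- stats::model.matrix(~ subj)
  } else {
    design <- stats::model.matrix(~ subj + grp)
  }
  if (qr(design)$rank < ncol(design)) {
    design <- design[, seq_len(qr(design)$rank), drop = FALSE]
  }
  counts <- x$counts
  nz <- rowSums(counts) > 0
  offs <- norm_offsets(factors)[colnames(counts)]
  estimate_dispersions(counts[nz, , drop = FALSE], design, offs,
                       prior_df = prior_df)$common
}

#' Run the study's full set of differential-expression contrasts
#'
#' Dual-normalization orchestration: (a) for the within-treatment MB-vs-EV
#' contrasts, the joint matrix (both compartments) is filtered and
#' TMM-normalized once, then each treatment's paired contrast is tested;
#' (b) for the between-treatment contrasts, the MB-only and EV-only
#' matrices are filtered and TMM-normalized separately, then each treatment
#' pair is tested within its compartment. The three filtered id sets are
#' returned for the preferential-expression stage.
#'
#' @param x `mir_counts` with both compartments and all treatments.
#' @param cpm_threshold,min_samples low-expressor filter parameters.
#' @param prior_df QL prior df.
#' @param all_groups also run the all-treatments F-test per compartment.
#' @return list with `within_treatment` (one MB-vs-EV table per treatment),
#'   `between_treatment` (per compartment, one table per treatment pair,
#'   e.g. `CLFSvsCTL`), optional `all_groups` F tables, and `filtered_ids`
#'   (`joint`, `MB`, `EV` id sets that passed the filter).
#' @export
run_all_contrasts <- function(x, cpm_threshold = 0.5, min_samples = 2,
                              prior_df = 10, all_groups = FALSE) {
  stopifnot(inherits(x, "mir_counts"))
  trts <- treatment_levels(x$samples$treatment)
  # (a) joint normalization, MB vs EV within each treatment
  joint <- filter_low_expressors(x, cpm_threshold, min_samples)
  joint_nf <- tmm_factors(joint$kept)
  joint_disp <- context_dispersion(joint$kept, joint_nf,
                                   prior_df = prior_df)
  within <- list()
  for (trt in trts) {
    within[[trt]] <- run_one_contrast(
      joint$kept, joint_nf, "within_treatment_between_population",
      treatment = trt, prior_df = prior_df, dispersion = joint_disp)
  }
  # (b) per-compartment normalization, treatment pairs
  pairs <- list()
  if (length(trts) >= 2) {
    cmb <- utils::combn(seq_along(trts), 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) {
      c(trts[cmb[1, i]], trts[cmb[2, i]])
    })
  }
  between <- list()
  all_grp <- list()
  filtered_ids <- list(joint = rownames(joint$kept$counts))
  for (comp in c("MB", "EV")) {
    sub <- subset_mir_counts(
      x, sample_ids = x$samples$sample_id[x$samples$compartment == comp])
    flt <- filter_low_expressors(sub, cpm_threshold, min_samples)
    nf <- tmm_factors(flt$kept)
    filtered_ids[[comp]] <- rownames(flt$kept$counts)
    comp_disp <- context_dispersion(flt$kept, nf, prior_df = prior_df)
    tabs <- list()
    for (pr in pairs) {
      nm <- paste0(pr[2], "vs", pr[1])
      tabs[[nm]] <- run_one_contrast(
        flt$kept, nf, "between_treatment_within_population",
        compartment = comp, treatments = pr, prior_df = prior_df,
        dispersion = comp_disp)
    }
    between[[comp]] <- tabs
    if (all_groups && length(trts) >= 3) {
      d <- build_design(flt$kept$samples,
                        "between_treatment_within_population",
                        compartment = comp, treatments = trts)
      counts <- flt$kept$counts[, d$sample_ids, drop = FALSE]
      offs <- norm_offsets(nf)[d$sample_ids]
      disp <- estimate_dispersions(counts, d$design, offs,
                                   prior_df = prior_df)
      fit <- fit_nb_glm(counts, d$design, offs, dispersion = disp$common)
      all_grp[[comp]] <- ql_f_test(fit, d$coef, prior_df = prior_df)
    }
  }
  out <- list(within_treatment = within, between_treatment = between,
              filtered_ids = filtered_ids,
              norm = list(joint = joint_nf))
  if (all_groups) out$all_groups <- all_grp
  out
}
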