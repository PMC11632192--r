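# Linear mixed-effects analysis of the endpoint table: the study model
# response ~ day * treatment + isSiesta + (1 | participant), REML, with
# Wald inference and change-from-baseline contrasts per treatment arm.

#' Model design for endpoint analysis
#'
#' Fixed effects: day, treatment, isSiesta, and day x treatment; random
#' intercept per participant. The first `day_levels` entry is the baseline
#' reference, the first `treatment_levels` entry the reference arm.
#'
#' @param response endpoint column name in the study table.
#' @param day_levels,treatment_levels factor level orders (NULL: order of
#'   appearance with "baseline"/"placebo" promoted to reference when present).
#' @param fixed one-sided formula for the fixed effects (default the study
#'   model `~ day * treatment + isSiesta`); reduced models (e.g. omitting
#'   the day x treatment interaction) are used for model comparison.
#' @return a `model_design` object.
#' @export
model_design <- function(response, day_levels = NULL, treatment_levels = NULL,
                         fixed = ~ day * treatment + isSiesta) {
  structure(list(response = response, day_levels = day_levels,
                 treatment_levels = treatment_levels, fixed = fixed),
            class = "model_design")
}

prepare_model_frame <- function(table, design) {
  need <- c(design$response, "day", "treatment", "isSiesta", "participant")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("study table lacks columns: ", paste(miss, collapse = ", "))
  df <- table[stats::complete.cases(table[need]), need]
  promote <- function(x, levels, pref) {
    if (is.null(levels)) {
      levels <- unique(as.character(x))
      hit <- intersect(pref, levels)
      if (length(hit)) levels <- c(hit[1], setdiff(levels, hit[1]))
    }
    factor(as.character(x), levels = levels)
  }
  df$day <- promote(df$day, design$day_levels, "baseline")
  df$treatment <- promote(df$treatment, design$treatment_levels, "placebo")
  names(df)[1] <- ".response"
  df
}

#' Simulate an endpoint table directly from the mixed-model generative form
#'
#' Draws a long-format study table (participant x day x session) with a
#' Gaussian response following the analysis model itself:
#' `y = X beta + u_participant + e`. Complements [simulate_study()], which
#' generates endpoints through full session simulation: this generator is
#' the correctly specified case used for calibration checks of the fitting
#' code (type-I error, coverage, REML-vs-posterior agreement).
#'
#' @param n_per_arm participants per treatment arm.
#' @param beta named coefficients on the model-matrix scale (names as in
#'   `fit_lmm` estimates; unnamed terms default to 0).
#' @param sd_participant,sd_resid random-intercept and residual SDs.
#' @param days,treatments factor levels (first = reference).
#' @param session_times four session clock times.
#' @param seed integer seed.
#' @return data.frame with participant, treatment, day, session_time,
#'   isSiesta, cohort and `y`.
#' @export
simulate_endpoint_table <- function(n_per_arm = 6,
                                    beta = c("(Intercept)" = 0),
                                    sd_participant = 0.5, sd_resid = 1,
                                    days = c("baseline", "day1", "day7"),
                                    treatments = c("placebo", "active"),
                                    session_times = c("10:00", "12:00", "14:00", "16:00"),
                                    seed = 1L) {
  grid <- expand.grid(session_time = session_times, day = days,
                      participant_i = seq_len(n_per_arm), treatment = treatments,
                      stringsAsFactors = FALSE)
  grid$participant <- paste0(grid$treatment, "_", grid$participant_i)
  grid$isSiesta <- as.integer(grid$session_time == "14:00")
  grid$day <- factor(grid$day, levels = days)
  grid$treatment <- factor(grid$treatment, levels = treatments)
  X <- stats::model.matrix(~ day * treatment + isSiesta, grid)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(beta), names(b))
  if (length(unknown)) stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  b[names(beta)] <- beta
  with_seed(seed, {
    u <- stats::rnorm(length(unique(grid$participant)), 0, sd_participant)
    names(u) <- unique(grid$participant)
    grid$y <- drop(X %*% b) + u[grid$participant] +
      stats::rnorm(nrow(grid), 0, sd_resid)
  })
  grid$cohort <- as.character(grid$treatment)
  grid[c("participant", "cohort", "treatment", "day", "session_time", "isSiesta", "y")]
}

#' Fit the study's linear mixed-effects model
#'
#' REML fit of `response ~ day * treatment + isSiesta + (1 | participant)`
#' via lme4. Rank deficiency of the fixed-effects design is an error naming
#' the aliased columns; non-convergence is flagged, never silent.
#'
#' @param table endpoint table (one row per participant x day x session),
#'   e.g. from [compile_endpoints()].
#' @param design a [model_design()].
#' @return an `lmm_fit`: `estimates` (data.frame term/estimate/se/z/p),
#'   `vcov`, `sigma_participant`, `sigma_resid`, `logLik`, `converged`,
#'   `n_obs`, `n_participants`, and the underlying `merMod` as `model`.
#' @export
fit_lmm <- function(table, design) {
  stopifnot(inherits(design, "model_design"))
  df <- prepare_model_frame(table, design)
  tab <- table(df$participant)
  if (sum(tab >= 2) < 2) stop("need >= 2 participants with >= 2 observations")
  X <- stats::model.matrix(design$fixed, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effects design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  form <- stats::as.formula(paste(".response ~",
                                  paste(deparse(design$fixed[[2]]), collapse = ""),
                                  "+ (1 | participant)"))
  fit <- suppressMessages(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    estimates = data.frame(term = names(beta), estimate = unname(beta),
                           se = unname(se), z = unname(z),
                           p = 2 * stats::pnorm(-abs(unname(z)))),
    vcov = V,
    sigma_participant = vc$sdcor[vc$grp == "participant"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(fit)),
    converged = converged,
    n_obs = nrow(df), n_participants = length(unique(df$participant)),
    data = df, model = fit), class = "lmm_fit")
}

#' Joint Wald test of a set of fixed-effect terms
#'
#' Chi-square test that all coefficients whose names match `pattern` are
#' zero (normal approximation to the REML sampling distribution).
#'
#' @param fit an `lmm_fit`.
#' @param pattern regular expression selecting coefficient names (default:
#'   the day x treatment interaction terms).
#' @return list `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, pattern = ":") {
  stopifnot(inherits(fit, "lmm_fit"))
  idx <- grep(pattern, fit$estimates$term)
  if (!length(idx)) stop("no coefficients match pattern: ", pattern)
  b <- fit$estimates$estimate[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(idx),
       p = stats::pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Change-from-baseline contrasts per treatment arm
#'
#' For each treatment arm and each post-baseline day, estimates the within-
#' arm difference (day d) - (baseline) as a linear combination of fixed
#' effects, with Wald SE, z and two-sided p. The cell-weight representation
#' of each contrast (+1 on the target day, -1 on baseline, within-arm) is
#' emitted for auditability; its weights sum to zero over the day factor.
#'
#' @param fit an `lmm_fit` from [fit_lmm()].
#' @return data.frame with columns treatment, day, estimate, se, z, p, and a
#'   `contrasts` attribute holding the coefficient-space vectors (matrix).
#' @export
contrasts_change_from_baseline <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) warning("contrasts computed from a non-converged fit")
  terms <- fit$estimates$term
  days <- levels(fit$data$day); arms <- levels(fit$data$treatment)
  rows <- list(); L_all <- list()
  for (arm in arms) {
    for (d in days[-1]) {
      L <- stats::setNames(numeric(length(terms)), terms)
      main <- paste0("day", d)
      if (!main %in% terms) stop("day level absent from design: ", d)
      L[main] <- 1
      if (arm != arms[1]) {
        inter <- paste0("day", d, ":treatment", arm)
        if (!inter %in% terms) stop("interaction term absent from design: ", inter)
        L[inter] <- 1
      }
      est <- sum(L * fit$estimates$estimate)
      se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
      z <- est / se
      key <- paste(arm, d, sep = ".")
      rows[[key]] <- data.frame(treatment = arm, day = d, estimate = est,
                                se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
      L_all[[key]] <- L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "contrasts") <- do.call(rbind, L_all)
  # cell-weight form: +1 target day, -1 baseline (sums to 0 over days)
  cells <- do.call(rbind, lapply(strsplit(names(L_all), ".", fixed = TRUE),
                                 function(p) {
    w <- stats::setNames(numeric(length(days)), days)
    w[p[2]] <- 1; w[days[1]] <- -1
    w
  }))
  rownames(cells) <- names(L_all)
  attr(out, "cell_weights") <- cells
  out
}
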