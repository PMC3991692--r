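#' Validate a repeated-measurements table
#'
#' Long-format table of repeated LC measurements: columns `subject_id`,
#' `eye_id`, `group`, `replicate` (1 or 2), `parameter`, `value`. Eyes are
#' nested in subjects and every (subject, eye, parameter) must appear with
#' exactly two replicates.
#'
#' @param table a data frame with the columns above.
#' @param parameter optional parameter name to restrict the check to.
#' @return The (subsetted) table, invisibly validated.
#' @export
validate_repeated_table <- function(table, parameter = NULL) {
  need <- c("subject_id", "eye_id", "group", "replicate", "parameter", "value")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("repeated table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(parameter)) table <- table[table$parameter == parameter, ]
  if (!all(table$replicate %in% c(1L, 2L)))
    stop("replicate must be 1 or 2")
  key <- interaction(table$subject_id, table$eye_id, table$parameter, drop = TRUE)
  counts <- tapply(table$replicate, key, function(r) {
    length(r) == 2L && all(sort(r) == c(1L, 2L))
  })
  if (!all(counts)) {
    bad <- names(counts)[!counts]
    stop("eyes without exactly replicates {1, 2}: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  table
}

# wide per-eye view: one row per eye with both replicate values
eye_pairs <- function(table) {
  w <- stats::reshape(
    table[, c("subject_id", "eye_id", "group", "replicate", "value")],
    idvar = c("subject_id", "eye_id", "group"),
    timevar = "replicate", direction = "wide")
  names(w)[names(w) == "value.1"] <- "v1"
  names(w)[names(w) == "value.2"] <- "v2"
  w$diff <- w$v1 - w$v2
  w
}

# method-of-moments fallback: residual variance = within-eye mean square
moments_components <- function(w) {
  n_eyes <- nrow(w)
  resid_var <- sum(w$diff^2) / (2 * n_eyes)
  eye_means <- (w$v1 + w$v2) / 2
  subj_means <- tapply(eye_means, w$subject_id, mean)
  eyes_per_subj <- tapply(eye_means, w$subject_id, length)
  # between-eye-within-subject and between-subject components (ANOVA-style,
  # truncated at zero); approximate under unbalanced eye counts
  if (any(eyes_per_subj > 1)) {
    dev <- eye_means - subj_means[as.character(w$subject_id)]
    ms_eye <- sum(dev^2) / max(1, sum(eyes_per_subj - 1))
    eye_var <- max(0, ms_eye - resid_var / 2)
  } else eye_var <- 0
  subj_var <- max(0, var(as.numeric(subj_means)) - eye_var - resid_var / 2)
  c(subject = subj_var, eye = eye_var, residual = resid_var)
}

#' Fit the repeated-scan measurement-error model
#'
#' Estimates the imprecision SD (the typical random error between repeated
#' scans of the same eye) for one parameter from a repeated-measurements
#' table. Because the same method analyses both scans, the method bias is
#' fixed at 1 and the measurement-error model reduces to a nested
#' random-effects decomposition
#' \deqn{y = \mu + subject + eye(subject) + \epsilon,}
#' fitted by REML ([lme4::lmer()]); the imprecision SD is the residual SD.
#' Accounting for the eye-within-subject level keeps between-eye anatomical
#' variation out of the error term when some subjects contribute both eyes.
#' If REML fails, ANOVA-style method-of-moments components (negative
#' components truncated to zero) are used and flagged.
#'
#' @param table a repeated-measurements data frame
#'   (see [validate_repeated_table()]).
#' @param parameter_name which parameter to fit.
#' @return An object of class `lc_imprecision` with fields `parameter`,
#'   `mean_value`, `imprecision_sd`, `relative_imprecision` (percent),
#'   `variance_components` (subject, eye-within-subject, residual),
#'   `n_eyes`, `n_subjects`, `method` ("reml", "moments" or "exact-zero"),
#'   and the per-eye pairs used (for resampling).
#' @export
fit_measurement_error_model <- function(table, parameter_name) {
  table <- validate_repeated_table(table, parameter_name)
  if (!nrow(table)) stop("no rows for parameter ", parameter_name)
  w <- eye_pairs(table)
  if (nrow(w) < 3) stop("need at least 3 eyes with 2 replicates each")
  mean_value <- mean(c(w$v1, w$v2))

  if (all(w$diff == 0)) {
    # replicates are exact duplicates: zero measurement error by definition
    vc <- c(subject = NA_real_, eye = NA_real_, residual = 0)
    return(new_imprecision(parameter_name, mean_value, 0, vc, w, "exact-zero"))
  }

  # the eye-within-subject level is identifiable only when some subject
  # contributes both eyes; otherwise it coincides with the subject level and
  # is dropped (keeping it would only add a flat likelihood ridge)
  eyes_per_subject <- tapply(w$eye_id, w$subject_id, length)
  has_eye_level <- any(eyes_per_subject > 1)
  ctl <- lme4::lmerControl(optimizer = "bobyqa",
                           check.conv.singular = "ignore",
                           optCtrl = list(rhoend = 1e-12))
  fit <- tryCatch({
    d <- table
    d$eye_uid <- interaction(d$subject_id, d$eye_id, drop = TRUE)
    suppressMessages(suppressWarnings(
      if (has_eye_level)
        lme4::lmer(value ~ 1 + (1 | subject_id) + (1 | eye_uid), data = d,
                   REML = TRUE, control = ctl)
      else
        lme4::lmer(value ~ 1 + (1 | subject_id), data = d,
                   REML = TRUE, control = ctl)))
  }, error = function(e) NULL)

  if (is.null(fit)) {
    warning("REML fit failed; falling back to method-of-moments components")
    vc <- moments_components(w)
    return(new_imprecision(parameter_name, mean_value, sqrt(vc["residual"]),
                           vc, w, "moments"))
  }
  vcd <- as.data.frame(lme4::VarCorr(fit))
  resid_var <- vcd$vcov[vcd$grp == "Residual"]
  subj_var <- vcd$vcov[vcd$grp == "subject_id"]
  eye_var <- if (has_eye_level) vcd$vcov[vcd$grp == "eye_uid"] else NA_real_
  vc <- c(subject = subj_var, eye = eye_var, residual = resid_var)
  new_imprecision(parameter_name, mean_value, sqrt(resid_var), vc, w, "reml")
}

new_imprecision <- function(parameter, mean_value, sd, vc, pairs, method) {
  structure(list(
    parameter = parameter,
    mean_value = mean_value,
    imprecision_sd = unname(sd),
    relative_imprecision = if (mean_value != 0) 100 * unname(sd) / abs(mean_value) else NA_real_,
    variance_components = vc,
    n_eyes = nrow(pairs),
    n_subjects = length(unique(pairs$subject_id)),
    method = method,
    pairs = pairs,
    flag_small = FALSE), class = "lc_imprecision")
}

#' @method print lc_imprecision
#' @export
print.lc_imprecision <- function(x, ...) {
  cat(sprintf("imprecision of %s: SD %.4g (relative %.2f%%), mean %.4g; %d eyes / %d subjects [%s]%s\n",
              x$parameter, x$imprecision_sd, x$relative_imprecision,
              x$mean_value, x$n_eyes, x$n_subjects, x$method,
              if (isTRUE(x$flag_small)) " (small group)" else ""))
  invisible(x)
}

#' Relative imprecision
#'
#' The imprecision SD divided by the measurement's average, in percent.
#'
#' @param est an [fit_measurement_error_model()] result, or a numeric
#'   imprecision SD (then `mean_value` must be given).
#' @param mean_value the measurement average (ignored when `est` is a fitted
#'   object).
#' @return Percent relative imprecision.
#' @examples
#' relative_imprecision(1.0, 48.8)  # 2.0 (%)
#' @export
relative_imprecision <- function(est, mean_value = NULL) {
  if (inherits(est, "lc_imprecision")) {
    sd <- est$imprecision_sd
    mean_value <- est$mean_value
  } else sd <- est
  if (is.null(mean_value) || mean_value == 0)
    stop("mean value must be nonzero")
  100 * sd / abs(mean_value)
}

#' Per-group imprecision estimates
#'
#' Fits the measurement-error model independently within each group label
#' (e.g. diagnostic category). Groups with fewer than `min_eyes` eyes are
#' still fitted when possible but flagged.
#'
#' @param table a repeated-measurements data frame.
#' @param parameter_name which parameter to fit.
#' @param min_eyes smallest group size considered reliable.
#' @return A named list of `lc_imprecision` objects, one per group.
#' @export
imprecision_by_group <- function(table, parameter_name, min_eyes = 4L) {
  need <- c("subject_id", "eye_id", "group", "replicate", "parameter", "value")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("repeated table lacks columns: ", paste(missing_cols, collapse = ", "))
  # validation happens per group (the same subject label in two groups is
  # treated as two different subjects by the nested model)
  groups <- unique(as.character(table$group))
  out <- lapply(groups, function(g) {
    sub <- table[table$group == g, ]
    est <- fit_measurement_error_model(sub, parameter_name)
    if (est$n_eyes < min_eyes) est$flag_small <- TRUE
    est
  })
  names(out) <- groups
  out
}

#' Compare imprecision between two groups
#'
#' Ratio of residual (imprecision) variances of two fitted groups with a
#' seeded bootstrap confidence interval obtained by resampling eyes (with
#' their replicate pairs) within each group. Inside the bootstrap the residual
#' variance is recomputed with its balanced two-replicate closed form
#' (sum of squared scan differences / 2n), the same estimand the REML fit
#' targets in this design.
#'
#' @param est_a,est_b `lc_imprecision` objects.
#' @param draws bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return List with `ratio` (variance ratio a/b), `conf_int`, `draws`.
#' @export
compare_group_imprecision <- function(est_a, est_b, draws = 1000L, seed = 1L,
                                      conf = 0.95) {
  stopifnot(inherits(est_a, "lc_imprecision"), inherits(est_b, "lc_imprecision"))
  va <- est_a$variance_components["residual"]
  vb <- est_b$variance_components["residual"]
  if (!is.finite(vb) || vb <= 0) stop("denominator group has zero residual variance")
  ratio <- unname(va / vb)
  da <- est_a$pairs$diff
  db <- est_b$pairs$diff
  boot_var <- function(d) {
    i <- sample.int(length(d), replace = TRUE)
    sum(d[i]^2) / (2 * length(d))
  }
  stat <- with_seed(seed, vapply(seq_len(draws), function(j) {
    boot_var(da) / max(boot_var(db), .Machine$double.eps)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(ratio = ratio,
       conf_int = unname(quantile(stat, c(alpha, 1 - alpha))),
       draws = stat)
}

#' Simulate a nested repeated-measurements table
#'
#' Generates a long-format table from the nested model
#' `value = mean + subject + eye(subject) + error`, with two replicates per
#' eye and a configurable number of subjects contributing both eyes. Used to
#' validate the imprecision estimator by parameter recovery.
#'
#' @param n_subjects number of subjects.
#' @param n_two_eyed how many subjects contribute both eyes.
#' @param subject_sd,eye_sd,residual_sd standard deviations of the model
#'   components (units of the measured parameter).
#' @param grand_mean overall mean.
#' @param parameter parameter name written into the table.
#' @param group group label written into the table.
#' @param seed integer seed.
#' @return A repeated-measurements data frame.
#' @export
simulate_repeated_table <- function(n_subjects = 40L, n_two_eyed = 15L,
                                    subject_sd = 2, eye_sd = 1,
                                    residual_sd = 0.5, grand_mean = 24.2,
                                    parameter = "pore_diameter_mean",
                                    group = "all", seed = 1L) {
  stopifnot(n_two_eyed <= n_subjects)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      s_eff <- rnorm(1, 0, subject_sd)
      eyes <- if (s <= n_two_eyed) c("OD", "OS") else "OD"
      for (e in eyes) {
        e_eff <- rnorm(1, 0, eye_sd)
        v <- grand_mean + s_eff + e_eff + rnorm(2, 0, residual_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", s), eye_id = e, group = group,
          replicate = 1:2, parameter = parameter, value = v)
      }
    }
    do.call(rbind, rows)
  })
}
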