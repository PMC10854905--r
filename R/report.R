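# Demographic and per-eye comparison reports for a paired case-control
# cohort, with gated test selection and the two adjusted logistic models.

.eye_var_names <- c(
  "iop_mmhg", "ica_c6_mm", "oa_mm", "onsasw_3_mm", "onsasw_9_mm",
  "onsasw_15_mm", "rel_art_caliber", "rel_ven_caliber", "avr",
  "angle_sn_artery_deg", "angle_sn_vein_deg", "angle_in_artery_deg",
  "angle_in_vein_deg", "angle_st_artery_deg", "angle_st_vein_deg",
  "angle_it_artery_deg", "angle_it_vein_deg")

#' Build the case-control comparison report
#'
#' Produces (1) a demographics table comparing the two groups on
#' subject-level variables (t, chi-square or Mann-Whitney chosen by the
#' normality gate), (2) a per-eye table with the four group-by-role means
#' +/- SD, paired affected-vs-contralateral tests within each group, and
#' independent between-group tests per eye role, each footnoted with the
#' gate's choice, and (3) two adjusted logistic models: CRVO-affected vs
#' BRVO-affected (markers adjusted for age, hypertension duration, BMI and
#' IOP) and CRVO-affected vs CRVO-contralateral (calibers adjusted for
#' IOP).
#'
#' @param cohort a [generate_cohort()]-shaped data.frame (one row per
#'   eye; one affected + one contralateral row per subject).
#' @param eye_vars eye-level variable names to compare.
#' @param alpha significance level used in the printed flags.
#' @return list of class `comparison_report`: `demographics`, `per_eye`,
#'   `model_affected_vs_affected`, `model_crvo_affected_vs_contralateral`.
#' @export
build_comparison_report <- function(cohort, eye_vars = .eye_var_names,
                                    alpha = 0.05) {
  needed <- c("subject", "group", "eye_role", "age_y", "sex", "bmi",
              "hbp_duration_y", eye_vars)
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(cohort)
  groups <- sort(unique(cohort$group))
  stopifnot(length(groups) == 2)
  g1 <- groups[1]; g2 <- groups[2]

  subj <- cohort[cohort$eye_role == "affected", ]  # one row per subject

  demo_row <- function(var, label) {
    x <- subj[[var]][subj$group == g1]
    y <- subj[[var]][subj$group == g2]
    gate <- normality_and_variance_gate(x, y)
    res <- two_group_continuous(x, y, gate = gate)
    data.frame(variable = label,
               mean_g1 = mean(x), sd_g1 = stats::sd(x),
               mean_g2 = mean(y), sd_g2 = stats::sd(y),
               test = res$test, statistic = res$statistic,
               p = res$p_value)
  }
  sex_tab <- table(factor(subj$group, levels = groups),
                   factor(subj$sex, levels = c("male", "female")))
  sex_res <- chi_square_2x2(sex_tab[1, 1], sex_tab[1, 2],
                            sex_tab[2, 1], sex_tab[2, 2])
  demographics <- rbind(
    demo_row("age_y", "age (y)"),
    data.frame(variable = "sex (male/female)",
               mean_g1 = sex_tab[1, 1], sd_g1 = sex_tab[1, 2],
               mean_g2 = sex_tab[2, 1], sd_g2 = sex_tab[2, 2],
               test = sex_res$test, statistic = sex_res$statistic,
               p = sex_res$p_value),
    demo_row("height_m", "height (m)"),
    demo_row("weight_kg", "weight (kg)"),
    demo_row("bmi", "BMI (kg/m2)"),
    demo_row("hbp_duration_y", "duration of hypertension (y)")
  )

  cells <- expand.grid(group = groups, eye_role = c("affected", "contralateral"),
                       stringsAsFactors = FALSE)
  per_eye <- do.call(rbind, lapply(eye_vars, function(var) {
    row <- data.frame(variable = var)
    for (i in seq_len(nrow(cells))) {
      v <- cohort[[var]][cohort$group == cells$group[i] &
                           cohort$eye_role == cells$eye_role[i]]
      row[[paste0("mean_", cells$group[i], "_", substr(cells$eye_role[i], 1, 3))]] <- mean(v)
      row[[paste0("sd_", cells$group[i], "_", substr(cells$eye_role[i], 1, 3))]] <- stats::sd(v)
    }
    for (g in groups) {
      sub <- cohort[cohort$group == g, ]
      sub <- sub[order(sub$subject, sub$eye_role), ]
      aff <- sub[[var]][sub$eye_role == "affected"]
      con <- sub[[var]][sub$eye_role == "contralateral"]
      res <- two_group_continuous(aff, con, paired = TRUE)
      row[[paste0("paired_", g, "_test")]] <- res$test
      row[[paste0("paired_", g, "_p")]] <- res$p_value
    }
    for (role in c("affected", "contralateral")) {
      x <- cohort[[var]][cohort$group == g1 & cohort$eye_role == role]
      y <- cohort[[var]][cohort$group == g2 & cohort$eye_role == role]
      res <- two_group_continuous(x, y)
      row[[paste0("between_", substr(role, 1, 3), "_test")]] <- res$test
      row[[paste0("between_", substr(role, 1, 3), "_p")]] <- res$p_value
    }
    row
  }))

  # logistic model (a): CRVO-affected vs BRVO-affected eyes, imaging
  # markers adjusted for age, hypertension duration, BMI, IOP
  aff <- cohort[cohort$eye_role == "affected", ]
  crvo_name <- if ("CRVO" %in% groups) "CRVO" else g2
  out_a <- as.integer(aff$group == crvo_name)
  # dimensionless calibers are entered per 0.01 increment so the reported
  # odds ratios live on an interpretable scale
  cov_a <- data.frame(onsasw_3_mm = aff$onsasw_3_mm,
                      rel_art_per_0.01 = 100 * aff$rel_art_caliber,
                      rel_ven_per_0.01 = 100 * aff$rel_ven_caliber)
  mod_a <- logistic_regression(
    out_a, cov_a,
    adjust_for = aff[, c("age_y", "hbp_duration_y", "bmi", "iop_mmhg")])

  # logistic model (b): CRVO affected vs contralateral eyes, calibers
  # adjusted for IOP
  crvo <- cohort[cohort$group == crvo_name, ]
  out_b <- as.integer(crvo$eye_role == "affected")
  cov_b <- data.frame(rel_art_per_0.01 = 100 * crvo$rel_art_caliber,
                      rel_ven_per_0.01 = 100 * crvo$rel_ven_caliber)
  mod_b <- logistic_regression(
    out_b, cov_b,
    adjust_for = crvo[, "iop_mmhg", drop = FALSE])

  structure(list(demographics = demographics, per_eye = per_eye,
                 model_affected_vs_affected = mod_a,
                 model_crvo_affected_vs_contralateral = mod_b,
                 groups = groups, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Demographics (", x$groups[1], " vs ", x$groups[2], ") ==\n", sep = "")
  print(format(x$demographics, digits = 3), row.names = FALSE)
  cat("\n== Per-eye comparisons ==\n")
  show <- x$per_eye[, c("variable", grep("^mean_|_p$", names(x$per_eye),
                                         value = TRUE))]
  print(format(show, digits = 3), row.names = FALSE)
  cat("\n== Adjusted logistic models ==\n")
  cat("(a) CRVO-affected vs BRVO-affected:\n")
  print(x$model_affected_vs_affected)
  cat("(b) CRVO affected vs contralateral:\n")
  print(x$model_crvo_affected_vs_contralateral)
  invisible(x)
}
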