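# Simulated case-control cohorts: one affected and one contralateral
# normal eye per subject, in two groups (BRVO: branch retinal vein
# occlusion; CRVO: central).  Default means and SDs are the published
# group summaries of the study population this package models, so the
# default cohort reproduces that study's effect sizes.

# eye-level default cells: list of c(BRVO-affected, BRVO-contralateral,
# CRVO-affected, CRVO-contralateral) means and sds
.eye_defaults <- list(
  iop_mmhg = list(mean = c(16.39, 16.11, 19.58, 15.92),
                  sd = c(3.00, 3.79, 8.84, 1.74)),
  ica_c6_mm = list(mean = c(4.07, 4.03, 3.98, 3.91),
                   sd = c(0.61, 0.51, 0.50, 0.50)),
  oa_mm = list(mean = c(3.23, 3.22, 3.40, 3.47),
               sd = c(0.43, 0.46, 0.41, 0.28)),
  onsasw_3_mm = list(mean = c(1.01, 0.99, 1.16, 1.01),
                     sd = c(0.21, 0.34, 0.19, 0.16)),
  onsasw_9_mm = list(mean = c(0.86, 0.82, 1.01, 0.88),
                     sd = c(0.15, 0.12, 0.21, 0.14)),
  onsasw_15_mm = list(mean = c(0.79, 0.78, 0.84, 0.81),
                      sd = c(0.12, 0.13, 0.10, 0.09)),
  rel_art_caliber = list(mean = c(0.057, 0.058, 0.059, 0.062),
                         sd = c(0.010, 0.010, 0.015, 0.009)),
  rel_ven_caliber = list(mean = c(0.076, 0.077, 0.095, 0.077),
                         sd = c(0.009, 0.010, 0.015, 0.011)),
  angle_sn_artery_deg = list(mean = c(62.406, 63.482, 48.994, 62.583),
                             sd = c(14.605, 16.364, 12.865, 24.240)),
  angle_sn_vein_deg = list(mean = c(66.999, 61.722, 55.403, 61.500),
                           sd = c(19.078, 18.242, 20.259, 18.108)),
  angle_in_artery_deg = list(mean = c(64.673, 65.773, 53.089, 59.049),
                             sd = c(19.888, 16.094, 16.113, 14.238)),
  angle_in_vein_deg = list(mean = c(67.788, 65.380, 59.778, 69.518),
                           sd = c(16.344, 20.733, 19.382, 14.393)),
  angle_st_artery_deg = list(mean = c(68.421, 71.354, 56.155, 65.832),
                             sd = c(18.789, 11.650, 16.306, 14.445)),
  angle_st_vein_deg = list(mean = c(66.719, 67.096, 66.907, 64.552),
                           sd = c(15.836, 16.945, 23.359, 17.940)),
  angle_it_artery_deg = list(mean = c(78.268, 74.581, 57.872, 80.617),
                             sd = c(25.170, 17.619, 22.942, 21.042)),
  angle_it_vein_deg = list(mean = c(72.225, 74.826, 67.992, 66.566),
                           sd = c(21.063, 16.625, 23.633, 17.837))
)

.subject_defaults <- list(
  n_subjects = c(BRVO = 34L, CRVO = 25L),
  age_y = list(mean = c(53, 50), sd = c(10, 15)),
  male_fraction = c(18 / 34, 16 / 25),
  height_m = list(mean = c(1.65, 1.66), sd = c(0.06, 0.08)),
  weight_kg = list(mean = c(71.12, 71.43), sd = c(9.43, 9.27)),
  # duration of hypertension: zero-inflated log-normal chosen to match the
  # published medians/IQRs (BRVO median 0, 75th pct 4.5 y; CRVO median and
  # 75th pct both 0)
  hbp_zero_fraction = c(0.5, 0.8),
  hbp_meanlog = c(log(4.5), log(2)),
  hbp_sdlog = c(1, 1)
)

#' Specification for a simulated case-control cohort
#'
#' Defaults are the published group summaries (means +/- SDs, counts) of
#' the BRVO/CRVO case-control population: two eyes per subject, the
#' affected eye and the contralateral normal eye.  Numeric columns are
#' drawn from per-cell normal distributions truncated at 0 (hypertension
#' duration from a zero-inflated log-normal); eyes are exchangeable within
#' subject apart from the affected-eye effect (no inter-eye correlation is
#' modeled).
#'
#' @param n_subjects named vector c(BRVO=, CRVO=).
#' @param effects TRUE (default) keeps the per-cell published means;
#'   FALSE collapses every variable to its BRVO-contralateral cell, giving
#'   a global null cohort.
#' @param eye_vars,subject_vars optional overrides of the default
#'   parameter lists (same structure as the defaults).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(BRVO = 34L, CRVO = 25L),
                        effects = TRUE, eye_vars = NULL,
                        subject_vars = NULL, seed = 1L) {
  ev <- if (is.null(eye_vars)) .eye_defaults else eye_vars
  sv <- if (is.null(subject_vars)) .subject_defaults else subject_vars
  check_that(all(n_subjects >= 1), "n_subjects", "must be >= 1")
  for (nm in names(ev)) {
    check_that(all(ev[[nm]]$sd >= 0), paste0("eye_vars$", nm),
               "SDs must be >= 0")
  }
  if (!effects) {
    ev <- lapply(ev, function(v) list(mean = rep(v$mean[2], 4),
                                      sd = rep(v$sd[2], 4)))
    sv$age_y <- list(mean = rep(sv$age_y$mean[1], 2),
                     sd = rep(sv$age_y$sd[1], 2))
    sv$male_fraction <- rep(sv$male_fraction[1], 2)
    sv$height_m <- list(mean = rep(sv$height_m$mean[1], 2),
                        sd = rep(sv$height_m$sd[1], 2))
    sv$weight_kg <- list(mean = rep(sv$weight_kg$mean[1], 2),
                         sd = rep(sv$weight_kg$sd[1], 2))
    sv$hbp_zero_fraction <- rep(sv$hbp_zero_fraction[1], 2)
    sv$hbp_meanlog <- rep(sv$hbp_meanlog[1], 2)
    sv$hbp_sdlog <- rep(sv$hbp_sdlog[1], 2)
  }
  structure(list(n_subjects = n_subjects, effects = effects,
                 eye_vars = ev, subject_vars = sv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a simulated cohort
#'
#' Two rows (eyes) per subject.  The arteriolar-to-venular ratio `avr` is
#' computed per eye as `rel_art_caliber / rel_ven_caliber`, and BMI as
#' weight / height^2, so the defining identities hold exactly in every
#' simulated record.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `cohort_table`, one row per eye.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    sv <- spec$subject_vars
    groups <- names(spec$n_subjects)
    subj <- list()
    offset <- 0L
    for (gi in seq_along(groups)) {
      n <- as.integer(spec$n_subjects[gi])
      subj[[gi]] <- data.frame(
        subject = offset + seq_len(n),
        group = groups[gi],
        age_y = pmax(18, stats::rnorm(n, sv$age_y$mean[gi], sv$age_y$sd[gi])),
        sex = ifelse(stats::runif(n) < sv$male_fraction[gi], "male", "female"),
        height_m = pmax(1.3, stats::rnorm(n, sv$height_m$mean[gi],
                                          sv$height_m$sd[gi])),
        weight_kg = pmax(35, stats::rnorm(n, sv$weight_kg$mean[gi],
                                          sv$weight_kg$sd[gi])),
        hbp_duration_y = ifelse(
          stats::runif(n) < sv$hbp_zero_fraction[gi], 0,
          stats::rlnorm(n, sv$hbp_meanlog[gi], sv$hbp_sdlog[gi])),
        lat_aff = ifelse(stats::runif(n) < 0.5, "OD", "OS")
      )
      offset <- offset + n
    }
    subj <- do.call(rbind, subj)
    subj$bmi <- subj$weight_kg / subj$height_m^2

    # expand to eyes: affected then contralateral per subject
    eyes <- subj[rep(seq_len(nrow(subj)), each = 2), ]
    eyes$eye_role <- rep(c("affected", "contralateral"), nrow(subj))
    eyes$laterality <- ifelse(eyes$eye_role == "affected", eyes$lat_aff,
                              ifelse(eyes$lat_aff == "OD", "OS", "OD"))
    eyes$lat_aff <- NULL
    cell <- match(eyes$group, groups) * 2L - 2L +
      ifelse(eyes$eye_role == "affected", 1L, 2L)
    for (nm in names(spec$eye_vars)) {
      v <- spec$eye_vars[[nm]]
      eyes[[nm]] <- pmax(0, stats::rnorm(nrow(eyes), v$mean[cell], v$sd[cell]))
    }
    eyes$avr <- eyes$rel_art_caliber / eyes$rel_ven_caliber
    rownames(eyes) <- NULL
    first <- c("subject", "group", "eye_role", "laterality", "age_y", "sex",
               "height_m", "weight_kg", "bmi", "hbp_duration_y")
    eyes <- eyes[, c(first, setdiff(names(eyes), first))]
    class(eyes) <- c("cohort_table", class(eyes))
    eyes
  })
}

#' Validate the paired structure of a cohort table
#'
#' @param cohort a `cohort_table` data.frame.
#' @return invisibly TRUE; stops when a subject does not have exactly one
#'   affected and one contralateral eye or spans two groups.
#' @export
validate_cohort <- function(cohort) {
  tab <- table(cohort$subject, cohort$eye_role)
  if (!all(dim(tab) == c(length(unique(cohort$subject)), 2)) ||
        !all(tab == 1)) {
    stop("cohort must have exactly one affected and one contralateral eye per subject",
         call. = FALSE)
  }
  gpers <- tapply(cohort$group, cohort$subject, function(g) length(unique(g)))
  if (any(gpers != 1)) {
    stop("group label must be constant within subject", call. = FALSE)
  }
  invisible(TRUE)
}
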