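#' Specification of a synthetic cohort
#'
#' Declares the generative model used to emulate a morphometry study without
#' clinical data. Each feature is
#' `baseline + sum(slope * covariate) + group_shift * noise_sd + subject_intercept + N(0, noise_sd)`,
#' where group shifts are expressed in residual-SD units so that classifier
#' difficulty is controlled by one effect-size knob.
#'
#' @param n_per_group named counts for NC, AD and FTD subjects.
#' @param sets feature-set blocks ([feature_set_spec()] list); defaults to the
#'   full 3449-feature layout.
#' @param effect_size group mean shift, residual-SD units, on affected features.
#' @param sparsity fraction of features carrying a group effect.
#' @param overlap Jaccard overlap between the AD and FTD affected-feature
#'   sets: disease maps share part of their support (both dementias atrophy
#'   overlapping regions) while retaining disease-specific features.
#' @param age_slope_volume mm^3 per year on volume features (negative:
#'   age-related atrophy).
#' @param age_slope_thickness mm per year on thickness features.
#' @param sex_effect_volume mm^3 added for males (head-size related).
#' @param icv_slope_volume mm^3 per mm^3 of intracranial volume.
#' @param fs_effect_thickness mm offset at 3T (scanner contrast bias).
#' @param noise_sd_volume,noise_sd_thickness residual SD in feature units.
#' @param subject_sd_frac SD of the per-subject random intercept as a
#'   fraction of the residual SD; shared by all scans of one subject so that
#'   subject-level fold splitting matters.
#' @param scans_per_subject visits per subject (>= 1).
#' @param seed integer; the generator is fully deterministic given the seed.
#' @param group_effect_maps optional 3 x D matrix (rows NC/AD/FTD, residual-SD
#'   units) overriding the sparsity/overlap-derived maps; used when a test
#'   needs a hand-placed effect.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(NC = 100, AD = 100, FTD = 100),
                        sets = default_feature_sets(),
                        effect_size = 2, sparsity = 0.1, overlap = 0.3,
                        age_slope_volume = -5, age_slope_thickness = -0.01,
                        sex_effect_volume = 30, icv_slope_volume = 1e-4,
                        fs_effect_thickness = 0.05,
                        noise_sd_volume = 25, noise_sd_thickness = 0.15,
                        subject_sd_frac = 0.5, scans_per_subject = 1L,
                        seed = 1L, group_effect_maps = NULL) {
  stopifnot(all(c("NC", "AD", "FTD") %in% names(n_per_group)),
            all(n_per_group >= 0), noise_sd_volume > 0, noise_sd_thickness > 0,
            sparsity >= 0, sparsity <= 1, scans_per_subject >= 1)
  blocks <- set_block_table(sets)
  D <- sum(blocks$dim)
  is_vol <- rep(blocks$feature_type == "volume", blocks$dim)
  scale_num <- rep(ifelse(blocks$scale == "ROI", 1000,
                          as.numeric(blocks$scale)), blocks$dim)
  baseline <- ifelse(is_vol, scale_num, 2.5)
  noise_sd <- ifelse(is_vol, noise_sd_volume, noise_sd_thickness)
  slopes <- list(
    age = ifelse(is_vol, age_slope_volume, age_slope_thickness),
    sexM = ifelse(is_vol, sex_effect_volume, 0.02),
    icv = ifelse(is_vol, icv_slope_volume, 1e-7),
    fs3T = ifelse(is_vol, 10, fs_effect_thickness)
  )
  # group effect maps, residual-SD units; derived deterministically from seed
  maps <- if (!is.null(group_effect_maps)) {
    stopifnot(is.matrix(group_effect_maps), nrow(group_effect_maps) == 3,
              ncol(group_effect_maps) == D)
    rownames(group_effect_maps) <- c("NC", "AD", "FTD")
    group_effect_maps
  } else local({
    set.seed(seed + 104729L)
    n_aff <- round(sparsity * D)
    ad <- sort(sample.int(D, n_aff))
    n_shared <- round(n_aff * 2 * overlap / (1 + overlap)) # |A∩F| for Jaccard
    shared <- if (n_shared > 0) sample(ad, min(n_shared, length(ad))) else integer(0)
    pool <- setdiff(seq_len(D), ad)
    own <- if (n_aff - length(shared) > 0)
      sample(pool, min(n_aff - length(shared), length(pool))) else integer(0)
    ftd <- sort(c(shared, own))
    m <- matrix(0, nrow = 3, ncol = D, dimnames = list(c("NC", "AD", "FTD"), NULL))
    m["AD", ad] <- -effect_size   # atrophy: negative shifts
    m["FTD", ftd] <- -effect_size
    m
  })
  structure(list(n_per_group = n_per_group, sets = sets, blocks = blocks,
                 D = D, baseline = baseline, noise_sd = noise_sd,
                 slopes = slopes, group_effect_maps = maps,
                 effect_size = effect_size, sparsity = sparsity,
                 overlap = overlap, subject_sd_frac = subject_sd_frac,
                 scans_per_subject = as.integer(scans_per_subject),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ground truth of a synthetic cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return list with the per-group effect maps (residual-SD units) and the
#'   indices of features carrying signal for each disease group.
#' @export
ground_truth <- function(spec) {
  m <- spec$group_effect_maps
  list(effect_maps = m,
       affected = list(AD = which(m["AD", ] != 0),
                       FTD = which(m["FTD", ] != 0)),
       noise_sd = spec$noise_sd)
}

#' Generate a synthetic cohort
#'
#' Samples subject covariates (age ~ N(70, 8^2) years clipped to 45-95,
#' ICV ~ N(1.5e6, 1.5e5^2) mm^3, sex and field strength Bernoulli(1/2), three
#' sites, two scanners) and raw features under the linear generative model of
#' [cohort_spec()]. Repeated scans of one subject share the subject's random
#' intercept and covariates (age advances 1 year per visit).
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` ([subject_records()]) and `table`
#'   (raw [feature_table()]).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  groups <- rep(c("NC", "AD", "FTD"),
                times = spec$n_per_group[c("NC", "AD", "FTD")])
  n_subj <- length(groups)
  subj_id <- sprintf("S%04d", seq_len(n_subj))
  age0 <- pmin(pmax(stats::rnorm(n_subj, 70, 8), 45), 95)
  sex <- sample(c("M", "F"), n_subj, replace = TRUE)
  icv <- stats::rnorm(n_subj, 1.5e6, 1.5e5)
  fs <- sample(c("1.5T", "3T"), n_subj, replace = TRUE)
  site <- sample(c("siteA", "siteB", "siteC"), n_subj, replace = TRUE)
  scanner <- sample(c("scanner1", "scanner2"), n_subj, replace = TRUE)
  subj_fx <- stats::rnorm(n_subj) # shared intercept, scaled per feature below

  k <- spec$scans_per_subject
  n_rows <- n_subj * k
  ridx <- rep(seq_len(n_subj), each = k)
  visit <- rep(seq_len(k), times = n_subj)
  age <- age0[ridx] + (visit - 1)

  D <- spec$D
  X <- matrix(rep(spec$baseline, each = n_rows), nrow = n_rows)
  X <- X + outer(age, spec$slopes$age)
  X <- X + outer(as.numeric(sex[ridx] == "M"), spec$slopes$sexM)
  X <- X + outer(icv[ridx] - 1.5e6, spec$slopes$icv)
  X <- X + outer(as.numeric(fs[ridx] == "3T"), spec$slopes$fs3T)
  shift <- spec$group_effect_maps[groups[ridx], , drop = FALSE]
  dimnames(shift) <- NULL
  X <- X + sweep(shift, 2, spec$noise_sd, `*`)
  X <- X + outer(subj_fx[ridx], spec$subject_sd_frac * spec$noise_sd)
  X <- X + matrix(stats::rnorm(n_rows * D), n_rows) *
    rep(spec$noise_sd, each = n_rows)

  records <- subject_records(
    subject_id = subj_id[ridx], visit_id = sprintf("V%02d", visit),
    diagnosis = groups[ridx], age = age, sex = sex[ridx], icv = icv[ridx],
    field_strength = fs[ridx], site = site[ridx], scanner = scanner[ridx])
  table <- feature_table(records[, c("subject_id", "visit_id")], X, spec$sets,
                         kind = "raw")
  list(records = records, table = table)
}
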