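# Active-feature enrichment: set construction, enrichment fractions,
# sensitivity / specificity and randomization Z-scores.
#
# Vocabulary: the docked-feature set holds every feature identifier seen
# in successfully docked fragments; the AS set holds those with at least
# one occurrence center at the active site; active features are those
# also present in known active ligands.

#' Build the feature sets for enrichment analysis
#'
#' @param docked_features Identifiers of all features of the successfully
#'   docked fragments.
#' @param as_features Identifiers docked at the active site (must be a
#'   subset of \code{docked_features}).
#' @param active_ligand_features Identifiers present in known active
#'   ligands.
#' @return A \code{feature_sets}: list with \code{docked} (F_EGFd-like
#'   universe), \code{as} (F_AS), \code{non_as} (complement within the
#'   universe) and \code{active} (F_A = docked intersect active-ligand).
#' @export
build_sets <- function(docked_features, as_features,
                       active_ligand_features) {
  docked <- unique(docked_features)
  as_f <- unique(as_features)
  if (!all(as_f %in% docked))
    stopf("active-site features must be a subset of the docked features")
  structure(list(docked = docked, as = as_f,
                 non_as = setdiff(docked, as_f),
                 active = intersect(docked, unique(active_ligand_features))),
            class = "feature_sets")
}

#' @export
print.feature_sets <- function(x, ...) {
  cat(sprintf("feature_sets: |docked| = %d, |AS| = %d, |non-AS| = %d, |active| = %d\n",
              length(x$docked), length(x$as), length(x$non_as),
              length(x$active)))
  invisible(x)
}

#' Enrichment of active features
#'
#' Fractions of active features in the docked universe, in the
#' active-site set, and in its complement. Undefined ratios (empty
#' denominator set) are reported as \code{NA}, not 0.
#'
#' @param sets A \code{feature_sets}.
#' @return List with \code{e_docked}, \code{e_as}, \code{e_non_as}.
#' @export
enrichments <- function(sets) {
  if (length(sets$docked) == 0L) stopf("the docked feature set is empty")
  frac <- function(num, den)
    if (length(den) == 0L) NA_real_ else length(num) / length(den)
  list(e_docked = frac(sets$active, sets$docked),
       e_as = frac(intersect(sets$active, sets$as), sets$as),
       e_non_as = frac(intersect(sets$active, sets$non_as), sets$non_as))
}

#' Sensitivity and specificity of active-site feature mapping
#'
#' Sensitivity: fraction of active features that docked at the active
#' site. Specificity: fraction of inactive features (docked but not
#' active) that never docked there. The discrimination ratio
#' Se / (1 - Sp) is \code{Inf} when Sp = 1 and Se > 0.
#'
#' @param sets A \code{feature_sets}.
#' @return List with \code{se}, \code{sp}, \code{ratio}; components are
#'   \code{NA} when their denominator set is empty.
#' @export
sensitivity_specificity <- function(sets) {
  inactive <- setdiff(sets$docked, sets$active)
  se <- if (length(sets$active) == 0L) NA_real_ else
    length(intersect(sets$active, sets$as)) / length(sets$active)
  sp <- if (length(inactive) == 0L) NA_real_ else
    length(intersect(inactive, sets$non_as)) / length(inactive)
  ratio <- if (is.na(se) || is.na(sp)) NA_real_
  else if (sp == 1) { if (se > 0) Inf else NA_real_ }
  else se / (1 - sp)
  list(se = se, sp = sp, ratio = ratio)
}

#' Randomization Z-scores for sensitivity and specificity
#'
#' Null model: the identities of the features docked at the active site
#' are resampled uniformly without replacement from the docked universe
#' (preserving the set size), and sensitivity recomputed each time;
#' analogously for specificity with draws of the complement's size. The
#' Z-score is the distance of the observed value from the null mean in
#' null standard deviations; |Z| > 4 is conventionally called strongly
#' significant.
#'
#' @param sets A \code{feature_sets}.
#' @param n_randomizations Number of resamples (default 1e6 for
#'   production; >= 100 required).
#' @param seed Integer seed.
#' @return List with \code{z_se}, \code{z_sp}, the observed \code{se} /
#'   \code{sp}, the null means/sds, \code{n_randomizations}, \code{seed}.
#'   A Z is \code{NA} with a diagnostic when the null sd is zero.
#' @export
randomization_zscores <- function(sets, n_randomizations = 1e6, seed = 1L) {
  if (n_randomizations < 100) stopf("need >= 100 randomizations")
  obs <- sensitivity_specificity(sets)
  m <- length(sets$docked)
  n_as <- length(sets$as)
  n_active <- length(sets$active)
  inactive <- setdiff(sets$docked, sets$active)
  is_active <- sets$docked %in% sets$active
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  # Se null: |active ∩ draw| / |active| with draws of size |AS|
  null_se <- vapply(seq_len(n_randomizations), function(r)
    sum(is_active[sample.int(m, n_as)]) / n_active, numeric(1))
  # Sp null: |inactive ∩ draw| / |inactive| with draws of size |non-AS|
  n_non_as <- length(sets$non_as)
  null_sp <- vapply(seq_len(n_randomizations), function(r)
    sum(!is_active[sample.int(m, n_non_as)]) / length(inactive), numeric(1))
  zof <- function(obs_v, null_v) {
    s <- sd(null_v)
    if (!is.finite(obs_v) || is.na(obs_v)) return(NA_real_)
    if (s == 0) return(NA_real_)
    (obs_v - mean(null_v)) / s
  }
  list(z_se = zof(obs$se, null_se), z_sp = zof(obs$sp, null_sp),
       se = obs$se, sp = obs$sp,
       null_se_mean = mean(null_se), null_se_sd = sd(null_se),
       null_sp_mean = mean(null_sp), null_sp_sd = sd(null_sp),
       n_randomizations = as.integer(n_randomizations),
       seed = as.integer(seed))
}

#' Full enrichment report
#'
#' Convenience wrapper bundling enrichments, sensitivity/specificity and
#' (optionally) randomization Z-scores into one list, suitable for JSON
#' export.
#'
#' @param sets A \code{feature_sets}.
#' @param n_randomizations Resamples for the Z-scores; 0 skips them.
#' @param seed Integer seed.
#' @return Named list report.
#' @export
enrichment_report <- function(sets, n_randomizations = 1e5, seed = 1L) {
  rep_ <- c(list(n_docked = length(sets$docked), n_as = length(sets$as),
                 n_non_as = length(sets$non_as),
                 n_active = length(sets$active)),
            enrichments(sets), sensitivity_specificity(sets))
  if (n_randomizations > 0)
    rep_ <- c(rep_, randomization_zscores(sets, n_randomizations, seed))
  rep_
}
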