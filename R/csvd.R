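# Cerebral small vessel disease (CSVD) total burden score: one point each
# for qualifying white matter hyperintensity (WMH), cerebral microbleed
# (CMB), perivascular space (PVS) and lacuna findings, giving a 0-4 total;
# and the Montreal Cognitive Assessment (MoCA) cut-off of 26.
#
# WMH uses the Fazekas scale split into its periventricular (PVWMH) and
# deep (DWMH) subscales, each 0-3.

check_grade <- function(x, name, max) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 0) || any(x > max))
    abort(paste0(name, " must be integers in 0..", max),
          class = "strokeseg_value_error")
  invisible(as.integer(x))
}

check_count <- function(x, name) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 0))
    abort(paste0(name, " must be non-negative integers"),
          class = "strokeseg_value_error")
  invisible(as.integer(x))
}

#' WMH point of the CSVD score
#'
#' One point when deep WMH reaches Fazekas 2 or 3, and/or periventricular
#' WMH reaches Fazekas 3.
#'
#' @param dwmh_fazekas Deep WMH Fazekas grade, 0-3 (vectorized).
#' @param pvwmh_fazekas Periventricular WMH Fazekas grade, 0-3.
#' @return Integer 0/1 vector.
#' @export
wmh_point <- function(dwmh_fazekas, pvwmh_fazekas) {
  check_grade(dwmh_fazekas, "dwmh_fazekas", 3)
  check_grade(pvwmh_fazekas, "pvwmh_fazekas", 3)
  as.integer(dwmh_fazekas >= 2 | pvwmh_fazekas == 3)
}

#' CMB point of the CSVD score
#'
#' One point for one or more cerebral microbleeds.
#'
#' @param cmb_count Number of microbleeds (>= 0, vectorized).
#' @return Integer 0/1 vector.
#' @export
cmb_point <- function(cmb_count) {
  check_count(cmb_count, "cmb_count")
  as.integer(cmb_count >= 1)
}

#' PVS point of the CSVD score
#'
#' One point for basal-ganglia perivascular spaces of grade 2-4.
#'
#' @param pvs_grade Basal-ganglia PVS grade, 0-4 (vectorized).
#' @return Integer 0/1 vector.
#' @export
pvs_point <- function(pvs_grade) {
  check_grade(pvs_grade, "pvs_grade", 4)
  as.integer(pvs_grade >= 2)
}

#' Lacuna point of the CSVD score
#'
#' One point for one or more lacunae.
#'
#' @param lacuna_count Number of lacunae (>= 0, vectorized).
#' @return Integer 0/1 vector.
#' @export
lacuna_point <- function(lacuna_count) {
  check_count(lacuna_count, "lacuna_count")
  as.integer(lacuna_count >= 1)
}

#' Total CSVD burden score
#'
#' Data-frame-first scoring: takes per-subject MRI feature columns and
#' appends the four point columns and their 0-4 total.
#'
#' @param data Data frame with columns `pvwmh_fazekas`, `dwmh_fazekas`
#'   (0-3), `cmb_count` (>= 0), `pvs_grade` (0-4) and `lacuna_count`
#'   (>= 0).
#' @return The input as a tibble with added columns `wmh_point`,
#'   `cmb_point`, `pvs_point`, `lacuna_point` and `csvd_total`.
#' @examples
#' csvd_score(data.frame(pvwmh_fazekas = 0, dwmh_fazekas = 3,
#'                       cmb_count = 2, pvs_grade = 3, lacuna_count = 1))
#' @export
csvd_score <- function(data) {
  need <- c("pvwmh_fazekas", "dwmh_fazekas", "cmb_count", "pvs_grade",
            "lacuna_count")
  missing <- setdiff(need, names(data))
  if (length(missing))
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "strokeseg_value_error")
  out <- as_tibble(data)
  out$wmh_point <- wmh_point(out$dwmh_fazekas, out$pvwmh_fazekas)
  out$cmb_point <- cmb_point(out$cmb_count)
  out$pvs_point <- pvs_point(out$pvs_grade)
  out$lacuna_point <- lacuna_point(out$lacuna_count)
  out$csvd_total <- out$wmh_point + out$cmb_point + out$pvs_point +
    out$lacuna_point
  out
}

#' Classify cognition from the MoCA total
#'
#' Totals strictly below the cut-off (26 by default) are classified as
#' impaired; a total of exactly 26 is not impaired.
#'
#' @param moca_total MoCA totals, 0-30 (vectorized).
#' @param cutoff Cut-off point.
#' @return Factor with levels `"impaired"`, `"not_impaired"`.
#' @export
classify_cognition <- function(moca_total, cutoff = 26) {
  if (any(is.na(moca_total)) || any(moca_total < 0) || any(moca_total > 30))
    abort("MoCA totals must lie in 0..30", class = "strokeseg_value_error")
  factor(ifelse(moca_total < cutoff, "impaired", "not_impaired"),
         levels = c("impaired", "not_impaired"))
}

#' Follow-up MoCA improvement flag
#'
#' A follow-up gain of more than two points counts as a degree of
#' improvement in cognitive function.
#'
#' @param baseline,followup MoCA totals, 0-30 (vectorized).
#' @param margin Minimum gain that does **not** yet count (default 2: the
#'   gain must exceed it).
#' @return Logical vector.
#' @export
moca_improvement <- function(baseline, followup, margin = 2) {
  for (x in list(baseline, followup))
    if (any(is.na(x)) || any(x < 0) || any(x > 30))
      abort("MoCA totals must lie in 0..30", class = "strokeseg_value_error")
  followup - baseline > margin
}
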