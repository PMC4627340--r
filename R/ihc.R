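# Allred immunohistochemistry scoring and the 3-marker composite.
#
# An Allred score is intensity (0-3) plus proportion (0-5); either both
# components are zero or both positive, so totals live in {0} U {2..8}.
# The sample-level marker score is the maximum over up to three TMA cores.
# The composite is Allred(JUN) - Allred(CD8) - Allred(CD20), range
# [-16, 8]; positives are high risk, negatives low risk, zero is reported
# as indeterminate (the stratification rule is stated only with strict
# inequalities).

#' Allred total from intensity and proportion
#'
#' @param intensity staining intensity, 0-3.
#' @param proportion proportion category, 0-5.
#' @return intensity + proportion (vectorised).
#' @export
allred_total <- function(intensity, proportion) {
  if (any(!intensity %in% 0:3)) stop_input("intensity must be in 0..3")
  if (any(!proportion %in% 0:5)) stop_input("proportion must be in 0..5")
  bad <- xor(intensity == 0, proportion == 0)
  if (any(bad))
    stop_input("inconsistent Allred pair (one component zero): intensity=",
               intensity[bad][1], ", proportion=", proportion[bad][1])
  intensity + proportion
}

#' Sample-level marker score from replicate cores
#'
#' @param cores numeric vector of per-core Allred totals; `NA` = core not
#'   evaluable.
#' @return maximum total over evaluable cores; `NA` if none evaluable.
#' @export
sample_marker_score <- function(cores) {
  cores <- cores[!is.na(cores)]
  if (length(cores) == 0) return(NA_real_)
  max(cores)
}

#' Three-marker composite IHC risk score
#'
#' @param jun,cd8,cd20 sample-level Allred totals (vectorised).
#' @return jun - cd8 - cd20; `NA` where any marker is missing (with a
#'   message naming the exclusion).
#' @export
composite_score <- function(jun, cd8, cd20) {
  out <- jun - cd8 - cd20
  n_miss <- sum(is.na(out))
  if (n_miss > 0) message(n_miss, " sample(s) excluded: missing marker score")
  out
}

#' IHC risk group from the composite score
#'
#' @param score composite score(s).
#' @return factor: `"high"` (> 0), `"low"` (< 0), `"indeterminate"` (= 0).
#' @export
ihc_risk_group <- function(score) {
  if (any(!is.finite(score))) stop_input("score must be finite")
  factor(ifelse(score > 0, "high", ifelse(score < 0, "low", "indeterminate")),
         levels = c("low", "indeterminate", "high"))
}

#' Inter-rater agreement of composite scores
#'
#' @param scores_a,scores_b paired composite scores from two raters.
#' @return list(r = Pearson correlation, p = two-sided p-value, n).
#' @export
interrater_agreement <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop_input("unpaired scores")
  ok <- is.finite(scores_a) & is.finite(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  if (length(a) < 3) stop_input("need >= 3 pairs")
  if (sd(a) == 0 || sd(b) == 0) stop_input("constant scores; correlation undefined")
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Score an Allred core table
#'
#' Takes the long table produced by [generate_ihc()] (or read from TSV:
#' sample, marker, core, intensity, proportion), computes per-core totals,
#' per-marker sample scores (max over cores), the composite, and the risk
#' group.
#'
#' @param cores data.frame with columns sample, marker, core, intensity,
#'   proportion; markers must include JUN, CD8 and CD20.
#' @return data.frame: sample, JUN, CD8, CD20, composite, group.
#' @export
score_ihc_table <- function(cores) {
  need <- c("sample", "marker", "core", "intensity", "proportion")
  if (!all(need %in% names(cores)))
    stop_format("core table must have columns: ", paste(need, collapse = ", "))
  cores$total <- allred_total(cores$intensity, cores$proportion)
  samples <- unique(cores$sample)
  marker_score <- function(smp, mk) {
    v <- cores$total[cores$sample == smp & cores$marker == mk]
    sample_marker_score(if (length(v)) v else NA_real_)
  }
  jun <- vapply(samples, marker_score, 1, mk = "JUN")
  cd8 <- vapply(samples, marker_score, 1, mk = "CD8")
  cd20 <- vapply(samples, marker_score, 1, mk = "CD20")
  comp <- composite_score(jun, cd8, cd20)
  ok <- !is.na(comp)
  grp <- rep(NA_character_, length(comp))
  grp[ok] <- as.character(ihc_risk_group(comp[ok]))
  data.frame(sample = samples,
             JUN = jun, CD8 = cd8, CD20 = cd20, composite = comp,
             group = grp, stringsAsFactors = FALSE, row.names = NULL)
}
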