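#' Three-criterion graded histone-modification occupancy
#'
#' Combines, for one reader x mark pair within one domain class, the three
#' association read-outs into a grade: C1, Pearson correlation r >= r0
#' (default 0.300); C2, fraction of the reader's peaks significantly occupied
#' by the mark >= f0 (default 0.30, i.e. 30%); C3, overlap detected by the
#' heatmap/coverage analysis. The grade is the number of satisfied criteria:
#' 3 = "prominent" (all three), 2 = "detectable", 1 = "weak", and 0 = "none"
#' (reported explicitly rather than silently dropped). Both thresholds are
#' inclusive, so r = 0.300 and a fraction of exactly 0.30 satisfy their
#' criteria. The count-of-criteria mapping makes the grades mutually
#' exclusive.
#'
#' @param r Pearson correlation coefficient in [-1, 1]
#' @param sig_fraction significant-overlap fraction in [0, 1]
#' @param heatmap_flag logical: overlap detected by heatmap analysis
#' @param r0,f0 criterion thresholds
#' @param reader,mark,domain_class optional labels carried into the result
#' @return data.frame(reader, mark, domain_class, r, sig_fraction,
#'   heatmap_flag, grade, label)
#' @export
grade_association <- function(r, sig_fraction, heatmap_flag,
                              r0 = 0.300, f0 = 0.30,
                              reader = NA_character_, mark = NA_character_,
                              domain_class = NA_character_) {
  if (!is.finite(r) || r < -1 || r > 1) stopf("r out of [-1, 1]")
  if (!is.finite(sig_fraction) || sig_fraction < 0 || sig_fraction > 1)
    stopf("sig_fraction out of [0, 1]")
  stopifnot(is.logical(heatmap_flag), length(heatmap_flag) == 1)
  satisfied <- sum(r >= r0, sig_fraction >= f0, isTRUE(heatmap_flag))
  labels <- c("none", "weak", "detectable", "prominent")
  data.frame(reader = reader, mark = mark, domain_class = domain_class,
             r = r, sig_fraction = sig_fraction,
             heatmap_flag = isTRUE(heatmap_flag),
             grade = satisfied, label = labels[satisfied + 1L],
             stringsAsFactors = FALSE)
}
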