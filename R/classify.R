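#' Rule for calling positive mutation statuses
#'
#' Positive calling is upstream of this package's contribution: users may
#' bring positives from any variant caller. This rule covers the common
#' thresholds — a minimum number of mutant reads and, optionally, a minimum
#' VAF — so that a count matrix alone suffices.
#'
#' @param min_mutant_reads minimum mutant reads for a positive call
#'   (default 2, the rule used in dual-platform single-cell evaluation;
#'   simulation benchmarks use 1).
#' @param min_vaf optional minimum VAF in `[0, 1]`; `NULL` (default) disables
#'   the VAF condition.
#' @return Object of class `positive_rule`.
#' @export
positive_rule <- function(min_mutant_reads = 2L, min_vaf = NULL) {
  min_mutant_reads <- as.integer(min_mutant_reads)
  stopifnot(length(min_mutant_reads) == 1L, !is.na(min_mutant_reads),
            min_mutant_reads >= 1L)
  if (!is.null(min_vaf)) {
    stopifnot(is.numeric(min_vaf), length(min_vaf) == 1L,
              min_vaf >= 0, min_vaf <= 1)
  }
  structure(list(min_mutant_reads = min_mutant_reads, min_vaf = min_vaf),
            class = "positive_rule")
}

#' Configuration of the mutation-specific negative (MSN) classifier
#'
#' @param alpha p-value cutoff in (0, 1); rejection requires `p < alpha`
#'   strictly. No multiple-testing adjustment is applied; vary `alpha` instead.
#' @param sidedness passed to [fisher_exact_p()].
#' @param subthreshold_policy what to do with a non-positive cell that still
#'   has `mutant > 0` (possible when the positive rule requires more than one
#'   mutant read). `"always-unknown"` (default) never tests such cells;
#'   `"test-observed-counts"` runs the Fisher test on the observed counts, but
#'   a cell with mutant reads can never be labelled negative either way.
#' @return Object of class `msn_config`.
#' @export
msn_config <- function(alpha = 0.05,
                       sidedness = c("two-sided", "one-sided"),
                       subthreshold_policy = c("always-unknown",
                                               "test-observed-counts")) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(list(alpha = alpha,
                 sidedness = match.arg(sidedness),
                 subthreshold_policy = match.arg(subthreshold_policy)),
            class = "msn_config")
}

#' Configuration of the universal-minimum-coverage (UMC) baseline
#'
#' @param min_coverage minimum total reads (coverage) for a zero-mutant
#'   non-positive cell to be callable negative; the bound is inclusive
#'   (`total >= min_coverage`). Typical values: 20, 50, 100, 300.
#' @return Object of class `umc_config`.
#' @export
umc_config <- function(min_coverage = 20L) {
  min_coverage <- as.integer(min_coverage)
  stopifnot(length(min_coverage) == 1L, !is.na(min_coverage), min_coverage >= 1L)
  structure(list(min_coverage = min_coverage), class = "umc_config")
}

#' Identify positive mutation/sample pairs
#'
#' Labels each cell `"positive"` when it meets the rule's thresholds and
#' `"TBD"` (to-be-determined) otherwise. This is the first step of the
#' two-step status assignment; [classify_msn()] or [classify_umc()] then
#' resolve the TBD cells into negative or unknown. Callers with positives
#' from an external variant caller can skip this function and supply their
#' own positive/TBD [status_matrix()] directly.
#'
#' @param counts a [count_matrix()].
#' @param rule a [positive_rule()].
#' @return A [status_matrix()] with labels in `{"positive", "TBD"}`.
#' @export
#' @examples
#' cm <- example_five_sample_counts()
#' define_positive(cm, positive_rule(min_mutant_reads = 1))
define_positive <- function(counts, rule = positive_rule()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(rule, "positive_rule"))
  pos <- counts$mutant >= rule$min_mutant_reads
  if (!is.null(rule$min_vaf)) {
    v <- counts$mutant / counts$total
    v[counts$total == 0] <- 0
    pos <- pos & (v >= rule$min_vaf)
  }
  status <- matrix(ifelse(pos, "positive", "TBD"), nrow = nrow(counts$mutant))
  status_matrix(counts$keys, status, counts$samples)
}

# validate a user-supplied positive/TBD matrix against the counts
check_positive_matrix <- function(counts, positives, allow_zero_mutant = FALSE) {
  stopifnot(inherits(positives, "status_matrix"))
  check_same_axes(counts, positives)
  if (!all(positives$status %in% c("positive", "TBD"))) {
    stop("supplied positive matrix may only contain 'positive' and 'TBD' labels",
         call. = FALSE)
  }
  zero_pos <- positives$status == "positive" & counts$mutant == 0
  if (any(zero_pos)) {
    msg <- sprintf(
      "%d cell(s) marked positive have zero mutant reads", sum(zero_pos))
    if (allow_zero_mutant) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify non-positive cells with the mutation-specific negative (MSN) rule
#'
#' For every mutation, each non-positive (TBD) sample is compared against
#' every positive sample of that same mutation with Fisher's exact test on
#' mutant/wildtype read counts. The cell is labelled `"negative"` only when
#' the equal-VAF null hypothesis is rejected (`p < alpha`) against *all*
#' positive samples — evidence that the absence of mutant reads is not merely
#' low coverage; otherwise it is `"unknown"`. Positive labels pass through
#' untouched: the rule never creates or removes positives.
#'
#' A mutation with no positive sample at all leaves every TBD cell
#' `"unknown"` (with a warning): with no observed abundance to test against,
#' the all-positives condition would be vacuously true, which would absurdly
#' declare everything negative. Well-formed input should not contain such
#' mutations, since each listed mutation was called somewhere.
#'
#' @param counts a [count_matrix()].
#' @param positives optional [status_matrix()] with labels positive/TBD,
#'   e.g. from an external caller; when `NULL`, derived via
#'   [define_positive()] with `rule`.
#' @param cfg an [msn_config()].
#' @param rule a [positive_rule()], used only when `positives` is `NULL`.
#' @param allow_zero_mutant_positive accept (with a warning) a supplied
#'   positive matrix that marks zero-mutant cells positive; default rejects.
#' @param audit attach an `"audit"` attribute: a data frame with one row per
#'   tested (mutation, non-positive sample, positive sample) triple, holding
#'   the 2x2 table counts and the p-value (retrievable with [msn_audit()]).
#' @return A [status_matrix()] with labels in
#'   `{"positive", "negative", "unknown"}`.
#' @export
#' @examples
#' cm <- example_five_sample_counts()
#' st <- classify_msn(cm, rule = positive_rule(min_mutant_reads = 1),
#'                    audit = TRUE)
#' st$status
#' msn_audit(st)
classify_msn <- function(counts, positives = NULL, cfg = msn_config(),
                         rule = positive_rule(),
                         allow_zero_mutant_positive = FALSE,
                         audit = FALSE) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cfg, "msn_config"))
  if (is.null(positives)) {
    positives <- define_positive(counts, rule)
  } else {
    check_positive_matrix(counts, positives, allow_zero_mutant_positive)
  }

  status <- positives$status
  ids <- rownames(counts$mutant)
  audit_rows <- if (audit) vector("list", nrow(status)) else NULL
  no_positive <- character(0)

  for (i in seq_len(nrow(status))) {
    is_pos <- status[i, ] == "positive"
    tbd <- which(!is_pos)
    if (length(tbd) == 0L) next
    pos <- which(is_pos)
    if (length(pos) == 0L) {
      status[i, tbd] <- "unknown"
      no_positive <- c(no_positive, ids[i])
      next
    }
    for (j in tbd) {
      m <- counts$mutant[i, j]
      tt <- counts$total[i, j]
      testable <- m == 0 || cfg$subthreshold_policy == "test-observed-counts"
      if (testable) {
        p <- fisher_exact_p(m, tt, counts$mutant[i, pos], counts$total[i, pos],
                            cfg$sidedness)
      } else {
        p <- rep(NA_real_, length(pos))
      }
      # negative needs rejection against every positive AND zero mutant reads
      status[i, j] <- if (m == 0 && all(!is.na(p)) && all(p < cfg$alpha)) {
        "negative"
      } else {
        "unknown"
      }
      if (audit) {
        audit_rows[[i]] <- rbind(audit_rows[[i]], data.frame(
          mutation = ids[i],
          sample = counts$samples[j],
          vs_positive = counts$samples[pos],
          mutant = m, total = tt,
          pos_mutant = counts$mutant[i, pos],
          pos_total = counts$total[i, pos],
          p_value = p,
          rejected = !is.na(p) & p < cfg$alpha
        ))
      }
    }
  }
  if (length(no_positive) > 0) {
    warning(length(no_positive),
            " mutation(s) have no positive sample; their non-positive cells ",
            "were labelled unknown", call. = FALSE)
  }
  out <- status_matrix(counts$keys, status, counts$samples)
  if (audit) {
    attr(out, "audit") <- do.call(rbind, c(audit_rows,
                                           list(make.row.names = FALSE)))
  }
  out
}

#' Retrieve the per-comparison audit table of an MSN classification
#'
#' @param x a [status_matrix()] produced by `classify_msn(..., audit = TRUE)`.
#' @return Data frame of tested triples with 2x2 counts and p-values, or
#'   `NULL` when no audit was recorded.
#' @export
msn_audit <- function(x) attr(x, "audit")

#' Classify non-positive cells with the universal-minimum-coverage baseline
#'
#' The conventional rule the MSN method is benchmarked against: a non-positive
#' cell is `"negative"` when it has zero mutant reads and its coverage meets a
#' single global threshold (`total >= min_coverage`, inclusive), `"unknown"`
#' otherwise. The threshold ignores each mutation's observed abundance, which
#' is exactly the weakness the adaptive rule addresses.
#'
#' @inheritParams classify_msn
#' @param cfg a [umc_config()].
#' @return A [status_matrix()] with labels in
#'   `{"positive", "negative", "unknown"}`.
#' @export
#' @examples
#' cm <- example_two_biopsy_counts()
#' classify_umc(cm, cfg = umc_config(20))$status
classify_umc <- function(counts, positives = NULL, cfg = umc_config(),
                         rule = positive_rule(),
                         allow_zero_mutant_positive = FALSE) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cfg, "umc_config"))
  if (is.null(positives)) {
    positives <- define_positive(counts, rule)
  } else {
    check_positive_matrix(counts, positives, allow_zero_mutant_positive)
  }
  status <- positives$status
  tbd <- status == "TBD"
  neg <- tbd & counts$mutant == 0 & counts$total >= cfg$min_coverage
  status[neg] <- "negative"
  status[tbd & !neg] <- "unknown"
  status_matrix(counts$keys, status, counts$samples)
}
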