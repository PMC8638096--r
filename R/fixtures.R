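#' Built-in demonstration matrices
#'
#' Two small worked examples used throughout the documentation and tests.
#' `example_two_biopsy_counts()` is the two-biopsy lung-cancer illustration: EGFR
#' T790M seen at 40/72 reads (56% VAF) and C797S at 5/100 (5% VAF) in the
#' first biopsy, neither detected in a shallower follow-up biopsy (0/15 and
#' 0/30). Under a universal 20X minimum coverage the low-VAF C797S is called
#' negative and the high-VAF T790M unknown; the adaptive rule reverses both
#' calls, matching each mutation's observed abundance.
#' `example_five_sample_counts()` is a single mutation measured in five samples A-E
#' (10/20, 0/20, 4/9, 0/8, 0/5) used to walk through the
#' all-positive-comparisons requirement.
#'
#' @return A [count_matrix()].
#' @export
example_two_biopsy_counts <- function() {
  count_matrix(
    keys = data.frame(chrom = c("7", "7"),
                      pos = c(55249071L, 55249092L),
                      ref = c("C", "T"),
                      alt = c("T", "A")),
    mutant = cbind(biopsy1 = c(40L, 5L), biopsy2 = c(0L, 0L)),
    total = cbind(biopsy1 = c(72L, 100L), biopsy2 = c(15L, 30L))
  )
}

#' @rdname example_two_biopsy_counts
#' @export
example_five_sample_counts <- function() {
  count_matrix(
    keys = data.frame(chrom = "1", pos = 1000L, ref = "G", alt = "A"),
    mutant = matrix(c(10L, 0L, 4L, 0L, 0L), 1,
                    dimnames = list(NULL, LETTERS[1:5])),
    total = matrix(c(20L, 20L, 9L, 8L, 5L), 1)
  )
}

#' Write demonstration and test fixtures to disk
#'
#' Deterministic, seeded fixture files for demos, smoke tests and property
#' tests: the two built-in worked examples, a small random count matrix with
#' its positive/TBD matrix, or a synthetic paired-platform dataset (counts
#' plus pairing table) ready for [sweep_thresholds()].
#'
#' @param kind one of `"two-biopsy"`, `"five-sample"`, `"random-small"`,
#'   `"paired-demo"`.
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the random kinds; the same seed always produces
#'   byte-identical files.
#' @return Character vector of the paths written, invisibly.
#' @export
make_fixture <- function(kind = c("two-biopsy", "five-sample", "random-small",
                                  "paired-demo"),
                         dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)
  if (kind == "two-biopsy") {
    paths <- p("two_biopsy_counts.tsv")
    write_count_matrix(example_two_biopsy_counts(), paths)
  } else if (kind == "five-sample") {
    paths <- p("five_sample_counts.tsv")
    write_count_matrix(example_five_sample_counts(), paths)
  } else if (kind == "random-small") {
    set.seed(seed)
    cm <- random_count_matrix(n_mut = 12L, n_samples = 4L)
    paths <- c(p("random_counts.tsv"), p("random_positive.tsv"))
    write_count_matrix(cm, paths[1])
    write_status_matrix(define_positive(cm, positive_rule(2)), paths[2])
  } else {
    set.seed(seed)
    demo <- synth_paired_dataset(n_units = 3L, n_mut = 30L)
    paths <- c(p("paired_counts.tsv"), p("paired_map.tsv"))
    write_count_matrix(demo$counts, paths[1])
    utils::write.table(
      data.frame(unit = demo$pairs$unit, sample_A = demo$pairs$sample_a,
                 sample_B = demo$pairs$sample_b),
      paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Random count matrix for property tests and demos
#'
#' Draws per-mutation VAFs spanning high- to low-abundance mutations and
#' per-cell coverages from a wide range, then binomial mutant reads, with a
#' fraction of cells forced to true-absent (zero mutant reads). Uses the
#' current RNG state; seed outside.
#'
#' @param n_mut,n_samples matrix dimensions.
#' @param absent_prob probability a cell is true-absent.
#' @return A [count_matrix()].
#' @export
random_count_matrix <- function(n_mut = 10L, n_samples = 4L,
                                absent_prob = 0.3) {
  vaf_mut <- stats::runif(n_mut, 0.02, 0.6)
  total <- matrix(stats::rpois(n_mut * n_samples, lambda = 60) +
                    sample(0:2, n_mut * n_samples, TRUE) * 100L,
                  n_mut, n_samples)
  present <- matrix(stats::runif(n_mut * n_samples) > absent_prob,
                    n_mut, n_samples)
  mutant <- matrix(0L, n_mut, n_samples)
  vafm <- matrix(vaf_mut, n_mut, n_samples)
  mutant[present] <- stats::rbinom(sum(present), total[present], vafm[present])
  count_matrix(
    data.frame(chrom = "rand", pos = seq_len(n_mut), ref = "C", alt = "G"),
    mutant, total, paste0("S", seq_len(n_samples))
  )
}

#' Synthetic dual-platform single-cell dataset
#'
#' A stand-in paired design built entirely in code (no real single-cell data
#' is shipped): each unit ("cell") is measured by two platform samples that
#' share the unit's true mutation presence, with per-mutation VAFs and
#' platform-specific per-cell coverages. Clonal mutations are present in all
#' units, the rest in a random subset, mirroring intra-tumor heterogeneity.
#' Uses the current RNG state; seed outside.
#'
#' @param n_units number of cells.
#' @param n_mut number of unique mutations.
#' @param clonal_frac fraction of mutations present in every unit.
#' @param mean_coverage_a,mean_coverage_b mean per-cell coverage of the two
#'   platforms.
#' @param low_coverage_prob probability a cell x mutation measurement is
#'   shallow (coverage drawn around one tenth of the platform mean),
#'   emulating uneven capture.
#' @return List with `counts` (a [count_matrix()] of `2 * n_units` samples),
#'   `pairs` (a [pair_map()]) and `present` (units-truth logical matrix).
#' @export
synth_paired_dataset <- function(n_units = 6L, n_mut = 120L,
                                 clonal_frac = 0.5,
                                 mean_coverage_a = 120, mean_coverage_b = 80,
                                 low_coverage_prob = 0.25) {
  clonal <- seq_len(n_mut) <= round(clonal_frac * n_mut)
  present <- matrix(TRUE, n_mut, n_units)
  present[!clonal, ] <- stats::runif(sum(!clonal) * n_units) < 0.5
  vaf_mut <- stats::runif(n_mut, 0.05, 0.5)

  draw_platform <- function(mean_cov) {
    shallow <- stats::runif(n_mut * n_units) < low_coverage_prob
    lam <- ifelse(shallow, mean_cov / 10, mean_cov)
    total <- matrix(stats::rpois(n_mut * n_units, lam), n_mut, n_units)
    mutant <- matrix(0L, n_mut, n_units)
    mutant[present] <- stats::rbinom(sum(present), total[present],
                                     rep(vaf_mut, n_units)[present])
    list(mutant = mutant, total = total)
  }
  a <- draw_platform(mean_coverage_a)
  b <- draw_platform(mean_coverage_b)

  units <- paste0("cell", seq_len(n_units))
  samples <- c(paste0(units, "_A"), paste0(units, "_B"))
  counts <- count_matrix(
    data.frame(chrom = "synth", pos = seq_len(n_mut), ref = "A", alt = "C"),
    cbind(a$mutant, b$mutant), cbind(a$total, b$total), samples
  )
  list(counts = counts,
       pairs = pair_map(units, paste0(units, "_A"), paste0(units, "_B")),
       present = present)
}
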