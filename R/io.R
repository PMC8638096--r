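#' Read a count matrix from tab-separated text
#'
#' Expected header: `chrom  pos  ref  alt  <sample>:mut  <sample>:tot  ...`
#' with one `mut`/`tot` column pair per sample, the pair order fixed
#' (`:mut` immediately before its `:tot`). Counts must be plain non-negative
#' integers (no scientific notation); `mutant <= total` per cell; mutation
#' keys unique. Violations are reported with the offending data line number.
#' Sample order is order of first appearance and is preserved end to end.
#'
#' @param path file path.
#' @return A [count_matrix()].
#' @seealso [write_count_matrix()] — the two round-trip losslessly.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 6 || !identical(header[1:4], c("chrom", "pos", "ref", "alt"))) {
    stop("malformed header: expected 'chrom pos ref alt <sample>:mut <sample>:tot ...'",
         call. = FALSE)
  }
  cc <- header[-(1:4)]
  if (length(cc) %% 2 != 0) {
    stop("malformed header: unpaired sample count column", call. = FALSE)
  }
  mut_cols <- cc[seq(1, length(cc), 2)]
  tot_cols <- cc[seq(2, length(cc), 2)]
  samples <- sub(":mut$", "", mut_cols)
  if (!all(grepl(":mut$", mut_cols)) ||
      !identical(tot_cols, paste0(samples, ":tot"))) {
    stop("malformed header: sample columns must come as '<name>:mut' then '<name>:tot'",
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("malformed header: duplicate sample name", call. = FALSE)
  }

  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0) {
    warning("count matrix has no data rows", call. = FALSE)
    return(count_matrix(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character()),
      matrix(integer(), 0, length(samples)),
      matrix(integer(), 0, length(samples)), samples))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != length(header))) {
    stop("line ", which(widths != length(header))[1] + 1L,
         ": expected ", length(header), " fields", call. = FALSE)
  }
  tab <- do.call(rbind, parts)
  keys <- data.frame(chrom = tab[, 1], pos = NA_integer_, ref = tab[, 3],
                     alt = tab[, 4])
  pos_ok <- grepl("^[0-9]+$", tab[, 2])
  if (!all(pos_ok)) {
    stop("line ", which(!pos_ok)[1] + 1L, ": position '", tab[!pos_ok, 2][1],
         "' is not a plain integer", call. = FALSE)
  }
  keys$pos <- as.integer(tab[, 2])

  raw <- tab[, -(1:4), drop = FALSE]
  int_ok <- matrix(grepl("^[0-9]+$", raw), nrow = n)
  if (!all(int_ok)) {
    bad <- which(!apply(int_ok, 1, all))[1]
    stop("line ", bad + 1L, ": non-integer count '",
         raw[bad, which(!int_ok[bad, ])[1]], "'", call. = FALSE)
  }
  num <- matrix(as.integer(raw), nrow = n)
  mutant <- num[, seq(1, ncol(num), 2), drop = FALSE]
  total <- num[, seq(2, ncol(num), 2), drop = FALSE]
  over <- mutant > total
  if (any(over)) {
    bad <- which(apply(over, 1, any))[1]
    stop("line ", bad + 1L, ": mutant reads exceed total reads for sample '",
         samples[which(over[bad, ])[1]], "'", call. = FALSE)
  }
  ids <- mutation_id(keys)
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1]
    stop("line ", bad + 1L, ": duplicate mutation key '", ids[bad], "'",
         call. = FALSE)
  }
  colnames(mutant) <- colnames(total) <- samples
  count_matrix(keys, mutant, total, samples)
}

#' Write a count matrix as tab-separated text
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  header <- c("chrom", "pos", "ref", "alt",
              as.vector(rbind(paste0(x$samples, ":mut"),
                              paste0(x$samples, ":tot"))))
  n <- nrow(x$mutant)
  cells <- matrix(NA_character_, n, 2 * length(x$samples))
  cells[, seq(1, ncol(cells), 2)] <- as.character(x$mutant)
  cells[, seq(2, ncol(cells), 2)] <- as.character(x$total)
  rows <- cbind(x$keys$chrom, as.character(x$keys$pos), x$keys$ref, x$keys$alt,
                cells)
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")[seq_len(n)]),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read or write a status matrix as tab-separated text
#'
#' Layout: `chrom pos ref alt <sample> ...`, one status label per sample
#' column. `read_status_matrix()` accepts positive/TBD matrices (the
#' user-supplied positive format) as well as final
#' positive/negative/unknown matrices.
#'
#' @param path file path.
#' @return `read_status_matrix()`: a [status_matrix()];
#'   `write_status_matrix()`: `path`, invisibly.
#' @export
read_status_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)[1:4])) {
    stop("malformed header: expected 'chrom pos ref alt <sample> ...'",
         call. = FALSE)
  }
  samples <- names(tab)[-(1:4)]
  if (length(samples) == 0) stop("no sample columns", call. = FALSE)
  keys <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                     ref = tab$ref, alt = tab$alt)
  status_matrix(keys, as.matrix(tab[, samples, drop = FALSE]), samples)
}

#' @rdname read_status_matrix
#' @param x a [status_matrix()].
#' @export
write_status_matrix <- function(x, path) {
  stopifnot(inherits(x, "status_matrix"))
  header <- c("chrom", "pos", "ref", "alt", x$samples)
  rows <- cbind(x$keys$chrom, as.character(x$keys$pos), x$keys$ref, x$keys$alt,
                x$status)
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")[seq_len(nrow(x$status))]),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a unit-to-samples pairing table
#'
#' Layout: `unit  sample_A  sample_B`, tab-separated with header.
#'
#' @param path file path.
#' @return A [pair_map()].
#' @export
read_pair_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3) {
    stop("malformed pair map: expected columns 'unit sample_A sample_B'",
         call. = FALSE)
  }
  pair_map(tab[[1]], tab[[2]], tab[[3]])
}

#' Write an MSN audit table or a result table as tab-separated text
#'
#' @param x data frame (e.g. from [msn_audit()], [sweep_thresholds()] or
#'   [run_scenarios()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
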