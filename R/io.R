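#' Paired-end read set
#'
#' Container for a paired-end read library: two parallel character vectors of
#' equal-length reads. Mate 2 is stored exactly as given on input (i.e. not
#' reverse-complemented).
#'
#' @param fwd,rev Character vectors of mate-1 and mate-2 sequences.
#' @param read_length Expected uniform read length; inferred from the data
#'   when `NULL`. Ragged input is rejected.
#' @param source Free-text descriptor of where the reads came from.
#' @return An object of class `read_set`.
#' @export
read_set <- function(fwd, rev, read_length = NULL, source = "in-memory") {
  if (length(fwd) != length(rev))
    rf_stop("mate vectors differ in length", "pairing_error")
  fwd <- toupper(fwd); rev <- toupper(rev)
  lens <- c(nchar(fwd), nchar(rev))
  if (is.null(read_length)) read_length <- if (length(lens)) lens[1] else 0L
  if (length(lens) && any(lens != read_length))
    rf_stop("ragged read set: all reads must have the declared read_length", "parse_error")
  structure(list(fwd = fwd, rev = rev,
                 read_length = as.integer(read_length), source = source),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$fwd)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x), "pairs of", x$read_length, "bp reads (",
      x$source, ")\n")
  invisible(x)
}

## internal: read one FASTA/FASTQ file into an uppercase character vector
read_seq_file <- function(path) {
  if (!file.exists(path)) rf_stop(paste0("file not found: ", path), "io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  fmt <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) rf_stop(
      paste0("malformed ", fmt, " in '", path, "': ", conditionMessage(e)),
      "parse_error")
  )
  unname(toupper(as.character(ss)))
}

#' Load paired-end reads from FASTQ/FASTA
#'
#' Reads a paired-end library from one interleaved file or two split files.
#' Format (FASTA vs FASTQ) is auto-detected per file; FASTQ qualities are
#' ignored. Pairing follows file order: in split layout record i of file 1
#' pairs with record i of file 2; in interleaved layout consecutive records
#' pair. Mate 2 is stored as given.
#'
#' @param paths One (interleaved) or two (split) file paths.
#' @param paired_layout `"split"` or `"interleaved"`.
#' @param min_read_length If supplied, loading fails when any read is shorter
#'   (used to reject reads shorter than the largest assembly k-mer).
#' @return A [read_set()].
#' @export
load_reads <- function(paths, paired_layout = c("split", "interleaved"),
                       min_read_length = NULL) {
  paired_layout <- match.arg(paired_layout)
  if (paired_layout == "split") {
    if (length(paths) != 2L)
      rf_stop("split layout requires exactly two files", "io_error")
    fwd <- read_seq_file(paths[1])
    rev <- read_seq_file(paths[2])
    if (length(fwd) != length(rev))
      rf_stop(sprintf("unequal mate counts: %d records in '%s' vs %d in '%s'",
                      length(fwd), paths[1], length(rev), paths[2]),
              "pairing_error")
  } else {
    if (length(paths) != 1L)
      rf_stop("interleaved layout requires exactly one file", "io_error")
    all <- read_seq_file(paths[1])
    if (length(all) %% 2L != 0L)
      rf_stop(sprintf("odd record count (%d) in interleaved file '%s'",
                      length(all), paths[1]), "pairing_error")
    idx <- seq_along(all)
    fwd <- all[idx %% 2L == 1L]
    rev <- all[idx %% 2L == 0L]
  }
  rs <- read_set(fwd, rev, source = paste(paths, collapse = " + "))
  if (!is.null(min_read_length) && rs$read_length < min_read_length)
    rf_stop(sprintf("reads of length %d are shorter than the required minimum %d",
                    rs$read_length, min_read_length), "parse_error")
  rs
}

#' Write assembled repeats to FASTA
#'
#' Writes one FASTA record per assembled repeat, sequence lines wrapped at 60
#' columns, upper-cased. Headers carry the repeat id, length, number of
#' constituent raw contigs and mean re-mapping coverage, e.g.
#' `>rep_1 length=812 contigs=3 mean_cov=21.4`.
#'
#' @param repeats An `assembled_repeats` data frame (see [merge_paths()]), or
#'   any data frame with columns `id`, `sequence` and optionally `n_contigs`,
#'   `mean_coverage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(repeats, path) {
  n <- nrow(repeats)
  if (is.null(n)) rf_stop("repeats must be a data frame", "io_error")
  if (n == 0L) {
    ok <- tryCatch({ file.create(path); TRUE },
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !file.exists(path))
      rf_stop(paste0("cannot write '", path, "'"), "io_error")
    return(invisible(path))
  }
  nc <- if ("n_contigs" %in% names(repeats)) repeats$n_contigs else rep(1L, n)
  mc <- if ("mean_coverage" %in% names(repeats)) repeats$mean_coverage else rep(NA_real_, n)
  seqs <- toupper(repeats$sequence)
  names(seqs) <- sprintf("%s length=%d contigs=%d mean_cov=%s",
                         repeats$id, nchar(seqs), nc,
                         ifelse(is.na(mc), "NA", formatC(mc, format = "f", digits = 1)))
  ss <- Biostrings::DNAStringSet(seqs)
  tryCatch(Biostrings::writeXStringSet(ss, path, width = 60L),
           error = function(e) rf_stop(
             paste0("cannot write '", path, "': ", conditionMessage(e)), "io_error"))
  invisible(path)
}

#' Load a repeat library (FASTA) as a named character vector
#'
#' @param path FASTA file of reference repeat consensus sequences.
#' @return Named character vector of uppercase sequences.
#' @export
load_library <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) rf_stop(
                   paste0("malformed fasta '", path, "': ", conditionMessage(e)),
                   "parse_error"))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
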