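#' Pipeline configuration
#'
#' Collects every tunable parameter of the repeat-assembly pipeline in one
#' validated object. The defaults are the method's standard operating point:
#' k-mer lengths 29/39/49, frequent-k-mer cutoff factor 10 over the average
#' k-mer frequency, frequency bins spanning `[0.2f, 5f]` around each target
#' frequency `f` with successive targets halved, a minimum suffix-prefix
#' overlap of 15 bp at under 5 percent mismatches (substitutions plus indels),
#' a 5 bp shared-substring prefilter, at least one supporting read pair per
#' junction where the insert size makes straddling pairs possible, and a
#' minimum average re-mapping coverage of 2 for a contig to be kept.
#'
#' @param kmer_lengths Integer vector of odd k-mer lengths used for raw-contig
#'   assembly; all must be smaller than `read_length`.
#' @param freq_cutoff_factor Frequent-k-mer cutoff factor: a k-mer is frequent
#'   when its count is strictly greater than this factor times the average
#'   k-mer frequency.
#' @param bin_low_factor,bin_high_factor A frequency bin with target `f` spans
#'   `[bin_low_factor * f, bin_high_factor * f]`. Must bracket 1.
#' @param bin_ratio Factor (> 1) by which successive bin target frequencies
#'   decrease; must be smaller than `bin_high_factor / bin_low_factor` so that
#'   consecutive bins overlap.
#' @param min_overlap_bp Minimum suffix-prefix overlap length (bp) for a
#'   contig-graph edge.
#' @param max_mismatch_rate Maximum fraction of mismatches (substitutions +
#'   indels) in a qualifying overlap; the comparison is strict (`< rate`).
#' @param prefilter_substring_len Length `k0` of the exact shared substring
#'   required before two contigs are aligned at all.
#' @param min_read_pair_support Minimum number of read pairs straddling a
#'   junction for the edge to be kept, when such pairs are geometrically
#'   expected given the insert size.
#' @param min_avg_coverage Contigs whose mean re-mapping coverage falls below
#'   this value are discarded; positions below it delimit truncation.
#' @param read_length Read length of the input library (bp).
#' @param insert_size_mean,insert_size_sd Insert-size (outer fragment length)
#'   mean and standard deviation of the paired-end library.
#' @param matching_cutoff Evaluation matching cutoff `t_L`: minimum ratio of
#'   matched length to query length for a library hit.
#' @param canonical Count canonical k-mers (strand-independent) when `TRUE`;
#'   set `FALSE` only for strand-aware tests.
#' @param freq_baseline `"distinct-mean"` (default): average k-mer frequency is
#'   total occurrences over distinct observed k-mers. `"depth-estimate"`: use
#'   an estimate of the per-base read depth instead.
#' @param seed_length Exact-seed length of the built-in read mapper.
#' @param max_map_error_rate Maximum per-base error rate of an accepted read
#'   placement (aligned region).
#' @param rng_seed Seed used by every randomised step.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config(read_length = 100)
#' cfg$freq_cutoff_factor
#' @export
pipeline_config <- function(kmer_lengths = c(29L, 39L, 49L),
                            freq_cutoff_factor = 10,
                            bin_low_factor = 0.2,
                            bin_high_factor = 5,
                            bin_ratio = 2,
                            min_overlap_bp = 15L,
                            max_mismatch_rate = 0.05,
                            prefilter_substring_len = 5L,
                            min_read_pair_support = 1L,
                            min_avg_coverage = 2,
                            read_length = 100L,
                            insert_size_mean = 300,
                            insert_size_sd = 30,
                            matching_cutoff = 0.85,
                            canonical = TRUE,
                            freq_baseline = c("distinct-mean", "depth-estimate"),
                            seed_length = 20L,
                            max_map_error_rate = 0.06,
                            rng_seed = 42L) {
  freq_baseline <- match.arg(freq_baseline)
  cfg <- list(
    kmer_lengths = as.integer(sort(kmer_lengths)),
    freq_cutoff_factor = freq_cutoff_factor,
    bin_low_factor = bin_low_factor,
    bin_high_factor = bin_high_factor,
    bin_ratio = bin_ratio,
    min_overlap_bp = as.integer(min_overlap_bp),
    max_mismatch_rate = max_mismatch_rate,
    prefilter_substring_len = as.integer(prefilter_substring_len),
    min_read_pair_support = as.integer(min_read_pair_support),
    min_avg_coverage = min_avg_coverage,
    read_length = as.integer(read_length),
    insert_size_mean = insert_size_mean,
    insert_size_sd = insert_size_sd,
    matching_cutoff = matching_cutoff,
    canonical = isTRUE(canonical),
    freq_baseline = freq_baseline,
    seed_length = as.integer(seed_length),
    max_map_error_rate = max_map_error_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (length(kmer_lengths) < 1L || any(kmer_lengths < 3L))
      rf_stop("kmer_lengths must be positive integers >= 3", "config_error")
    if (any(kmer_lengths %% 2L == 0L))
      rf_stop("kmer_lengths must be odd", "config_error")
    if (!is_count1(freq_cutoff_factor) && freq_cutoff_factor != 0)
      rf_stop("freq_cutoff_factor must be a non-negative number", "config_error")
    if (!(bin_low_factor < 1 && 1 < bin_high_factor))
      rf_stop("bin factors must satisfy bin_low_factor < 1 < bin_high_factor", "config_error")
    if (bin_ratio <= 1)
      rf_stop("bin_ratio must exceed 1", "config_error")
    if (bin_ratio >= bin_high_factor / bin_low_factor)
      rf_stop("bin_ratio must be < bin_high_factor / bin_low_factor so consecutive bins overlap", "config_error")
    if (min_overlap_bp < prefilter_substring_len)
      rf_stop("min_overlap_bp must be >= prefilter_substring_len", "config_error")
    if (max_mismatch_rate < 0 || max_mismatch_rate >= 1)
      rf_stop("max_mismatch_rate must lie in [0, 1)", "config_error")
    if (matching_cutoff < 0 || matching_cutoff > 1)
      rf_stop("matching_cutoff must lie in [0, 1]", "config_error")
    if (any(kmer_lengths >= read_length))
      rf_stop("all kmer_lengths must be smaller than read_length", "config_error")
    if (insert_size_mean <= 0 || insert_size_sd <= 0)
      rf_stop("insert size parameters must be positive", "config_error")
    if (min_avg_coverage < 0 || min_read_pair_support < 0)
      rf_stop("coverage/support thresholds must be non-negative", "config_error")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Repeat-assembly pipeline configuration\n")
  cat("  k-mer lengths:        ", paste(x$kmer_lengths, collapse = ", "), "\n")
  cat("  frequency cutoff:     > ", x$freq_cutoff_factor, " x average k-mer frequency\n", sep = "")
  cat("  frequency bins:       [", x$bin_low_factor, "f, ", x$bin_high_factor,
      "f], ratio ", x$bin_ratio, "\n", sep = "")
  cat("  overlap:              >= ", x$min_overlap_bp, " bp, < ",
      100 * x$max_mismatch_rate, "% mismatches, k0 = ",
      x$prefilter_substring_len, "\n", sep = "")
  cat("  read-pair support:    >= ", x$min_read_pair_support, " when expected\n", sep = "")
  cat("  coverage threshold:   ", x$min_avg_coverage, "\n", sep = "")
  cat("  reads:                ", x$read_length, " bp, insert ", x$insert_size_mean,
      " +/- ", x$insert_size_sd, "\n", sep = "")
  cat("  matching cutoff t_L:  ", x$matching_cutoff, "\n", sep = "")
  invisible(x)
}

#' Read a flat key = value configuration file
#'
#' Reads a plain-text file of `key = value` lines (comments start with `#`)
#' and returns a [pipeline_config()] built from it; keys not present keep
#' their defaults. Values given as comma-separated numbers become vectors
#' (e.g. `kmer_lengths = 29,39,49`).
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied after the file (e.g. from command-line flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) rf_stop(paste0("config file not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      rf_stop(paste0("malformed config line: '", ln, "'"), "config_error")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!anyNA(num)) num else if (val %in% c("TRUE", "FALSE")) as.logical(val) else val
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}
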