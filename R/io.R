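#' @useDynLib rdnavar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median sd var rnorm runif rbinom rmultinom rgamma
#'   quantile lm.fit pt pnorm qchisq setNames complete.cases glm binomial
#'   coef plogis hclust as.dist qnorm
#' @importFrom utils read.delim write.table head modifyList packageVersion
NULL

# Interchange conventions used by every writer in the package:
#  * TSV, tab-separated, NA as missing token, '#' comment header lines
#  * coordinates 1-based inclusive in TSV; BED on disk is 0-based half-open
#  * gzip-transparent: paths ending in .gz are compressed

#' Write a data frame as TSV with a provenance comment header
#'
#' Every table the package emits carries comment lines naming the tool
#' version and the coordinate convention, so downstream consumers can audit
#' provenance without side channels.
#'
#' @param df data frame to write.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param comments extra comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("# rdnavar ", as.character(utils::packageVersion("rdnavar"))),
    "# coordinates: 1-based inclusive within subunit",
    paste0("# ", comments)
  )
  writeLines(hdr[nzchar(sub("^# ?", "", hdr)) | !grepl("^# $", hdr)], con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path input path (gzip-transparent).
#' @param ... passed to [utils::read.delim()].
#' @return data frame.
#' @export
read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA", ...)
}

#' Read short reads from FASTQ
#'
#' Qualities are kept as the raw Phred+33 ASCII string; decode with
#' [phred_to_int()] where per-base scores are needed.
#'
#' @param path FASTQ path, optionally gzip-compressed.
#' @return data frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  sset <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(
    read_id  = sub("\\s.*$", "", names(sset)),
    sequence = as.character(sset),
    quality  = as.character(S4Vectors::mcols(sset)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write short reads to FASTQ
#'
#' @param reads data frame with `read_id`, `sequence`, `quality` columns.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Convert Phred+33 ASCII quality strings to integer scores
#' @param quality character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_to_int <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Convert integer Phred scores to an ASCII quality string
#' @param scores integer vector of Phred scores.
#' @return character scalar.
#' @export
int_to_phred <- function(scores) {
  intToUtf8(scores + 33L)
}

#' Write a configuration snapshot alongside outputs
#'
#' @param config named list of parameters.
#' @param dir output directory.
#' @return path of the written YAML snapshot, invisibly.
#' @export
write_config_snapshot <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "config_snapshot.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}

# md5 of an input file, recorded in run logs
input_checksum <- function(path) {
  as.character(tools::md5sum(path))
}

# Evaluate code under a given seed, restoring the caller's RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
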