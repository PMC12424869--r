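# Perfect-match mapping of short reads to extended atlas alleles, read
# classification (unmapped / unique / multi-mapper), and SAM in/out.
#
# Only perfect alignments count downstream, so mapping is exact substring
# search rather than scored alignment: the index is a k-mer seed table with
# base-by-base verification (src/mapper.cpp). Quality-masked mode treats
# read positions with base quality <= min_base_quality as wildcards and
# requires a gapless match at all remaining positions.

#' Build a perfect-match index over atlas alleles
#'
#' @param atlas an [rdna_atlas()].
#' @param k seed k-mer length (default 31); exactness does not depend on k,
#'   only lookup speed does.
#' @return object of class `pm_index`.
#' @export
build_read_index <- function(atlas, k = 31L) {
  stopifnot(inherits(atlas, "rdna_atlas"))
  if (nrow(atlas$alleles) == 0L) stop("atlas has no alleles")
  ids <- paste(atlas$alleles$region_id, atlas$alleles$allele_id, sep = "|")
  if (anyDuplicated(ids))
    stop("duplicate (region, allele) ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(
    ptr = .build_index_cpp(atlas$alleles$extended_sequence, as.integer(k)),
    region_id = atlas$alleles$region_id,
    allele_id = atlas$alleles$allele_id,
    k = as.integer(k)
  ), class = "pm_index")
}

#' Map reads by perfect matching
#'
#' In `full` mode a hit requires the entire read to match an extended allele
#' verbatim; in `quality_masked` mode positions with base quality at or
#' below `min_base_quality` are wildcards and all other positions must
#' match, with no gaps. Both strands are searched. Empty reads are dropped
#' with a QC log entry (attribute `qc_log`), not an error.
#'
#' @param index a `pm_index` from [build_read_index()].
#' @param reads data frame with `read_id`, `sequence`, and (for masked mode)
#'   `quality` Phred+33 strings.
#' @param mode `"full"` or `"quality_masked"`.
#' @param min_base_quality mask threshold: qualities `<=` this value are
#'   wildcards (default 20, i.e. only bases with quality above 20 must match).
#' @return data frame of hits: `read_id`, `region_id`, `allele_id`,
#'   `offset` (0-based within the extended sequence), `strand`.
#' @export
map_reads_perfect <- function(index, reads, mode = c("full", "quality_masked"),
                              min_base_quality = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "pm_index"))
  qc <- character()
  empty <- !nzchar(reads$sequence)
  if (any(empty)) {
    qc <- paste0("empty read rejected: ", reads$read_id[empty])
    reads <- reads[!empty, , drop = FALSE]
  }
  masked <- mode == "quality_masked"
  quals <- if (masked) {
    if (is.null(reads$quality)) stop("quality_masked mode needs a quality column")
    reads$quality
  } else rep("", nrow(reads))
  raw <- .map_reads_cpp(index$ptr, reads$sequence, quals, masked,
                        as.integer(min_base_quality))
  hits <- data.frame(
    read_id = reads$read_id[raw$read],
    region_id = index$region_id[raw$seq],
    allele_id = index$allele_id[raw$seq],
    offset = raw$offset, strand = raw$strand,
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$read_id, hits$region_id, hits$allele_id,
                     hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "qc_log") <- qc
  hits
}

#' Reference brute-force perfect-match scanner
#'
#' Sliding-window comparison of every read (both strands) against every
#' extended allele at every offset, sharing no machinery with the indexed
#' mapper. Intended as an independent cross-check at small scale.
#'
#' @inheritParams map_reads_perfect
#' @param atlas an [rdna_atlas()].
#' @return hits data frame in the same layout as [map_reads_perfect()].
#' @export
scan_reads_naive <- function(atlas, reads, mode = c("full", "quality_masked"),
                             min_base_quality = 20L) {
  mode <- match.arg(mode)
  seqs <- atlas$alleles$extended_sequence
  seq_int <- lapply(seqs, utf8ToInt)
  out <- vector("list", nrow(reads) * 2L)
  n_out <- 0L
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (i in seq_len(nrow(reads))) {
    sq <- reads$read_id[i]
    for (strand in c("+", "-")) {
      read <- if (strand == "+") reads$sequence[i] else rc(reads$sequence[i])
      if (!nzchar(read)) next
      n <- nchar(read)
      if (mode == "full") {
        for (j in seq_along(seqs)) {
          m <- gregexpr(read, seqs[j], fixed = TRUE)[[1L]]
          if (m[1L] == -1L) next
          for (pos in as.integer(m)) {
            n_out <- n_out + 1L
            out[[n_out]] <- data.frame(
              read_id = sq, region_id = atlas$alleles$region_id[j],
              allele_id = atlas$alleles$allele_id[j], offset = pos - 1L,
              strand = strand, stringsAsFactors = FALSE)
          }
        }
      } else {
        q <- utf8ToInt(reads$quality[i]) - 33L
        if (strand == "-") q <- rev(q)
        ri <- utf8ToInt(read)
        good <- which(q > min_base_quality & ri %in% utf8ToInt("ACGT"))
        for (j in seq_along(seqs)) {
          O <- length(seq_int[[j]]) - n + 1L
          if (O < 1L) next
          ok <- rep(TRUE, O)
          for (p in good) {
            ok <- ok & seq_int[[j]][p:(p + O - 1L)] == ri[p]
            if (!any(ok)) break
          }
          for (pos in which(ok)) {
            n_out <- n_out + 1L
            out[[n_out]] <- data.frame(
              read_id = sq, region_id = atlas$alleles$region_id[j],
              allele_id = atlas$alleles$allele_id[j], offset = pos - 1L,
              strand = strand, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hits <- if (n_out) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(read_id = character(), region_id = character(),
               allele_id = character(), offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$read_id, hits$region_id, hits$allele_id,
                     hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify reads as unmapped, unique or multi-mapper
#'
#' A read is a unique mapper iff exactly one allele (across all regions) has
#' a perfect hit; two or more distinct alleles make it a multi-mapper. The
#' resolved region/allele is reported for unique mappers.
#'
#' @param hits hits data frame from [map_reads_perfect()] or [ingest_sam()].
#' @param read_ids ids of all reads that were mapped (so unmapped reads are
#'   accounted for); defaults to the ids present in `hits`.
#' @return data frame `read_id`, `class`, `n_alleles`, `region_id`,
#'   `allele_id` (the latter two NA unless unique).
#' @export
classify_reads <- function(hits, read_ids = unique(hits$read_id)) {
  key <- paste(hits$region_id, hits$allele_id, sep = "|")
  per_read <- tapply(key, hits$read_id, function(x) unique(x),
                     simplify = FALSE)
  n <- vapply(read_ids, function(id) {
    v <- per_read[[id]]
    if (is.null(v)) 0L else length(v)
  }, 1L)
  cls <- ifelse(n == 0L, "unmapped", ifelse(n == 1L, "unique", "multimapper"))
  resolved <- ifelse(cls == "unique",
                     vapply(read_ids, function(id) {
                       v <- per_read[[id]]
                       if (is.null(v) || length(v) != 1L) NA_character_ else v
                     }, ""), NA_character_)
  parts <- strsplit(resolved, "|", fixed = TRUE)
  data.frame(
    read_id = read_ids, class = cls, n_alleles = n,
    region_id = vapply(parts, function(p)
      if (length(p) == 2L) p[1L] else NA_character_, ""),
    allele_id = vapply(parts, function(p)
      if (length(p) == 2L) p[2L] else NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

# ---------------------------------------------------------------------------
# SAM interchange. References are named "region|allele" over the extended
# sequences. Written alignments are gapless by construction; ingested
# alignments (e.g. from `bwa mem -a`) are re-verified against the atlas
# before being trusted.

#' Write perfect hits as SAM
#'
#' @param hits hits data frame from [map_reads_perfect()].
#' @param reads the reads data frame the hits came from.
#' @param atlas the atlas mapped against.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reads, atlas, path) {
  ids <- paste(atlas$alleles$region_id, atlas$alleles$allele_id, sep = "|")
  lens <- nchar(atlas$alleles$extended_sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", ids, "\tLN:", lens)), con)
  if (nrow(hits) == 0L) return(invisible(path))
  ridx <- match(hits$read_id, reads$read_id)
  first <- !duplicated(hits$read_id)
  recs <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    seq <- reads$sequence[ridx[i]]
    qual <- if (!is.null(reads$quality)) reads$quality[ridx[i]] else
      strrep("I", nchar(seq))
    flag <- 0L
    if (hits$strand[i] == "-") {
      flag <- flag + 16L
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      qual <- paste(rev(strsplit(qual, "")[[1L]]), collapse = "")
    }
    if (!first[i]) flag <- flag + 256L
    recs[i] <- paste(hits$read_id[i], flag,
                     paste(hits$region_id[i], hits$allele_id[i], sep = "|"),
                     hits$offset[i] + 1L, 255L, paste0(nchar(seq), "M"),
                     "*", 0L, 0L, seq, qual, sep = "\t")
  }
  writeLines(recs, con)
  invisible(path)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1L]]
  if (m[1L] == -1L) return(data.frame(len = integer(), op = character()))
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1L]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Ingest alignments from SAM, keeping only verified perfect hits
#'
#' Secondary and supplementary alignments are retained (the `bwa mem -a`
#' behaviour). Every alignment is re-verified against the atlas sequence:
#' gapped CIGARs (I/D/N) are excluded; in full mode any soft clip excludes
#' the record, while in quality-masked mode clipped bases must be
#' low-quality; the stored sequence must match the allele at every
#' non-wildcard position.
#'
#' @param path SAM path.
#' @param atlas an [rdna_atlas()].
#' @inheritParams map_reads_perfect
#' @return hits data frame as in [map_reads_perfect()], with attribute
#'   `read_ids` naming every read seen in the file.
#' @export
ingest_sam <- function(path, atlas, mode = c("full", "quality_masked"),
                       min_base_quality = 20L) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  ids <- paste(atlas$alleles$region_id, atlas$alleles$allele_id, sep = "|")
  ext <- setNames(atlas$alleles$extended_sequence, ids)
  out <- list(); n_out <- 0L; seen <- character()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record at line ", ln)
    flag <- as.integer(f[2L])
    seen <- c(seen, f[1L])
    if (bitwAnd(flag, 4L) != 0L) next
    if (!f[3L] %in% ids)
      stop("SAM reference name not in atlas: ", f[3L])
    cig <- parse_cigar(f[6L])
    if (any(cig$op %in% c("I", "D", "N", "H", "P"))) next
    sc_lead <- if (nrow(cig) && cig$op[1L] == "S") cig$len[1L] else 0L
    sc_trail <- if (nrow(cig) && cig$op[nrow(cig)] == "S")
      cig$len[nrow(cig)] else 0L
    if (mode == "full" && (sc_lead > 0L || sc_trail > 0L)) next
    seq <- f[10L]; qual <- f[11L]
    n <- nchar(seq)
    q <- if (qual == "*") rep(60L, n) else utf8ToInt(qual) - 33L
    good <- if (mode == "full") rep(TRUE, n) else q > min_base_quality
    if (sc_lead > 0L && any(good[seq_len(sc_lead)])) next
    if (sc_trail > 0L && any(good[(n - sc_trail + 1L):n])) next
    if (mode == "quality_masked" && sc_lead + sc_trail > 0L)
      good[c(seq_len(sc_lead), if (sc_trail) (n - sc_trail + 1L):n)] <- FALSE
    offset <- as.integer(f[4L]) - 1L - sc_lead
    allele_seq <- ext[[f[3L]]]
    if (offset < 0L || offset + n > nchar(allele_seq)) next
    si <- utf8ToInt(substr(allele_seq, offset + 1L, offset + n))
    ri <- utf8ToInt(seq)
    if (any(good & si != ri)) next
    parts <- strsplit(f[3L], "|", fixed = TRUE)[[1L]]
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(
      read_id = f[1L], region_id = parts[1L], allele_id = parts[2L],
      offset = offset, strand = if (bitwAnd(flag, 16L)) "-" else "+",
      stringsAsFactors = FALSE)
  }
  hits <- if (n_out) unique(do.call(rbind, out[seq_len(n_out)])) else
    data.frame(read_id = character(), region_id = character(),
               allele_id = character(), offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$read_id, hits$region_id, hits$allele_id,
                     hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "read_ids") <- unique(seen)
  hits
}

#' Per-read mapping report
#' @param classified output of [classify_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(classified, path) {
  write_tsv_commented(classified, path,
    "mapping report: class in {unmapped, unique, multimapper}")
}
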