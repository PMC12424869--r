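# Atlas model: subunit references, ES/non-ES region annotations, atlas
# alleles with reference flanks, and the allele -> nucleotide-variant lookup
# tables that drive the frequency conversion.
#
# Coordinate convention: 1-based inclusive positions within each subunit
# (18S or 28S). Indels are left-anchored VCF-style with one shared reference
# base, e.g. "2177:G:GTG" inserts TG after the G at position 2177.

#' Parse canonical variant keys
#'
#' A variant key is `"<position>:<ref>:<alt>"` with 1-based position on the
#' subunit. SNVs have single-base ref and alt; insertions and deletions share
#' one left-anchor reference base (`"3514:G:GCAG"` is an insertion of CAG
#' after position 3514; `"100:ACG:A"` deletes CG after position 100).
#'
#' @param key character vector of variant keys.
#' @param subunit_id optional subunit the keys belong to (recycled).
#' @return data frame with columns `position`, `ref`, `alt`, `key`,
#'   `subunit_id`, `type` (snv/ins/del/mnv).
#' @export
#' @examples
#' parse_variant_key(c("4913:C:T", "3514:G:GCAG"))
parse_variant_key <- function(key, subunit_id = NA_character_) {
  m <- regmatches(key, regexec("^([0-9]+):([ACGT]+):([ACGT]+)$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed variant key: ", paste(key[bad], collapse = ", "))
  position <- as.integer(vapply(m, `[[`, "", 2L))
  ref <- vapply(m, `[[`, "", 3L)
  alt <- vapply(m, `[[`, "", 4L)
  if (any(ref == alt))
    stop("ref equals alt in key: ", paste(key[ref == alt], collapse = ", "))
  type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
          ifelse(nchar(ref) <  nchar(alt), "ins",
          ifelse(nchar(ref) >  nchar(alt), "del", "mnv")))
  data.frame(position = position, ref = ref, alt = alt, key = key,
             subunit_id = rep_len(subunit_id, length(key)), type = type,
             stringsAsFactors = FALSE)
}

#' Format a variant key from its parts
#' @param position 1-based position on the subunit.
#' @param ref,alt reference and alternate strings.
#' @return character vector of keys; `format(parse(key)) == key`.
#' @export
format_variant_key <- function(position, ref, alt) {
  paste(position, ref, alt, sep = ":")
}

#' Apply variant keys to a reference region sequence
#'
#' Reconstructs an allele's core sequence from the reference region and the
#' allele's variant list; used to validate lookup tables and by the
#' synthetic-atlas generator.
#'
#' @param region_seq reference sequence of the region.
#' @param region_start 1-based start of the region on the subunit.
#' @param keys character vector of variant keys (subunit coordinates).
#' @return mutated sequence (character scalar).
#' @export
apply_variant_keys <- function(region_seq, region_start, keys) {
  if (length(keys) == 0L) return(region_seq)
  v <- parse_variant_key(keys)
  v$rel <- v$position - region_start + 1L
  if (any(v$rel < 1L | v$rel + nchar(v$ref) - 1L > nchar(region_seq)))
    stop("variant outside region: ",
         paste(v$key[v$rel < 1L], collapse = ", "))
  v <- v[order(v$rel, decreasing = TRUE), , drop = FALSE]
  ends <- v$rel + nchar(v$ref) - 1L
  if (any(v$rel[-nrow(v)] <= ends[-1L]))
    stop("overlapping variants: ", paste(v$key, collapse = ", "))
  seq <- region_seq
  for (i in seq_len(nrow(v))) {
    span <- substr(seq, v$rel[i], ends[i])
    if (span != v$ref[i])
      stop("reference mismatch for ", v$key[i], ": region has ", span)
    seq <- paste0(substr(seq, 1L, v$rel[i] - 1L), v$alt[i],
                  substr(seq, ends[i] + 1L, nchar(seq)))
  }
  seq
}

#' Extend an allele core sequence with reference flanks
#'
#' Concatenates up to `flank_len` bases of non-variant reference sequence on
#' each side of the allele core so that reads as long as the flank can map
#' across region boundaries. Flanks are truncated at subunit ends.
#'
#' @param core_sequence allele sequence spanning the region.
#' @param subunit_seq full subunit reference sequence.
#' @param start,end 1-based inclusive region coordinates on the subunit.
#' @param flank_len maximum flank length in bases (default 150, matching the
#'   150 b read length the atlas is designed for).
#' @return extended sequence (character scalar).
#' @export
extend_allele <- function(core_sequence, subunit_seq, start, end,
                          flank_len = 150L) {
  n <- nchar(subunit_seq)
  if (start < 1L || end > n || start > end)
    stop("region coordinates [", start, ", ", end,
         "] outside subunit of length ", n)
  if (flank_len < 0L) stop("flank_len must be >= 0")
  f5 <- min(flank_len, start - 1L)
  f3 <- min(flank_len, n - end)
  paste0(substr(subunit_seq, start - f5, start - 1L),
         core_sequence,
         substr(subunit_seq, end + 1L, end + f3))
}

# ---------------------------------------------------------------------------
# Variant derivation by global alignment (for atlas rows without an explicit
# variant list). Needleman-Wunsch via Biostrings, then indel runs are
# left-shifted so keys are deterministic and VCF-style left-anchored.

left_shift_ops <- function(ops, ref_chars) {
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$op == "del") {
      while (op$i > 1L && ref_chars[op$i - 1L] == ref_chars[op$j]) {
        op$i <- op$i - 1L; op$j <- op$j - 1L
      }
    } else if (op$op == "ins") {
      while (op$p > 0L &&
             ref_chars[op$p] == substr(op$seq, nchar(op$seq), nchar(op$seq))) {
        op$seq <- paste0(ref_chars[op$p],
                         substr(op$seq, 1L, nchar(op$seq) - 1L))
        op$p <- op$p - 1L
      }
    }
    ops[[i]] <- op
  }
  ops
}

#' Derive variant keys by aligning an allele core to the reference region
#'
#' Global Needleman-Wunsch alignment of the core sequence against the
#' reference region, with left-shift normalization of indels, emitted as
#' left-anchored variant keys in subunit coordinates. Self-describes
#' synthetic or externally-sourced atlas rows that lack a variant list.
#'
#' @inheritParams apply_variant_keys
#' @param core_sequence the allele core sequence.
#' @return character vector of variant keys in ascending position order.
#' @export
derive_variant_keys <- function(core_sequence, region_seq, region_start) {
  if (core_sequence == region_seq) return(character())
  aln <- Biostrings::pairwiseAlignment(
    pattern = core_sequence, subject = region_seq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ref_chars <- strsplit(region_seq, "")[[1L]]
  ops <- list(); ref_pos <- 0L; i <- 1L
  while (i <= length(p)) {
    if (s[i] != "-" && p[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (s[i] != p[i])
        ops[[length(ops) + 1L]] <- list(op = "snv", i = ref_pos, alt = p[i])
      i <- i + 1L
    } else if (p[i] == "-") {            # deletion run (ref bases absent)
      j0 <- ref_pos + 1L
      while (i <= length(p) && p[i] == "-") { ref_pos <- ref_pos + 1L; i <- i + 1L }
      ops[[length(ops) + 1L]] <- list(op = "del", i = j0, j = ref_pos)
    } else {                             # insertion run (extra core bases)
      ins <- character()
      while (i <= length(p) && s[i] == "-") { ins <- c(ins, p[i]); i <- i + 1L }
      ops[[length(ops) + 1L]] <- list(op = "ins", p = ref_pos,
                                      seq = paste(ins, collapse = ""))
    }
  }
  ops <- left_shift_ops(ops, ref_chars)
  keys <- vapply(ops, function(op) {
    if (op$op == "snv") {
      format_variant_key(region_start - 1L + op$i, ref_chars[op$i], op$alt)
    } else if (op$op == "del") {
      if (op$i == 1L)
        stop("deletion at region start cannot be left-anchored within region")
      format_variant_key(region_start - 1L + op$i - 1L,
                         paste(ref_chars[(op$i - 1L):op$j], collapse = ""),
                         ref_chars[op$i - 1L])
    } else {
      if (op$p == 0L)
        stop("insertion before region start cannot be left-anchored within region")
      format_variant_key(region_start - 1L + op$p, ref_chars[op$p],
                         paste0(ref_chars[op$p], op$seq))
    }
  }, "")
  pos <- parse_variant_key(keys)$position
  keys[order(pos, keys)]
}

# ---------------------------------------------------------------------------
# Atlas container

#' Construct an rDNA variant atlas
#'
#' Bundles the subunit reference sequences, the ES/non-ES region tiling and
#' the per-region atlas alleles, extends every allele with reference flanks,
#' and validates the structural invariants (regions tile each subunit,
#' exactly one reference allele per region, abundances sum to at most 1).
#'
#' @param reference named character vector of uppercase subunit sequences
#'   (names are subunit ids such as `"18S"`, `"28S"`).
#' @param regions data frame with columns `region_id`, `subunit_id`,
#'   `region_class` (`"ES"`/`"non-ES"`), `start`, `end` (1-based inclusive).
#' @param alleles data frame with columns `region_id`, `allele_id`,
#'   `core_sequence`, `atlas_abundance`, and optionally `variants` (a list
#'   column of variant-key character vectors; missing entries are derived by
#'   alignment when the lookup table is built).
#' @param flank_len reference flank length in bases (default 150).
#' @return object of class `rdna_atlas`.
#' @export
rdna_atlas <- function(reference, regions, alleles, flank_len = 150L) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (any(grepl("[^ACGT]", reference)))
    stop("reference sequences must be uppercase ACGT")
  regions <- as.data.frame(regions)
  need <- c("region_id", "subunit_id", "region_class", "start", "end")
  stopifnot(all(need %in% names(regions)))
  regions$length <- regions$end - regions$start + 1L
  for (su in unique(regions$subunit_id)) {
    if (!su %in% names(reference)) stop("no reference for subunit ", su)
    r <- regions[regions$subunit_id == su, ]
    r <- r[order(r$start), ]
    if (r$start[1L] != 1L || r$end[nrow(r)] != nchar(reference[[su]]) ||
        (nrow(r) > 1L && any(r$start[-1L] != r$end[-nrow(r)] + 1L)))
      stop("regions do not tile subunit ", su)
  }
  alleles <- as.data.frame(alleles)
  stopifnot(all(c("region_id", "allele_id", "core_sequence",
                  "atlas_abundance") %in% names(alleles)))
  if (!"variants" %in% names(alleles))
    alleles$variants <- vector("list", nrow(alleles))
  if (anyDuplicated(alleles[c("region_id", "allele_id")]))
    stop("duplicate (region_id, allele_id)")
  ext <- character(nrow(alleles))
  for (i in seq_len(nrow(alleles))) {
    reg <- regions[regions$region_id == alleles$region_id[i], ]
    if (nrow(reg) != 1L) stop("unknown region ", alleles$region_id[i])
    ext[i] <- extend_allele(alleles$core_sequence[i],
                            reference[[reg$subunit_id]],
                            reg$start, reg$end, flank_len)
  }
  alleles$extended_sequence <- ext
  ab <- tapply(alleles$atlas_abundance, alleles$region_id, sum)
  if (any(ab > 1 + 1e-9))
    stop("atlas_abundance sums above 1 in region ",
         paste(names(ab)[ab > 1 + 1e-9], collapse = ", "))
  structure(list(reference = reference, regions = regions,
                 alleles = alleles, flank_len = as.integer(flank_len)),
            class = "rdna_atlas")
}

#' @export
print.rdna_atlas <- function(x, ...) {
  cat("rdna_atlas:", length(x$reference), "subunit(s),",
      nrow(x$regions), "regions,", nrow(x$alleles), "alleles, flank",
      x$flank_len, "bp\n")
  invisible(x)
}

region_row <- function(atlas, region_id) {
  r <- atlas$regions[atlas$regions$region_id == region_id, ]
  if (nrow(r) != 1L) stop("unknown region ", region_id)
  r
}

region_ref_seq <- function(atlas, region_id) {
  r <- region_row(atlas, region_id)
  substr(atlas$reference[[r$subunit_id]], r$start, r$end)
}

#' Build the allele-to-variant lookup tables
#'
#' For every region, maps each allele id to the ordered list of nucleotide
#' variant keys the allele carries. Variant lists supplied in the atlas are
#' validated by reconstructing the core sequence from the reference region;
#' missing lists are derived by global alignment ([derive_variant_keys()]).
#'
#' @param atlas an [rdna_atlas()].
#' @return named list: `lookup[[region_id]][[allele_id]]` is a character
#'   vector of variant keys (empty for the reference allele), class
#'   `rdna_lookup`.
#' @export
build_lookup_table <- function(atlas) {
  stopifnot(inherits(atlas, "rdna_atlas"))
  lookup <- list()
  for (rid in atlas$regions$region_id) {
    reg <- region_row(atlas, rid)
    refseq <- region_ref_seq(atlas, rid)
    al <- atlas$alleles[atlas$alleles$region_id == rid, , drop = FALSE]
    if (nrow(al) == 0L) next
    entry <- list()
    for (i in seq_len(nrow(al))) {
      keys <- al$variants[[i]]
      if (is.null(keys) || (length(keys) == 1L && is.na(keys[1L]))) {
        keys <- derive_variant_keys(al$core_sequence[i], refseq, reg$start)
      } else {
        keys <- as.character(keys)
        rebuilt <- tryCatch(apply_variant_keys(refseq, reg$start, keys),
                            error = function(e) NA_character_)
        if (is.na(rebuilt) || rebuilt != al$core_sequence[i])
          stop("allele ", rid, "/", al$allele_id[i],
               ": stated variants do not reconstruct its core sequence")
      }
      if (length(keys)) {
        pv <- parse_variant_key(keys)
        if (any(pv$position < reg$start | pv$position > reg$end))
          stop("allele ", rid, "/", al$allele_id[i],
               ": variant outside region coordinates")
        keys <- keys[order(pv$position, keys)]
      }
      entry[[al$allele_id[i]]] <- keys
    }
    if (!any(vapply(entry, length, 1L) == 0L))
      stop("region ", rid, " has no reference allele (empty variant set)")
    lookup[[rid]] <- entry
  }
  structure(lookup, class = "rdna_lookup",
            region_subunit = stats::setNames(atlas$regions$subunit_id,
                                             atlas$regions$region_id))
}

#' All variant keys of a lookup table, with their region and subunit
#'
#' Raw keys (`position:ref:alt`) are only unique within a subunit — the 18S
#' and the 28S can each have, say, a `60:G:A` — so cohort-level column ids
#' are qualified with the subunit, `"28S:60:G:A"` style.
#'
#' @param lookup an `rdna_lookup` from [build_lookup_table()].
#' @return data frame `key` (subunit-qualified id), `raw_key`,
#'   `region_id`, `subunit_id`; deduplicated, position-ordered.
#' @export
lookup_variants <- function(lookup) {
  rsu <- attr(lookup, "region_subunit")
  out <- do.call(rbind, lapply(names(lookup), function(rid) {
    keys <- unique(unlist(lookup[[rid]], use.names = FALSE))
    if (length(keys) == 0L) return(NULL)
    su <- if (!is.null(rsu)) unname(rsu[[rid]]) else NA_character_
    data.frame(key = if (is.na(su)) keys else paste(su, keys, sep = ":"),
               raw_key = keys, region_id = rid, subunit_id = su,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(key = character(), raw_key = character(),
                      region_id = character(), subunit_id = character()))
  out <- out[order(out$region_id, parse_variant_key(out$raw_key)$position,
                   out$raw_key), , drop = FALSE]
  if (anyDuplicated(out$key))
    stop("duplicate qualified variant keys: ",
         paste(unique(out$key[duplicated(out$key)]), collapse = ", "))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Atlas I/O: FASTA (one record per extended allele, id "region|allele") with
# a TSV sidecar for abundances and variant lists; BED for region annotations.

#' Write extended allele sequences to FASTA
#' @param atlas an [rdna_atlas()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_atlas_fasta <- function(atlas, path) {
  seqs <- Biostrings::DNAStringSet(atlas$alleles$extended_sequence)
  names(seqs) <- paste(atlas$alleles$region_id, atlas$alleles$allele_id,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the atlas sidecar TSV (allele metadata)
#' @param atlas an [rdna_atlas()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_atlas_sidecar <- function(atlas, path) {
  al <- atlas$alleles
  df <- data.frame(
    allele_id = al$allele_id, region_id = al$region_id,
    variants = vapply(al$variants, function(v)
      if (is.null(v)) NA_character_ else paste(v, collapse = ","), ""),
    atlas_abundance = al$atlas_abundance,
    core_sequence = al$core_sequence,
    stringsAsFactors = FALSE)
  write_tsv_commented(df, path,
    "atlas sidecar: variants comma-joined, empty for reference allele")
}

#' Write region annotations as BED (0-based half-open on disk)
#'
#' The BED name field encodes `region_id|region_class`; coordinates are
#' converted from the package's 1-based inclusive convention.
#'
#' @param regions the atlas `regions` data frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$subunit_id,
                   start = regions$start - 1L, end = regions$end,
                   name = paste(regions$region_id, regions$region_class,
                                sep = "|"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read region annotations from BED
#' @param path BED path (0-based half-open; name field `region_id|class`).
#' @return regions data frame in 1-based inclusive coordinates.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED needs 4 columns (chrom,start,end,name): ", path)
  parts <- strsplit(df[[4L]], "|", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 2L))
    stop("BED name field must be 'region_id|class' at line ",
         which(vapply(parts, length, 1L) != 2L)[1L])
  data.frame(region_id = vapply(parts, `[[`, "", 1L),
             subunit_id = df[[1L]],
             region_class = vapply(parts, `[[`, "", 2L),
             start = df[[2L]] + 1L, end = df[[3L]],
             stringsAsFactors = FALSE)
}

#' Read an atlas from FASTA + sidecar + reference + regions
#'
#' Inverse of [write_atlas_fasta()]/[write_atlas_sidecar()]. Extended
#' sequences are re-derived from core + reference and checked against the
#' FASTA records, so a round trip is validated, not assumed.
#'
#' @param fasta_path extended-allele FASTA (ids `region|allele`).
#' @param sidecar_path sidecar TSV from [write_atlas_sidecar()].
#' @param reference named character vector of subunit sequences.
#' @param regions regions data frame (e.g. from [read_regions_bed()]).
#' @param flank_len flank length used when the atlas was written.
#' @return an [rdna_atlas()].
#' @export
read_atlas <- function(fasta_path, sidecar_path, reference, regions,
                       flank_len = 150L) {
  side <- read_tsv_commented(sidecar_path)
  side$variants <- lapply(side$variants, function(v) {
    if (is.na(v)) NULL
    else if (!nzchar(v)) character()
    else strsplit(v, ",", fixed = TRUE)[[1L]]
  })
  atlas <- rdna_atlas(reference, regions, side, flank_len = flank_len)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- paste(atlas$alleles$region_id, atlas$alleles$allele_id, sep = "|")
  m <- match(ids, sub("\\s.*$", "", names(seqs)))
  if (anyNA(m)) stop("FASTA is missing alleles: ",
                     paste(ids[is.na(m)], collapse = ", "))
  if (!identical(unname(as.character(seqs)[m]),
                 atlas$alleles$extended_sequence))
    stop("FASTA extended sequences disagree with core + reference flanks")
  atlas
}

#' Export lookup tables as TSV
#' @param lookup an `rdna_lookup`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_lookup_tsv <- function(lookup, path) {
  rows <- do.call(rbind, lapply(names(lookup), function(rid) {
    data.frame(region_id = rid, allele_id = names(lookup[[rid]]),
               variant_keys = vapply(lookup[[rid]], paste, "",
                                     collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv_commented(rows, path, "lookup table: allele -> variant keys")
}
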