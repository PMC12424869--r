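# Allele counting and conversion to nucleotide-variant relative
# frequencies, plus depth statistics, population-variability ranking, the
# rDNA copy-number proxy and cross-platform concordance QC.

#' Count per-allele read support for one participant
#'
#' Three counting policies are supported. `fractional` (default) splits a
#' read hitting k distinct alleles as 1/k to each, so per-region totals
#' conserve the number of mapped reads. `unique_only` counts only unique
#' mappers (the rare-variant burden convention). `all_hits` adds 1 to every
#' hit allele (a naive all-alignments count).
#'
#' @param hits hits data frame for one participant.
#' @param policy `"fractional"`, `"unique_only"` or `"all_hits"`.
#' @return data frame `region_id`, `allele_id`, `count`.
#' @export
count_alleles <- function(hits,
                          policy = c("fractional", "unique_only", "all_hits")) {
  policy <- match.arg(policy)
  if (nrow(hits) == 0L)
    return(data.frame(region_id = character(), allele_id = character(),
                      count = numeric(), stringsAsFactors = FALSE))
  u <- unique(hits[c("read_id", "region_id", "allele_id")])
  k <- table(u$read_id)[u$read_id]
  w <- switch(policy,
    fractional  = 1 / as.numeric(k),
    unique_only = as.numeric(k == 1L),
    all_hits    = rep(1, nrow(u)))
  agg <- stats::aggregate(w, by = list(region_id = u$region_id,
                                       allele_id = u$allele_id), FUN = sum)
  names(agg)[3L] <- "count"
  agg <- agg[agg$count > 0, , drop = FALSE]
  agg <- agg[order(agg$region_id, agg$allele_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Cohort variant-frequency table
#'
#' Converts per-allele counts to nucleotide-variant relative frequencies:
#' within each region, the frequency of variant v for a participant is the
#' summed count of alleles carrying v divided by the total count of reads
#' mapped to the region. A region with zero total yields missing (NA)
#' frequencies — "region unobserved" — distinct from an observed 0.
#'
#' @param counts_by_participant named list of [count_alleles()] outputs, one
#'   per participant (names are participant ids), or a single data frame
#'   with a `participant_id` column.
#' @param lookup an `rdna_lookup` from [build_lookup_table()].
#' @return object of class `variant_freq_table`: a list with matrices
#'   `freq` (participants x variant keys, in `[0,1]` or NA),
#'   `variant_depth` (reads supporting each variant), `region_total`
#'   (participants x regions) and the `variant_region` annotation.
#' @export
variant_frequency_table <- function(counts_by_participant, lookup) {
  if (is.data.frame(counts_by_participant)) {
    counts_by_participant <- split(
      counts_by_participant[setdiff(names(counts_by_participant),
                                    "participant_id")],
      counts_by_participant$participant_id)
  }
  participants <- names(counts_by_participant)
  if (is.null(participants)) stop("participant ids required as list names")
  vinfo <- lookup_variants(lookup)
  keys <- vinfo$key
  regions <- names(lookup)
  freq <- matrix(NA_real_, length(participants), length(keys),
                 dimnames = list(participants, keys))
  vdepth <- matrix(0, length(participants), length(keys),
                   dimnames = list(participants, keys))
  rtot <- matrix(0, length(participants), length(regions),
                 dimnames = list(participants, regions))
  for (p in participants) {
    cnt <- counts_by_participant[[p]]
    unknown <- setdiff(unique(cnt$region_id), regions)
    if (length(unknown))
      stop("counts reference regions absent from lookup: ",
           paste(unknown, collapse = ", "))
    for (rid in unique(cnt$region_id)) {
      entry <- lookup[[rid]]
      sub <- cnt[cnt$region_id == rid, , drop = FALSE]
      missing_alleles <- setdiff(sub$allele_id, names(entry))
      if (length(missing_alleles))
        stop("allele in counts absent from lookup (region ", rid, "): ",
             paste(missing_alleles, collapse = ", "))
      total <- sum(sub$count)
      rtot[p, rid] <- total
      rv <- vinfo[vinfo$region_id == rid, , drop = FALSE]
      if (total <= 0 || nrow(rv) == 0L) next
      for (j in seq_len(nrow(rv))) {
        carriers <- names(entry)[vapply(entry, function(v)
          rv$raw_key[j] %in% v, TRUE)]
        vdepth[p, rv$key[j]] <- sum(sub$count[sub$allele_id %in% carriers])
      }
      freq[p, rv$key] <- vdepth[p, rv$key] / total
    }
    # regions with zero mapped reads stay NA (unobserved)
    zero_regions <- regions[rtot[p, ] <= 0]
    zkeys <- vinfo$key[vinfo$region_id %in% zero_regions]
    if (length(zkeys)) freq[p, zkeys] <- NA_real_
  }
  structure(list(freq = freq, variant_depth = vdepth, region_total = rtot,
                 variant_region = stats::setNames(vinfo$region_id, vinfo$key),
                 variant_raw = stats::setNames(vinfo$raw_key, vinfo$key)),
            class = "variant_freq_table")
}

#' @export
print.variant_freq_table <- function(x, ...) {
  cat("variant_freq_table:", nrow(x$freq), "participants x",
      ncol(x$freq), "variants over", ncol(x$region_total), "regions\n")
  invisible(x)
}

#' Per-variant read-depth statistics and low-depth flags
#'
#' Mean (across the cohort) of the reads mapped to alleles carrying each
#' variant; variants averaging below the threshold are flagged low-depth.
#' The threshold is strict: a mean of exactly `low_depth` is not flagged.
#'
#' @param vft a [variant_frequency_table()].
#' @param low_depth flag threshold in reads (default 5000).
#' @return data frame `key`, `region_id`, `mean_depth`, `low_depth`.
#' @export
depth_statistics <- function(vft, low_depth = 5000) {
  stopifnot(inherits(vft, "variant_freq_table"), nrow(vft$freq) >= 1L)
  md <- colMeans(vft$variant_depth)
  data.frame(key = colnames(vft$freq),
             region_id = unname(vft$variant_region[colnames(vft$freq)]),
             mean_depth = unname(md),
             low_depth = unname(md < low_depth),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank variants by population variability
#'
#' Orders variants by descending variance of frequency across participants
#' (ties broken by variant key) and reports the observed frequency range,
#' the view behind "top most-variable variant" summaries.
#'
#' @param vft a [variant_frequency_table()].
#' @param top_k number of variants to return.
#' @return data frame `key`, `region_id`, `variance`, `min`, `max`, `range`.
#' @export
rank_population_variability <- function(vft, top_k = 10L) {
  if (top_k <= 0L) stop("top_k must be positive")
  if (nrow(vft$freq) < 2L) stop("need at least 2 participants")
  v <- apply(vft$freq, 2L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  lo <- suppressWarnings(apply(vft$freq, 2L, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(vft$freq, 2L, max, na.rm = TRUE))
  lo[!is.finite(lo)] <- NA; hi[!is.finite(hi)] <- NA
  ord <- order(-v, colnames(vft$freq))
  out <- data.frame(key = colnames(vft$freq)[ord],
                    region_id = unname(vft$variant_region[colnames(vft$freq)][ord]),
                    variance = unname(v[ord]), min = unname(lo[ord]),
                    max = unname(hi[ord]),
                    range = unname(hi[ord] - lo[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out, top_k)
}

#' Estimate 45S rDNA copy number from the rDNA read fraction
#'
#' The copy-number proxy is the fraction of sequencing reads mapping to the
#' rDNA, scaled by a calibration constant into 45S copy units.
#'
#' @param n_rdna_reads reads mapped to rDNA (vectorized).
#' @param n_total_reads total sequenced reads.
#' @param scale_constant copies per unit read fraction.
#' @return data frame `rdna_read_fraction`, `c45S`.
#' @export
estimate_rdna_copy_number <- function(n_rdna_reads, n_total_reads,
                                      scale_constant) {
  if (any(n_total_reads <= 0)) stop("n_total_reads must be positive")
  if (any(n_rdna_reads < 0 | n_rdna_reads > n_total_reads))
    stop("n_rdna_reads must lie in [0, n_total_reads]")
  frac <- n_rdna_reads / n_total_reads
  data.frame(rdna_read_fraction = frac, c45S = frac * scale_constant)
}

#' Concordance between two variant-frequency profiles
#'
#' Pearson and Spearman correlations over shared non-missing variants (e.g.
#' short-read vs long-read calls on the same sample), plus the list of
#' variants whose frequencies differ by more than a threshold.
#'
#' @param freq_a,freq_b named numeric vectors of variant frequencies.
#' @param discordance_threshold absolute frequency difference above which a
#'   variant is reported discordant (default 0.1).
#' @param depth_flags optional named logical vector of low-depth flags used
#'   to annotate discordant variants.
#' @return list with `pearson`, `spearman`, `n_shared`, `discordant` (data
#'   frame `key`, `freq_a`, `freq_b`, `delta`, `low_depth`).
#' @export
variant_concordance <- function(freq_a, freq_b, discordance_threshold = 0.1,
                                depth_flags = NULL) {
  shared <- intersect(names(freq_a), names(freq_b))
  a <- freq_a[shared]; b <- freq_b[shared]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need at least 3 shared non-missing variants")
  delta <- abs(a - b)
  disc <- which(delta > discordance_threshold)
  list(
    pearson = stats::cor(a, b, method = "pearson"),
    spearman = stats::cor(a, b, method = "spearman"),
    n_shared = length(a),
    discordant = data.frame(
      key = names(a)[disc], freq_a = unname(a[disc]),
      freq_b = unname(b[disc]), delta = unname(delta[disc]),
      low_depth = if (is.null(depth_flags)) rep(NA, length(disc)) else
        unname(depth_flags[names(a)[disc]]),
      stringsAsFactors = FALSE, row.names = NULL))
}

#' Write a variant-frequency table (and sidecars) as TSV
#' @param vft a [variant_frequency_table()].
#' @param dir output directory; writes `variant_frequencies.tsv`,
#'   `region_totals.tsv` and `variant_depth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_frequency_tables <- function(vft, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- data.frame(participant_id = rownames(vft$freq), vft$freq,
                  check.names = FALSE)
  write_tsv_commented(f, file.path(dir, "variant_frequencies.tsv"),
    "frequencies in [0,1]; NA = region unobserved, 0 = variant absent")
  rt <- data.frame(participant_id = rownames(vft$region_total),
                   vft$region_total, check.names = FALSE)
  write_tsv_commented(rt, file.path(dir, "region_totals.tsv"),
                      "reads mapped per region")
  vd <- data.frame(participant_id = rownames(vft$variant_depth),
                   vft$variant_depth, check.names = FALSE)
  write_tsv_commented(vd, file.path(dir, "variant_depth.tsv"),
                      "reads supporting each variant")
  invisible(dir)
}
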